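#!/usr/bin/env Rscript
# Variant filtering: consequence classes, the <=0.005 multi-database MAF
# gate, then the strict trio-recessive model and the proband-only fallback.
# Finding expected under non-paternity: the strict model returns nothing,
# the fallback keeps the planted homozygous nonsense variant.

suppressMessages(library(triorecess))

trio <- read_trio_vcf("results/sim/trio.vcf")
fc <- filter_cascade(trio, trio_config())

surv <- fc[fc$pass & is_autosome(fc$chrom), ]
cat(nrow(trio), "records ->", sum(fc$pass_consequence), "damaging class ->",
    nrow(surv), "past the MAF gate\n")
cat("strict trio-recessive tags:",
    sum(surv$model_trio != "none"), "\n")
cat("proband-only tags:",
    sum(surv$model_proband == "hom_proband_only"), "homozygous,",
    sum(surv$model_proband == "comp_het_proband_only"), "compound het\n")

keep <- surv[surv$model_proband != "none" | surv$model_trio != "none", ]
write.table(keep, "results/02_surviving_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Survivors with an inheritance tag written to results/02_surviving_variants.tsv\n")
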