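#!/usr/bin/env Rscript
# Homozygosity mapping in the proband: maximal runs of homozygous calls,
# regions of more than 30 Mb retained, the carrier mother's heterozygosity
# inside each region as a descriptive cross-check, and localization of the
# candidate variant.

suppressMessages(library(triorecess))

trio <- read_trio_vcf("results/sim/trio.vcf")
auto <- trio[is_autosome(trio$chrom), ]

runs <- detect_runs(auto$chrom, auto$pos, auto$gt_proband)
large <- filter_large_regions(runs, 30)
large <- cross_sample_roh(large, auto$chrom, auto$pos, auto$gt_mother)

cat(nrow(runs), "runs detected;", nrow(large), "longer than 30 Mb\n")
print(large)

cand <- read.delim("results/02_surviving_variants.tsv")
hom <- cand[cand$model_proband == "hom_proband_only", ]
idx <- annotate_in_region(hom$chrom, hom$pos, large)
cat(sum(!is.na(idx)), "of", nrow(hom),
    "homozygous candidates lie inside a large region\n")

write.table(large, "results/03_large_roh.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
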