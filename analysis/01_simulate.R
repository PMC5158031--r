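#!/usr/bin/env Rscript
# Generate the study-condition inputs: a 50,000-site trio exome with a
# planted 40 Mb autozygous segment on chromosome 3 carrying a homozygous
# nonsense variant in GNAT1, an unrelated recorded father, Y markers, and
# 200-target capture depths at 80x with one planted deletion and one
# planted duplication. Everything downstream reads these files.

suppressMessages(library(triorecess))

spec <- simulation_spec(
  father_mode = "unrelated",
  planted_cnv = list(list(target = 50, ratio = 0.5),
                     list(target = 150, ratio = 1.5)),
  seed = 1L)

sim <- simulate_trio(spec)
dep <- simulate_depth(spec)
out <- "results/sim"
write_simulation(sim, dep, out)

cat("Simulated trio:", nrow(sim$trio), "records (",
    sum(is_autosome(sim$trio$chrom)), "autosomal,",
    spec$n_y_markers, "Y markers )\n")
pv <- spec$planted_variant
cat(sprintf("Planted variant: %s %s:%d (CDS %d), child hom_alt, mother het, father hom_ref\n",
            pv$gene, pv$chrom, pv$pos, pv$cds_pos))
cat("Planted segment: chr3 40-80 Mb; planted CNVs at targets 50 (x0.5) and 150 (x1.5)\n")
cat("Inputs written under", out, "\n")
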