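#!/usr/bin/env Rscript
# Depth-of-coverage CNV screen of the proband against the reference pool:
# correlation gate, per-target copy scores, inclusive threshold calls,
# common-CNV exclusion, and the exome depth QC summary.

suppressMessages(library(triorecess))

d <- read_depth_table("results/sim/depth.tsv")
pop <- read_population_cnv("results/sim/population_cnv.tsv")
pool <- d$depths[, grep("^pool", colnames(d$depths)), drop = FALSE]

scr <- cnv_screen(d$depths[, "proband"], pool, d$targets,
                  population = pop, config = trio_config())
cat(sprintf("Pool correlation %.4f (gate > 0.97: %s)\n",
            scr$correlation, scr$valid))
print(scr$calls)

qc <- depth_qc_summary(d$depths[, "proband"], d$targets)
cat(sprintf("QC: %.1f%% of targeted bases >=10x, %.1f%% >=25x, mean depth %.1fx\n",
            100 * qc$fraction_at["10"], 100 * qc$fraction_at["25"],
            qc$mean_depth))

write.table(scr$calls, "results/04_cnv_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
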