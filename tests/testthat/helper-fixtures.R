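# Construct small trio tables in code.

make_trio <- function(gt_p, gt_m, gt_f,
                      chrom = "1", pos = seq_along(gt_p) * 1000,
                      gene = "", consequence = "missense",
                      af_exac = NA_real_, af_evs = NA_real_,
                      af_hapmap = NA_real_, af_1kg = NA_real_) {
  n <- length(gt_p)
  data.frame(
    chrom = rep_len(chrom, n), pos = pos,
    ref = rep_len("A", n), alt = rep_len("G", n),
    consequence = rep_len(consequence, n),
    gene = rep_len(gene, n), cds_pos = rep_len(NA_real_, n),
    af_evs = rep_len(af_evs, n), af_hapmap = rep_len(af_hapmap, n),
    af_1kg = rep_len(af_1kg, n), af_exac = rep_len(af_exac, n),
    gt_proband = gt_p, gt_mother = gt_m, gt_father = gt_f,
    stringsAsFactors = FALSE
  )
}

# Random trio table for property tests (all fields independent).
random_trio <- function(n, n_genes = max(1, n %/% 3)) {
  states <- c("hom_ref", "het", "hom_alt", "missing")
  freqs <- function() ifelse(runif(n) < 0.3, NA_real_, runif(n)^3)
  make_trio(
    gt_p = sample(states, n, replace = TRUE, prob = c(4, 3, 2, 1)),
    gt_m = sample(states, n, replace = TRUE, prob = c(4, 3, 2, 1)),
    gt_f = sample(states, n, replace = TRUE, prob = c(4, 3, 2, 1)),
    gene = sprintf("G%03d", sample.int(n_genes, n, replace = TRUE)),
    consequence = sample(c("nonsense", "missense", "splice_site",
                           "small_insertion", "small_deletion", "other"),
                         n, replace = TRUE)
  ) |> transform(af_evs = freqs(), af_hapmap = freqs(),
                 af_1kg = freqs(), af_exac = freqs())
}
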