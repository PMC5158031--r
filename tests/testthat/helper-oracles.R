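# Independent brute-force oracles. Deliberately naive (quadratic loops,
# per-element evaluation of the definitions) and shared by the unit and
# acceptance suites.

# All maximal homozygous runs with at most k embedded het calls, by
# exhaustive enumeration of candidate windows over non-missing markers.
oracle_runs <- function(chrom, pos, state, k = 0) {
  out <- list()
  for (ch in unique(chrom)) {
    obs <- which(chrom == ch & state != "missing")
    s <- state[obs]
    hom <- s %in% c("hom_ref", "hom_alt")
    n <- length(obs)
    cum_het <- cumsum(!hom)
    n_het_in <- function(a, b) cum_het[b] - if (a > 1) cum_het[a - 1] else 0
    valid <- list()
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a > b || !hom[a] || !hom[b]) next
      if (n_het_in(a, b) > k) next
      if ((b - a + 1) - n_het_in(a, b) < 2) next
      valid[[length(valid) + 1]] <- c(a, b)
    }
    if (length(valid) == 0) next
    vm <- do.call(rbind, valid)
    for (i in seq_len(nrow(vm))) {
      a <- vm[i, 1]; b <- vm[i, 2]
      contained <- any(vm[, 1] <= a & vm[, 2] >= b &
                         (vm[, 1] < a | vm[, 2] > b))
      if (!contained) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start_pos = pos[obs[a]], end_pos = pos[obs[b]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start_pos = numeric(0),
                      end_pos = numeric(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_containment <- function(chrom, pos, regions) {
  vapply(seq_along(chrom), function(i) {
    for (j in seq_len(nrow(regions))) {
      if (regions$chrom[j] == chrom[i] &&
          pos[i] >= regions$start_pos[j] && pos[i] <= regions$end_pos[j])
        return(j)
    }
    NA_integer_
  }, integer(1))
}

# Per-row evaluation of the consequence + MAF gates straight from their
# definitions.
oracle_cascade_pass <- function(trio, threshold) {
  damaging <- c("nonsense", "missense", "splice_site",
                "small_insertion", "small_deletion")
  vapply(seq_len(nrow(trio)), function(i) {
    if (!trio$consequence[i] %in% damaging) return(FALSE)
    for (col in c("af_evs", "af_hapmap", "af_1kg", "af_exac")) {
      v <- trio[[col]][i]
      if (!is.na(v) && v > threshold) return(FALSE)
    }
    TRUE
  }, logical(1))
}

oracle_cnv_calls <- function(scores, del, dup) {
  call <- rep(NA_character_, length(scores))
  for (i in seq_along(scores)) {
    if (is.na(scores[i])) next
    if (scores[i] <= del) call[i] <- "deletion"
    else if (scores[i] >= dup) call[i] <- "duplication"
  }
  call
}

# Pairwise closed-interval overlap of calls against common population CNVs.
oracle_common_filter <- function(calls, population, bound) {
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(population))) {
      if (is.na(population$freq[j]) || population$freq[j] <= bound) next
      if (calls$chrom[i] == population$chrom[j] &&
          calls$start[i] < population$end[j] &&
          population$start[j] < calls$end[i]) keep[i] <- FALSE
    }
  }
  calls[keep, , drop = FALSE]
}

# Per-base recount of the depth QC summary.
oracle_qc <- function(depths, targets, thresholds) {
  per_base <- rep(depths, times = targets$end - targets$start)
  list(fraction_at = vapply(thresholds,
                            function(t) mean(per_base >= t), numeric(1)),
       mean_depth = mean(per_base))
}
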