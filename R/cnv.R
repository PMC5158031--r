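#' Correlation gate against the reference pool
#'
#' Pearson correlation between a sample's per-target depth vector and the
#' per-target median of the reference pool. Comparison is considered valid
#' only when the correlation strictly exceeds `corr_min` (default 0.97);
#' zero-variance vectors make the correlation undefined and the comparison
#' invalid.
#'
#' @param sample_depths Numeric vector of per-target depths.
#' @param pool Numeric matrix of pool depths, targets in rows, one column
#'   per reference sample, on the identical target list.
#' @param corr_min Strict lower bound for a valid comparison.
#' @return List with `correlation` (may be `NA`) and logical `valid`.
#' @export
reference_correlation <- function(sample_depths, pool, corr_min = 0.97) {
  pool <- as.matrix(pool)
  stopifnot(length(sample_depths) == nrow(pool), ncol(pool) >= 1)
  med <- pool_median_profile(pool)
  if (stats::sd(sample_depths) == 0 || stats::sd(med) == 0) {
    return(list(correlation = NA_real_, valid = FALSE))
  }
  r <- cor(sample_depths, med)
  list(correlation = r, valid = r > corr_min)
}

# Reference profile: per-target median over the pool after normalizing
# each pool sample to its own total depth (so library size never leaks
# into the median), rescaled to depth units.
pool_median_profile <- function(pool) {
  tot <- colSums(pool)
  stopifnot(all(tot > 0))
  shares <- sweep(pool, 2, tot, "/")
  apply(shares, 1, median) * mean(tot)
}

#' Per-target copy score
#'
#' Double-normalized depth ratio: the sample's share of its total depth at a
#' target, divided by the reference profile's share of its own total, where
#' the reference profile is the per-target median of the
#' library-size-normalized pool. The diploid expectation is 1.0, a
#' heterozygous deletion ~0.5, a heterozygous duplication ~1.5; the score is
#' invariant to every library size by construction.
#'
#' @inheritParams reference_correlation
#' @return Numeric vector of scores; targets where the pool median depth is
#'   zero are `NA` with a warning.
#' @export
copy_score <- function(sample_depths, pool) {
  pool <- as.matrix(pool)
  stopifnot(length(sample_depths) == nrow(pool))
  med <- pool_median_profile(pool)
  stopifnot(sum(sample_depths) > 0, sum(med) > 0)
  score <- (sample_depths / sum(sample_depths)) / (med / sum(med))
  if (any(med == 0)) {
    warning(sum(med == 0),
            " target(s) with zero pool median depth: score undefined")
    score[med == 0] <- NA_real_
  }
  score
}

#' Threshold CNV caller
#'
#' Flags exactly the targets whose copy score is at or below the deletion
#' threshold or at or above the duplication threshold (both inclusive, as
#' printed: \eqn{\le 0.5}, \eqn{\ge 1.5}). `NA` scores are never called.
#'
#' @param scores Numeric copy scores, one per target.
#' @param targets Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per score.
#' @param config A [trio_config()] supplying the two thresholds.
#' @return Data frame of calls: target columns, `target_index`, `score`,
#'   `call` in `{"deletion","duplication"}`.
#' @export
call_cnv <- function(scores, targets, config = trio_config()) {
  stopifnot(nrow(targets) == length(scores))
  del <- !is.na(scores) & scores <= config$cnv_del_threshold
  dup <- !is.na(scores) & scores >= config$cnv_dup_threshold
  idx <- which(del | dup)
  out <- targets[idx, c("chrom", "start", "end"), drop = FALSE]
  out$target_index <- idx
  out$score <- scores[idx]
  out$call <- as.character(ifelse(del[idx], "deletion", "duplication"))
  rownames(out) <- NULL
  out
}

#' Common-CNV exclusion
#'
#' Removes calls that overlap a population CNV reported at frequency
#' strictly above the recessive-variant bound (default 0.005); calls
#' overlapping only unknown-frequency population entries are retained.
#'
#' @param calls Output of [call_cnv()].
#' @param population Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `freq` (`NA` = unknown).
#' @param common_freq Strict frequency bound above which a population CNV is
#'   considered common.
#' @return The surviving subset of `calls`.
#' @export
filter_common_cnv <- function(calls, population, common_freq = 0.005) {
  if (nrow(calls) == 0 || nrow(population) == 0) return(calls)
  common <- population[!is.na(population$freq) &
                         population$freq > common_freq, , drop = FALSE]
  if (nrow(common) == 0) return(calls)
  gr_calls <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1L, calls$end))
  gr_pop <- GenomicRanges::GRanges(
    common$chrom, IRanges::IRanges(common$start + 1L, common$end))
  hit <- suppressWarnings( # disjoint seqlevels mean no overlap, not an error
    GenomicRanges::countOverlaps(gr_calls, gr_pop)) > 0
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Depth quality-control summary
#'
#' Length-weighted fraction of targeted bases covered at or above each depth
#' threshold, and the length-weighted mean depth, treating each target's
#' mean depth as uniform across its bases.
#'
#' @param sample_depths Numeric per-target mean depths.
#' @param targets Data frame with `start`, `end` (0-based half-open).
#' @param thresholds Depth thresholds (defaults 10 and 25, the conventional
#'   exome QC cutoffs).
#' @return List with `fraction_at` (named by threshold) and `mean_depth`;
#'   all `NA` with a warning on an empty profile.
#' @export
depth_qc_summary <- function(sample_depths, targets, thresholds = c(10, 25)) {
  if (length(sample_depths) == 0) {
    warning("empty depth profile: QC undefined")
    return(list(fraction_at = setNames(rep(NA_real_, length(thresholds)),
                                       thresholds),
                mean_depth = NA_real_))
  }
  stopifnot(nrow(targets) == length(sample_depths), all(sample_depths >= 0))
  len <- targets$end - targets$start
  stopifnot(all(len > 0))
  frac <- vapply(thresholds,
                 function(t) sum(len[sample_depths >= t]) / sum(len),
                 numeric(1))
  list(fraction_at = setNames(frac, thresholds),
       mean_depth = sum(len * sample_depths) / sum(len))
}

#' One-sample CNV screen
#'
#' Composes the correlation gate, copy score, threshold calls and common-CNV
#' exclusion for one sample against a reference pool.
#'
#' @inheritParams reference_correlation
#' @param targets Target table (`chrom`, `start`, `end`).
#' @param population Optional population CNV frequency table
#'   (see [filter_common_cnv()]).
#' @param config A [trio_config()].
#' @return List with `correlation`, `valid`, `scores`, `calls` (empty with a
#'   warning when the correlation gate fails).
#' @export
cnv_screen <- function(sample_depths, pool, targets, population = NULL,
                       config = trio_config()) {
  gate <- reference_correlation(sample_depths, pool, config$cnv_corr_min)
  if (!gate$valid) {
    warning("correlation gate failed (r = ",
            format(gate$correlation, digits = 3),
            "): no valid CNV comparison")
    calls <- call_cnv(numeric(0), targets[0, , drop = FALSE], config)
    return(c(gate, list(scores = rep(NA_real_, length(sample_depths)),
                        calls = calls)))
  }
  scores <- copy_score(sample_depths, pool)
  calls <- call_cnv(scores, targets, config)
  if (!is.null(population))
    calls <- filter_common_cnv(calls, population, config$cnv_common_freq)
  c(gate, list(scores = scores, calls = calls))
}
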