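#' Opposite-homozygote count against one parent
#'
#' Counts autosomal sites where the child is homozygous for the alternate
#' allele while the named parent is homozygous reference — impossible under
#' error-free Mendelian transmission, so an elevated count against one
#' parent points at mis-assigned parentage. The reverse direction (child
#' homozygous reference, parent homozygous alternate) is available via
#' `direction`.
#'
#' @param trio Trio table (sex chromosomes and MT are excluded by
#'   chromosome name).
#' @param parent `"father"` or `"mother"`.
#' @param direction `"child_alt"` (default; child hom_alt vs parent hom_ref)
#'   or `"child_ref"` (the reverse).
#' @return Integer count.
#' @export
opposite_homozygote_count <- function(trio,
                                      parent = c("father", "mother"),
                                      direction = c("child_alt",
                                                    "child_ref")) {
  parent <- match.arg(parent)
  direction <- match.arg(direction)
  g_parent <- trio[[paste0("gt_", parent)]]
  auto <- is_autosome(trio$chrom)
  child <- trio$gt_proband
  if (direction == "child_alt") {
    sum(auto & child == "hom_alt" & g_parent == "hom_ref")
  } else {
    sum(auto & child == "hom_ref" & g_parent == "hom_alt")
  }
}

#' Y-chromosome marker divergence
#'
#' Compares haploid Y-marker alleles between father and son: `compared` is
#' the number of sites non-missing in both, `divergent` the number of those
#' with different alleles. A father--son pair shares the Y haplotype, so any
#' divergence beyond genotyping error questions the assumed paternity.
#'
#' @param father_alleles,son_alleles Vectors of haploid alleles (`NA` =
#'   missing), any comparable encoding.
#' @return List with integers `compared` and `divergent`.
#' @export
y_marker_divergence <- function(father_alleles, son_alleles) {
  stopifnot(length(father_alleles) == length(son_alleles))
  both <- !is.na(father_alleles) & !is.na(son_alleles)
  list(compared = sum(both),
       divergent = sum(both & father_alleles != son_alleles))
}

#' Trio consistency summary
#'
#' Tallies opposite-homozygote counts in both directions against each
#' parent, the Y-marker divergence between father and proband (taken from
#' rows on the Y chromosome, where the haploid call is encoded as
#' `hom_ref`/`hom_alt`), and the advisory non-paternity flag.
#'
#' @param trio Trio table.
#' @param config A [trio_config()].
#' @return List of class `consistency_summary`: `father_count`,
#'   `mother_count` (paper direction: child hom_alt, parent hom_ref),
#'   `father_count_rev`, `mother_count_rev`, `n_y_markers_compared`,
#'   `n_y_markers_divergent`, `paternity_questioned`.
#' @export
consistency_summary <- function(trio, config = trio_config()) {
  y <- trio[is_y_chrom(trio$chrom), , drop = FALSE]
  to_allele <- function(s) ifelse(s == "hom_ref", 0L,
                                  ifelse(s == "hom_alt", 1L, NA_integer_))
  ydiv <- y_marker_divergence(to_allele(y$gt_father),
                              to_allele(y$gt_proband))
  res <- list(
    father_count = opposite_homozygote_count(trio, "father", "child_alt"),
    mother_count = opposite_homozygote_count(trio, "mother", "child_alt"),
    father_count_rev = opposite_homozygote_count(trio, "father", "child_ref"),
    mother_count_rev = opposite_homozygote_count(trio, "mother", "child_ref"),
    n_y_markers_compared = ydiv$compared,
    n_y_markers_divergent = ydiv$divergent
  )
  res$paternity_questioned <- paternity_signal(
    res, ratio_threshold = config$paternity_ratio,
    y_divergent_min = config$y_divergent_min)
  class(res) <- "consistency_summary"
  res
}

#' Advisory non-paternity flag
#'
#' `TRUE` when the pseudocount ratio
#' `(father_count + 1) / (mother_count + 1)` reaches `ratio_threshold`, or
#' when at least `y_divergent_min` Y markers are divergent. The flag is an
#' explicit, reproducible formalization of an informal judgement; it is
#' advisory and never alters variant filtering.
#'
#' @param summary List with `father_count`, `mother_count`, and optionally
#'   `n_y_markers_divergent` (0 assumed if absent).
#' @param ratio_threshold Ratio at or above which the flag raises.
#' @param y_divergent_min Divergent-Y-marker count at or above which the
#'   flag raises.
#' @return Logical.
#' @export
paternity_signal <- function(summary, ratio_threshold = 20,
                             y_divergent_min = 3) {
  ydiv <- summary$n_y_markers_divergent
  if (is.null(ydiv)) ydiv <- 0L
  ratio <- (summary$father_count + 1) / (summary$mother_count + 1)
  ratio >= ratio_threshold || ydiv >= y_divergent_min
}

#' @export
print.consistency_summary <- function(x, ...) {
  cat("Trio consistency summary\n")
  cat(sprintf("  opposite homozygotes (child alt / parent ref): father %d, mother %d\n",
              x$father_count, x$mother_count))
  cat(sprintf("  reverse direction: father %d, mother %d\n",
              x$father_count_rev, x$mother_count_rev))
  cat(sprintf("  Y markers: %d compared, %d divergent\n",
              x$n_y_markers_compared, x$n_y_markers_divergent))
  cat(sprintf("  paternity questioned (advisory): %s\n",
              x$paternity_questioned))
  invisible(x)
}
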