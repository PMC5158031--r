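#' Pipeline configuration
#'
#' All tunable thresholds of the prioritization pipeline in one flat,
#' auditable object. Defaults reproduce the published analysis settings:
#' a minor-allele-frequency gate at 0.005 (inclusive), homozygous regions
#' retained when strictly longer than 30 Mb, per-target copy scores called
#' as deletion at \eqn{\le 0.5} and duplication at \eqn{\ge 1.5}, a Pearson
#' correlation gate of \eqn{> 0.97} against the reference pool, common-CNV
#' exclusion above population frequency 0.005, and a 50-nt
#' nonsense-mediated-decay window upstream of the last exon--exon junction.
#'
#' @param maf_threshold Inclusive upper bound on every known database allele
#'   frequency; variants absent from a database pass that database.
#' @param roh_min_length_mb Regions strictly longer than this (Mb) are kept
#'   by [filter_large_regions()].
#' @param roh_het_tolerance Number of embedded heterozygous calls tolerated
#'   inside one run of homozygosity (0 = strict).
#' @param cnv_del_threshold,cnv_dup_threshold Inclusive copy-score bounds for
#'   suspected deletion / duplication.
#' @param cnv_corr_min Pearson correlation with the pool median that a sample
#'   must strictly exceed before CNV comparison is considered valid.
#' @param cnv_common_freq Calls overlapping a population CNV with frequency
#'   strictly above this are discarded as common.
#' @param nmd_window_nt Coding nucleotides upstream of the last exon--exon
#'   junction that are still NMD-insensitive (field consensus 50--55; the
#'   conservative 50 is the default).
#' @param paternity_ratio Advisory flag threshold on the pseudocount ratio
#'   (father opposite-homozygote count + 1) / (mother count + 1).
#' @param y_divergent_min Advisory flag threshold on the number of divergent
#'   Y-chromosome markers between father and son.
#' @param missing_parent_compatible If `TRUE` (default) a missing parental
#'   genotype does not disqualify a variant under the strict trio model.
#' @param shortening_convention `"reference_length"` (default) reports
#'   `protein_length - stop_codon_position`; `"peptide_length"` reports the
#'   loss relative to the mutant peptide, one residue more.
#' @param random_seed Seed used by stages that randomize (currently only the
#'   simulator, which takes its own seed from its spec).
#'
#' @return A list of class `trio_config`.
#' @examples
#' cfg <- trio_config()
#' cfg$maf_threshold
#' @export
trio_config <- function(maf_threshold = 0.005,
                        roh_min_length_mb = 30,
                        roh_het_tolerance = 0L,
                        cnv_del_threshold = 0.5,
                        cnv_dup_threshold = 1.5,
                        cnv_corr_min = 0.97,
                        cnv_common_freq = 0.005,
                        nmd_window_nt = 50L,
                        paternity_ratio = 20,
                        y_divergent_min = 3L,
                        missing_parent_compatible = TRUE,
                        shortening_convention = c("reference_length",
                                                  "peptide_length"),
                        random_seed = 1L) {
  shortening_convention <- match.arg(shortening_convention)
  stopifnot(
    maf_threshold >= 0, maf_threshold <= 1,
    cnv_del_threshold < cnv_dup_threshold,
    nmd_window_nt >= 0,
    roh_het_tolerance >= 0,
    cnv_corr_min >= -1, cnv_corr_min <= 1,
    paternity_ratio > 0
  )
  structure(
    list(
      maf_threshold = maf_threshold,
      roh_min_length_mb = roh_min_length_mb,
      roh_het_tolerance = as.integer(roh_het_tolerance),
      cnv_del_threshold = cnv_del_threshold,
      cnv_dup_threshold = cnv_dup_threshold,
      cnv_corr_min = cnv_corr_min,
      cnv_common_freq = cnv_common_freq,
      nmd_window_nt = as.integer(nmd_window_nt),
      paternity_ratio = paternity_ratio,
      y_divergent_min = as.integer(y_divergent_min),
      missing_parent_compatible = isTRUE(missing_parent_compatible),
      shortening_convention = shortening_convention,
      random_seed = as.integer(random_seed)
    ),
    class = "trio_config"
  )
}

#' @export
print.trio_config <- function(x, ...) {
  cat("trio_config:\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
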