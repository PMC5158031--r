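#' Consequence-class gate
#'
#' Keeps only the variant classes the published filtering retained:
#' nonsense, missense, splice-site, and small insertions or deletions.
#' Everything else (synonymous, UTR, intronic, ...) is annotated upstream
#' as `"other"` and dropped.
#'
#' @param consequence Character vector of consequence classes.
#' @return Logical vector, `TRUE` where the class passes the gate.
#' @examples
#' consequence_filter(c("nonsense", "other", "small_deletion"))
#' @export
consequence_filter <- function(consequence) {
  stopifnot(!anyNA(consequence))
  bad <- setdiff(unique(consequence), CONSEQUENCE_CLASSES)
  if (length(bad) > 0)
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  consequence %in% DAMAGING_CLASSES
}

#' Multi-database minor-allele-frequency gate
#'
#' A variant passes when every *known* database frequency is at or below the
#' threshold (inclusive, as printed: \eqn{\le 0.005} by default). A frequency
#' absent from a database (`NA`) passes that database: absence of evidence
#' must not discard a novel variant.
#'
#' @param pop_freqs Numeric matrix or data frame, one row per variant and one
#'   column per database, `NA` = unknown; or a plain numeric vector treated
#'   as a single variant's frequencies.
#' @param threshold Inclusive frequency bound in `[0, 1]`.
#' @return Logical vector, one element per variant.
#' @examples
#' maf_filter(c(exac = 0.0000083), 0.005)           # TRUE
#' maf_filter(rbind(c(0.01, NA), c(NA, NA)), 0.005) # FALSE, TRUE
#' @export
maf_filter <- function(pop_freqs, threshold = 0.005) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.null(dim(pop_freqs))) pop_freqs <- matrix(pop_freqs, nrow = 1)
  m <- as.matrix(pop_freqs)
  if (nrow(m) == 0) return(logical(0))
  if (length(m) > 0) {
    known <- m[!is.na(m)]
    stopifnot(all(known >= 0 & known <= 1))
  }
  apply(m, 1, function(f) all(f[!is.na(f)] <= threshold))
}

# A parental state is compatible with a required state when equal, or when
# missing and the configuration treats missing parents as non-disqualifying.
parent_compatible <- function(state, required, missing_ok) {
  state == required | (missing_ok & state == "missing")
}

#' Inheritance tags under the strict trio-recessive model
#'
#' `recessive_hom_trio`: proband homozygous for the alternate allele with
#' both unaffected parents heterozygous carriers. `compound_het_trio`: two
#' passing variants in one gene, the proband heterozygous for both, with the
#' trans configuration established through parental origin (each allele
#' carried by exactly one parent). All other patterns tag `none`.
#'
#' @param trio Trio table (see [read_trio_vcf()]) restricted to the variants
#'   under consideration (i.e. already past the consequence and frequency
#'   gates); gene-level grouping uses its `gene` column.
#' @param missing_ok Treat a missing parental call as compatible
#'   (default `TRUE`; the published analysis does not state a rule).
#' @return Character vector of tags, one per row of `trio`.
#' @export
tag_inheritance_trio <- function(trio, missing_ok = TRUE) {
  n <- nrow(trio)
  if (n == 0) return(character(0))
  p <- trio$gt_proband; m <- trio$gt_mother; f <- trio$gt_father

  hom <- p == "hom_alt" &
    parent_compatible(m, "het", missing_ok) &
    parent_compatible(f, "het", missing_ok)

  maternal <- p == "het" & m == "het" &
    parent_compatible(f, "hom_ref", missing_ok)
  paternal <- p == "het" & f == "het" &
    parent_compatible(m, "hom_ref", missing_ok)

  comp <- rep(FALSE, n)
  for (g in unique(trio$gene[trio$gene != ""])) {
    idx <- which(trio$gene == g)
    mat_i <- idx[maternal[idx]]
    pat_i <- idx[paternal[idx]]
    # need one allele from each parent, carried by distinct variants
    if (length(mat_i) > 0 && length(pat_i) > 0 &&
        length(union(mat_i, pat_i)) >= 2) {
      comp[union(mat_i, pat_i)] <- TRUE
    }
  }

  tags <- rep("none", n)
  tags[comp] <- "compound_het_trio"
  tags[hom] <- "recessive_hom_trio"
  tags
}

#' Inheritance tags under the proband-only fallback model
#'
#' Used when the strict trio model returns nothing (for instance under
#' de-novo mutation or mis-assigned parentage): parental genotypes are
#' ignored. `hom_proband_only`: proband homozygous alternate.
#' `comp_het_proband_only`: at least two passing heterozygous variants in
#' one gene in the proband (phase unknowable without parents, so any pair
#' qualifies).
#'
#' @inheritParams tag_inheritance_trio
#' @return Character vector of tags, one per row of `trio`.
#' @export
tag_inheritance_proband_only <- function(trio) {
  n <- nrow(trio)
  if (n == 0) return(character(0))
  p <- trio$gt_proband
  hom <- p == "hom_alt"

  het <- p == "het"
  comp <- rep(FALSE, n)
  for (g in unique(trio$gene[trio$gene != ""])) {
    idx <- which(trio$gene == g & het)
    if (length(idx) >= 2) comp[idx] <- TRUE
  }

  tags <- rep("none", n)
  tags[comp] <- "comp_het_proband_only"
  tags[hom] <- "hom_proband_only"
  tags
}

#' Full filtering cascade
#'
#' Applies the consequence gate and the multi-database frequency gate, then
#' tags each surviving variant under both inheritance model families.
#'
#' @param trio Trio table from [read_trio_vcf()] or [simulate_trio()].
#' @param config A [trio_config()].
#' @return The trio table with logical columns `pass_consequence`,
#'   `pass_maf`, `pass`, and tag columns `model_trio`, `model_proband`
#'   (`"none"` for variants failing the upstream gates).
#' @export
filter_cascade <- function(trio, config = trio_config()) {
  trio$pass_consequence <- consequence_filter(trio$consequence)
  trio$pass_maf <- maf_filter(trio[, FREQ_COLUMNS, drop = FALSE],
                              config$maf_threshold)
  trio$pass <- trio$pass_consequence & trio$pass_maf

  trio$model_trio <- rep("none", nrow(trio))
  trio$model_proband <- rep("none", nrow(trio))
  keep <- which(trio$pass)
  if (length(keep) > 0) {
    sub <- trio[keep, , drop = FALSE]
    trio$model_trio[keep] <-
      tag_inheritance_trio(sub, config$missing_parent_compatible)
    trio$model_proband[keep] <- tag_inheritance_proband_only(sub)
  }
  trio
}
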