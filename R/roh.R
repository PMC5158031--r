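#' Detect runs of homozygosity
#'
#' Finds maximal runs of homozygous genotype calls along each chromosome.
#' Missing calls neither break a run nor count as markers. With
#' `het_tolerance = k > 0`, a run is a maximal marker window containing at
#' most k heterozygous calls, trimmed so both endpoints are homozygous
#' markers; with the strict default (0) runs are plain homozygous stretches.
#' A run needs at least two homozygous markers. Runs never span chromosomes,
#' and the span is measured marker-to-marker (first to last homozygous
#' marker), not padded towards flanking heterozygous calls.
#'
#' @param chrom Chromosome per marker.
#' @param pos 1-based position per marker, sorted increasing within each
#'   chromosome (unsorted input is an error).
#' @param state Genotype state per marker
#'   (`hom_ref`/`het`/`hom_alt`/`missing`).
#' @param het_tolerance Maximum embedded heterozygous calls per run.
#' @return Data frame of regions: `chrom`, `start_pos`, `end_pos`,
#'   `length_mb` (`(end - start) / 1e6`), `n_markers` (homozygous markers in
#'   the run), `n_het` (tolerated heterozygous calls inside it).
#' @export
detect_runs <- function(chrom, pos, state, het_tolerance = 0L) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(state),
            all(state %in% GT_STATES))
  k <- as.integer(het_tolerance)
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    p <- pos[sel]
    if (is.unsorted(p, strictly = FALSE))
      stop("markers not sorted by position on chromosome ", ch)
    obs <- sel[state[sel] != "missing"]
    if (length(obs) == 0) next
    s <- state[obs]
    hom <- s %in% c("hom_ref", "hom_alt")
    n <- length(obs)
    bad <- which(!hom)
    # sentinels: k+1 trailing "hets" so windows with fewer than k embedded
    # hets still enumerate
    padded <- c(0L, bad, rep(n + 1L, k + 1L))
    seen <- character(0)
    for (j in seq_len(length(bad) + 1L)) {
      lo <- padded[j] + 1L
      hi <- padded[j + k + 1L] - 1L
      if (lo > hi) next
      in_win <- lo:hi
      hom_in <- in_win[hom[in_win]]
      if (length(hom_in) < 2) next
      lo2 <- min(hom_in); hi2 <- max(hom_in)
      key <- paste(lo2, hi2)
      if (key %in% seen) next
      seen <- c(seen, key)
      start_pos <- pos[obs[lo2]]
      end_pos <- pos[obs[hi2]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_pos = start_pos,
        end_pos = end_pos,
        length_mb = (end_pos - start_pos) / 1e6,
        n_markers = length(hom_in),
        n_het = sum(!hom[lo2:hi2]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start_pos = numeric(0),
                      end_pos = numeric(0), length_mb = numeric(0),
                      n_markers = integer(0), n_het = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(chrom_rank(res$chrom), res$start_pos), , drop = FALSE]
  # drop windows nested inside a larger reported window on the same chromosome
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    same <- which(res$chrom == res$chrom[i])
    for (j in same) {
      if (j != i && res$start_pos[j] <= res$start_pos[i] &&
          res$end_pos[j] >= res$end_pos[i] &&
          (res$start_pos[j] < res$start_pos[i] ||
           res$end_pos[j] > res$end_pos[i])) keep[i] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep large homozygous regions
#'
#' Retains regions strictly longer than `min_mb` megabases ("more than
#' 30 Mb" by default, hence the strict inequality: a region of exactly
#' 30.0 Mb is dropped).
#'
#' @param regions Output of [detect_runs()].
#' @param min_mb Strict lower bound in Mb.
#' @return The surviving subset of `regions`.
#' @export
filter_large_regions <- function(regions, min_mb = 30) {
  out <- regions[regions$length_mb > min_mb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate variants inside homozygous regions
#'
#' @param chrom,pos Variant coordinates (1-based).
#' @param regions Non-overlapping regions per chromosome
#'   (as from [detect_runs()]).
#' @return Integer vector: row index into `regions` of the containing region
#'   (closed interval `[start_pos, end_pos]`, same chromosome), `NA` if none.
#' @export
annotate_in_region <- function(chrom, pos, regions) {
  if (length(chrom) == 0) return(integer(0))
  if (nrow(regions) == 0) return(rep(NA_integer_, length(chrom)))
  gr_v <- GenomicRanges::GRanges(as.character(chrom),
                                 IRanges::IRanges(pos, pos))
  gr_r <- GenomicRanges::GRanges(as.character(regions$chrom),
                                 IRanges::IRanges(regions$start_pos,
                                                  regions$end_pos))
  hits <- suppressWarnings( # disjoint seqlevels are an expected no-overlap
    GenomicRanges::findOverlaps(gr_v, gr_r, type = "within",
                                select = "first"))
  as.integer(hits)
}

#' Maternal heterozygosity inside proband regions
#'
#' Annotates each proband region with the fraction of the mother's
#' non-missing markers inside its span that are heterozygous. A carrier
#' mother is expected to stay heterozygous across an identical-by-descent
#' segment of her child, so this is a descriptive cross-check, not a filter.
#'
#' @param regions Proband regions from [detect_runs()].
#' @param chrom,pos,state The mother's marker calls on the shared map.
#' @return `regions` with columns `mother_n_markers` and `mother_het_fraction`
#'   (`NA` when the mother has no non-missing marker in the span).
#' @export
cross_sample_roh <- function(regions, chrom, pos, state) {
  stopifnot(all(state %in% GT_STATES))
  n_obs <- integer(nrow(regions))
  frac <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    sel <- chrom == regions$chrom[i] &
      pos >= regions$start_pos[i] & pos <= regions$end_pos[i] &
      state != "missing"
    n_obs[i] <- sum(sel)
    if (n_obs[i] > 0) frac[i] <- mean(state[sel] == "het")
  }
  regions$mother_n_markers <- n_obs
  regions$mother_het_fraction <- frac
  regions
}
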