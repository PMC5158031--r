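#' Protein shortening caused by a premature stop codon
#'
#' Under the default `"reference_length"` convention the loss is
#' `protein_length - stop_codon_position`: a stop at residue 321 of the
#' 350-residue rod transducin alpha subunit loses 29 residues, a stop at
#' 302 loses 48. The alternative `"peptide_length"` convention counts the
#' residue replaced by the stop as well (`protein_length -
#' stop_codon_position + 1`, i.e. 30/49), since the mutant peptide has
#' `stop_codon_position - 1` residues; both are exposed because the field's
#' reporting is not uniform.
#'
#' @param stop_codon_position 1-based residue index at which translation
#'   terminates.
#' @param protein_length Reference protein length in residues.
#' @param convention `"reference_length"` (default) or `"peptide_length"`.
#' @return Integer number of amino acids lost.
#' @examples
#' shortening(321, 350) # 29
#' shortening(302, 350) # 48
#' @export
shortening <- function(stop_codon_position, protein_length,
                       convention = c("reference_length",
                                      "peptide_length")) {
  convention <- match.arg(convention)
  if (any(stop_codon_position < 1 | stop_codon_position > protein_length))
    stop("stop_codon_position out of range [1, protein_length]")
  base <- protein_length - stop_codon_position
  as.integer(if (convention == "reference_length") base else base + 1L)
}

#' Nonsense-mediated decay escape
#'
#' A premature stop codon escapes NMD when it lies in the last coding exon,
#' or within `window_nt` coding nucleotides (inclusive) upstream of the last
#' exon--exon junction — the 50--55 nt rule. A single-exon transcript always
#' escapes.
#'
#' @param cds_position_of_stop 1-based coding-sequence nucleotide position
#'   of the (start of the) premature stop codon.
#' @param transcript A [transcript_model()].
#' @param window_nt NMD-insensitive window upstream of the last junction
#'   (default 50 nt, the conservative end of the consensus range).
#' @return Logical.
#' @export
nmd_escape <- function(cds_position_of_stop, transcript, window_nt = 50) {
  lens <- transcript$exon_lengths
  stopifnot(cds_position_of_stop >= 1,
            cds_position_of_stop <= sum(lens))
  if (length(lens) == 1) return(TRUE)
  junction <- sum(lens[-length(lens)]) # CDS nt index of last exon-exon junction
  cds_position_of_stop > junction ||
    (junction - cds_position_of_stop) <= window_nt
}

#' Per-domain retention after truncation
#'
#' The truncated peptide retains residues `1 .. stop_codon_position - 1`.
#' A site interval is `retained` when it ends before the stop, `lost` when
#' it starts at or after the stop, and `partial` otherwise.
#'
#' @param stop_codon_position 1-based residue index of the premature stop.
#' @param domain_map A [domain_map()].
#' @return Named character vector over the map's sites with values in
#'   `{"retained", "partial", "lost"}`.
#' @examples
#' site_retention(321, gnat1_domain_map())[c("PDE6G_306_310", "RHO_311_328")]
#' @export
site_retention <- function(stop_codon_position, domain_map) {
  stopifnot(stop_codon_position >= 1,
            stop_codon_position <= domain_map$protein_length)
  s <- domain_map$sites
  status <- ifelse(s$end < stop_codon_position, "retained",
                   ifelse(s$start >= stop_codon_position, "lost", "partial"))
  setNames(status, s$name)
}

#' Domain map constructor
#'
#' Named 1-based closed residue intervals over a protein; point sites are
#' length-1 intervals.
#'
#' @param protein Protein name.
#' @param protein_length Length in residues.
#' @param sites Data frame with `name`, `start`, `end`.
#' @return List of class `domain_map`.
#' @export
domain_map <- function(protein, protein_length, sites) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("name", "start", "end") %in% names(sites)),
            !anyDuplicated(sites$name),
            all(sites$start >= 1), all(sites$end <= protein_length),
            all(sites$start <= sites$end))
  structure(list(protein = protein,
                 protein_length = as.integer(protein_length),
                 sites = sites[, c("name", "start", "end")]),
            class = "domain_map")
}

#' Read a domain map from JSON
#'
#' Expected shape: `{"protein": ..., "protein_length": ...,
#' "sites": [{"name":..., "start":..., "end":...}, ...]}` with 1-based
#' closed residue intervals.
#'
#' @param path JSON file.
#' @return A [domain_map()].
#' @export
read_domain_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain_map(j$protein, j$protein_length, j$sites)
}

#' Packaged GNAT1 functional-site map
#'
#' The rod transducin alpha subunit (GNAT1, 350 residues) with its
#' literature-reported functional sites: beta/gamma-transducin binding
#' (1--23), nuclear localization signal (21--52), magnesium coordination
#' (43, 177), GTP/GDP binding (36--43, 171--177, 196--200, 265--268,
#' 321--323), the PDE6-gamma inhibitory binding site (306--310) and the
#' activated-rhodopsin binding sites (311--328, 340--350).
#'
#' @return A [domain_map()].
#' @export
gnat1_domain_map <- function() {
  read_domain_map(system.file("extdata", "gnat1_domains.json",
                              package = "triorecess", mustWork = TRUE))
}

#' Transcript model constructor
#'
#' Ordered coding-exon lengths (5' to 3') for one transcript. When
#' `protein_length` is supplied, the coding lengths must sum to
#' `3 * (protein_length + 1)` (CDS including the natural stop codon).
#'
#' @param exon_lengths Integer vector of coding-exon lengths in nt.
#' @param gene Gene symbol.
#' @param strand `"+"` or `"-"` (informational).
#' @param protein_length Optional cross-check.
#' @return List of class `transcript_model`.
#' @export
transcript_model <- function(exon_lengths, gene = "", strand = "+",
                             protein_length = NULL) {
  exon_lengths <- as.integer(exon_lengths)
  stopifnot(length(exon_lengths) >= 1, all(exon_lengths > 0))
  if (!is.null(protein_length))
    stopifnot(sum(exon_lengths) == 3L * (protein_length + 1L))
  structure(list(gene = gene, strand = strand,
                 exon_lengths = exon_lengths,
                 cds_length = sum(exon_lengths)),
            class = "transcript_model")
}

#' Synthetic GNAT1 coding-exon model
#'
#' An 8-coding-exon model of the 1053-nt GNAT1 CDS (350 residues plus the
#' stop codon). The interior exon boundaries are synthetic — the true
#' genomic split is not reproduced here — but the last coding exon starts at
#' c.877, so the two reported premature stops (c.904, c.963) both fall in
#' the last coding exon, as established for this gene; NMD verdicts are
#' therefore insensitive to the invented interior bounds.
#'
#' @return A [transcript_model()].
#' @export
gnat1_transcript <- function() {
  transcript_model(c(104L, 173L, 76L, 129L, 118L, 123L, 153L, 177L),
                   gene = "GNAT1", strand = "-", protein_length = 350L)
}

#' Truncation report for a stop-gain variant
#'
#' Composes [shortening()], [nmd_escape()] and [site_retention()] for a
#' stop-gain variant given its coding-sequence position.
#'
#' @param cds_pos 1-based CDS nucleotide position of the variant.
#' @param consequence Consequence class of the variant; anything other than
#'   `"nonsense"` yields `NULL` with a message.
#' @param transcript A [transcript_model()].
#' @param domain_map A [domain_map()].
#' @param config A [trio_config()] (NMD window, shortening convention).
#' @return List of class `truncation_report` with `stop_codon_position`,
#'   `shortening_aa`, `nmd_escape`, `site_status`; or `NULL` for
#'   non-stop-gain input.
#' @export
truncation_report <- function(cds_pos, consequence = "nonsense",
                              transcript, domain_map,
                              config = trio_config()) {
  if (!identical(consequence, "nonsense")) {
    message("not a stop-gain variant: no truncation report")
    return(NULL)
  }
  stopifnot(cds_pos >= 1, cds_pos <= transcript$cds_length)
  codon <- as.integer(ceiling(cds_pos / 3))
  codon_start_nt <- 3L * codon - 2L
  structure(list(
    gene = transcript$gene,
    protein = domain_map$protein,
    stop_codon_position = codon,
    shortening_aa = shortening(codon, domain_map$protein_length,
                               config$shortening_convention),
    nmd_escape = nmd_escape(codon_start_nt, transcript,
                            config$nmd_window_nt),
    site_status = site_retention(codon, domain_map)
  ), class = "truncation_report")
}

#' @export
print.truncation_report <- function(x, ...) {
  cat(sprintf("Truncation report: %s p.(%d*)\n", x$gene,
              x$stop_codon_position))
  cat(sprintf("  shortening: %d aa (of %s)\n", x$shortening_aa, x$protein))
  cat(sprintf("  NMD escape: %s\n", x$nmd_escape))
  st <- x$site_status
  for (nm in names(st)) cat(sprintf("  %-16s %s\n", nm, st[[nm]]))
  invisible(x)
}
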