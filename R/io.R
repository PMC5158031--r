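# File readers/writers for the pipeline's external formats:
# VCF 4.2 trio genotypes (INFO keys CSQCLASS, GENE, CDSPOS, AF_EVS,
# AF_HAPMAP, AF_1KG, AF_EXAC), BED3+N TSV depth tables, GFF3 transcripts.

INFO_FREQ_KEYS <- c(af_evs = "AF_EVS", af_hapmap = "AF_HAPMAP",
                    af_1kg = "AF_1KG", af_exac = "AF_EXAC")

# Map one VCF GT string to a genotype state; NA for unparsable.
parse_gt_string <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(g, "[/|]")[[1]]
  if (length(alleles) == 0 || !all(grepl("^[0-9.]+$", alleles)))
    return(NA_character_)
  if (any(alleles == ".")) return("missing")
  a <- as.integer(alleles)
  if (all(a == 0)) "hom_ref" else if (all(a > 0)) "hom_alt" else "het"
}

#' Read a trio VCF
#'
#' Reads a VCF with exactly the three mapped trio samples into a flat trio
#' table. Consequence class, gene, CDS position and per-database allele
#' frequencies are taken from the INFO keys `CSQCLASS`, `GENE`, `CDSPOS`,
#' `AF_EVS`, `AF_HAPMAP`, `AF_1KG`, `AF_EXAC`; an absent frequency key
#' becomes `NA` (unknown), never 0.
#'
#' @param path VCF file (plain or bgzipped).
#' @param role_map Named character vector mapping VCF sample names to roles;
#'   every sample column must be mapped, and the roles `proband`, `mother`,
#'   `father` must each occur exactly once.
#' @return Data frame sorted by (chromosome, position) with columns `chrom`,
#'   `pos`, `ref`, `alt`, `consequence`, `gene`, `cds_pos`, the four
#'   `af_*` columns, and `gt_proband`, `gt_mother`, `gt_father` (states
#'   `hom_ref`/`het`/`hom_alt`/`missing`; an unparsable genotype becomes
#'   `missing` with a warning).
#' @export
read_trio_vcf <- function(path,
                          role_map = c(proband = "proband",
                                       mother = "mother",
                                       father = "father")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  unmapped <- setdiff(samples, names(role_map))
  if (length(unmapped) > 0)
    stop("VCF sample(s) not in role_map: ", paste(unmapped, collapse = ", "))
  roles <- unname(role_map[samples])
  for (r in c("proband", "mother", "father")) {
    if (sum(roles == r) != 1)
      stop("role_map must assign role '", r, "' to exactly one VCF sample")
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  empty_states <- function() character(0)
  if (n == 0) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      consequence = character(0), gene = character(0),
                      cds_pos = numeric(0),
                      af_evs = numeric(0), af_hapmap = numeric(0),
                      af_1kg = numeric(0), af_exac = numeric(0),
                      gt_proband = empty_states(),
                      gt_mother = empty_states(),
                      gt_father = empty_states(),
                      stringsAsFactors = FALSE)
    return(out)
  }

  info_chr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else v
  }
  info_num <- function(key) suppressWarnings(as.numeric(info_chr(key)))

  consequence <- info_chr("CSQCLASS")
  consequence[is.na(consequence)] <- "other"
  gene <- info_chr("GENE")
  gene[is.na(gene)] <- ""

  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    consequence = consequence,
    gene = gene,
    cds_pos = info_num("CDSPOS"),
    stringsAsFactors = FALSE
  )
  for (col in names(INFO_FREQ_KEYS)) out[[col]] <- info_num(INFO_FREQ_KEYS[[col]])

  gt <- vcfR::extract.gt(vcf, element = "GT")
  n_bad <- 0L
  for (i in seq_along(samples)) {
    states <- vapply(gt[, i], parse_gt_string, character(1), USE.NAMES = FALSE)
    n_bad <- n_bad + sum(is.na(states))
    states[is.na(states)] <- "missing"
    out[[paste0("gt_", roles[i])]] <- states
  }
  if (n_bad > 0)
    warning(n_bad, " unparsable genotype call(s) set to missing")

  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a trio table as VCF 4.2
#'
#' Inverse of [read_trio_vcf()]: genotype states and annotations round-trip.
#'
#' @param trio Trio table.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(trio, path) {
  enc <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=triorecess",
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CDSPOS,Number=1,Type=Integer,Description="CDS position of the variant">',
    '##INFO=<ID=AF_EVS,Number=1,Type=Float,Description="Allele frequency, Exome Variant Server">',
    '##INFO=<ID=AF_HAPMAP,Number=1,Type=Float,Description="Allele frequency, HapMap">',
    '##INFO=<ID=AF_1KG,Number=1,Type=Float,Description="Allele frequency, 1000 Genomes">',
    '##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description="Allele frequency, ExAC">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "proband", "mother", "father", sep = "\t")
  )
  info <- vapply(seq_len(nrow(trio)), function(i) {
    parts <- c(paste0("CSQCLASS=", trio$consequence[i]))
    if (nzchar(trio$gene[i])) parts <- c(parts, paste0("GENE=", trio$gene[i]))
    if (!is.na(trio$cds_pos[i]))
      parts <- c(parts, paste0("CDSPOS=", format(trio$cds_pos[i],
                                                 scientific = FALSE)))
    for (col in names(INFO_FREQ_KEYS)) {
      v <- trio[[col]][i]
      if (!is.na(v))
        parts <- c(parts, paste0(INFO_FREQ_KEYS[[col]], "=",
                                 format(v, scientific = FALSE, digits = 10)))
    }
    paste(parts, collapse = ";")
  }, character(1))
  body <- paste(trio$chrom, format(trio$pos, scientific = FALSE, trim = TRUE),
                ".", trio$ref, trio$alt, ".", "PASS", info, "GT",
                enc[trio$gt_proband], enc[trio$gt_mother],
                enc[trio$gt_father], sep = "\t")
  writeLines(c(hdr, if (nrow(trio) > 0) body), path)
  invisible(path)
}

#' Read a BED-like depth table
#'
#' Tab-separated with a header: columns `chrom`, `start`, `end` (0-based
#' half-open) followed by one numeric depth column per sample; all samples
#' share the target list by construction of the format.
#'
#' @param path TSV file.
#' @return List with `targets` (data frame `chrom`, `start`, `end`) and
#'   `depths` (numeric matrix, targets x samples). An empty table returns
#'   zero-row components with a warning; duplicated target intervals or
#'   non-numeric depths are fatal.
#' @export
read_depth_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, fill = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4 || !identical(names(tab)[1:3], c("chrom", "start", "end")))
    stop("depth table must have columns chrom, start, end, then samples")
  targets <- tab[, 1:3]
  if (nrow(tab) == 0) {
    warning("empty depth table")
    return(list(targets = targets,
                depths = matrix(numeric(0), nrow = 0,
                                ncol = ncol(tab) - 3,
                                dimnames = list(NULL, names(tab)[-(1:3)]))))
  }
  key <- paste(targets$chrom, targets$start, targets$end)
  if (anyDuplicated(key)) stop("duplicated target interval in depth table")
  if (any(targets$end <= targets$start)) stop("invalid target interval")
  depths <- as.matrix(tab[, -(1:3), drop = FALSE])
  if (!is.numeric(depths) || anyNA(depths) || any(depths < 0))
    stop("depth columns must be non-negative numbers")
  list(targets = targets, depths = depths)
}

#' Write a BED-like depth table
#'
#' @param targets Data frame `chrom`, `start`, `end`.
#' @param depths Matrix, targets x samples, with sample column names.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(targets, depths, path) {
  stopifnot(nrow(targets) == nrow(depths))
  tab <- cbind(targets[, c("chrom", "start", "end")], as.data.frame(depths))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript coding-exon model from GFF3
#'
#' Imports the file with `rtracklayer`, keeps `CDS` features, orders them
#' along the transcript (reversed for minus strand) and returns a
#' [transcript_model()] of their lengths.
#'
#' @param path GFF3 file.
#' @return A [transcript_model()].
#' @export
read_transcript_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", path)
  strand <- as.character(GenomicRanges::strand(gr))[1]
  gr <- gr[order(GenomicRanges::start(gr))]
  lens <- GenomicRanges::width(gr)
  if (strand == "-") lens <- rev(lens)
  gene <- if (!is.null(gr$gene)) gr$gene[1] else ""
  transcript_model(lens, gene = gene, strand = strand)
}

#' Write a transcript model as GFF3
#'
#' Lays the ordered coding exons onto nominal genomic coordinates (2-kb
#' introns) and exports with `rtracklayer`.
#'
#' @param transcript A [transcript_model()].
#' @param path Output GFF3 path.
#' @param chrom Chromosome name to use.
#' @param offset Genomic start offset of the first exon.
#' @return `path`, invisibly.
#' @export
write_transcript_gff <- function(transcript, path, chrom = "3",
                                 offset = 50000000) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("writing GFF3 requires the rtracklayer package")
  lens <- transcript$exon_lengths
  if (transcript$strand == "-") lens <- rev(lens)
  starts <- offset + cumsum(c(0, head(lens, -1) + 2000))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts + 1, width = lens),
    strand = transcript$strand)
  gr$source <- "triorecess"
  gr$type <- "CDS"
  gr$gene <- transcript$gene
  phases <- cumsum(c(0, head(transcript$exon_lengths, -1))) %% 3
  gr$phase <- as.integer(if (transcript$strand == "-") rev(phases) else phases)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a population CNV frequency table
#'
#' TSV with header `chrom`, `start`, `end` (0-based half-open), `freq`
#' (empty/NA = unknown frequency).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_population_cnv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "freq") %in% names(tab)))
  tab
}
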