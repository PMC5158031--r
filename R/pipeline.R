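#' Run the full prioritization pipeline
#'
#' Composes every stage on files: reads the trio VCF, applies the
#' consequence/frequency cascade and both inheritance models, maps runs of
#' homozygosity in the proband (with the mother's heterozygosity as a
#' descriptive cross-check), screens the proband's depth profile for
#' copy-number changes against the reference pool, tallies
#' Mendelian-consistency and Y-marker statistics, and annotates stop-gain
#' candidates on the supplied transcript/domain model with a truncation
#' report. Deterministic given fixed inputs.
#'
#' @param vcf Path to the trio VCF.
#' @param depth Optional path to a BED-like depth table whose non-trio
#'   columns form the reference pool.
#' @param transcript Optional GFF3 transcript path or a
#'   [transcript_model()].
#' @param domains Optional domain-map JSON path or a [domain_map()].
#' @param population_cnv Optional population CNV table path or data frame.
#' @param config A [trio_config()].
#' @param role_map Sample-to-role map for [read_trio_vcf()].
#' @return List of class `candidate_report`: `candidates` (ranked data
#'   frame of variants surviving the proband-only model, with strict-trio
#'   tags, region containment and CNV overlap), `strict_candidates`,
#'   `regions` (large regions with maternal het fractions), `all_regions`,
#'   `cnv`, `qc`, `consistency`, `truncations`, `config`.
#' @export
run_pipeline <- function(vcf, depth = NULL, transcript = NULL,
                         domains = NULL, population_cnv = NULL,
                         config = trio_config(),
                         role_map = c(proband = "proband",
                                      mother = "mother",
                                      father = "father")) {
  trio <- read_trio_vcf(vcf, role_map)
  report_from_trio(trio, depth = depth, transcript = transcript,
                   domains = domains, population_cnv = population_cnv,
                   config = config)
}

#' Pipeline over an in-memory trio table
#'
#' Same composition as [run_pipeline()] for a trio table already in memory
#' (e.g. straight from [simulate_trio()]).
#'
#' @param trio Trio table.
#' @inheritParams run_pipeline
#' @param depth Optional list `list(targets =, depths =)` or a path.
#' @return A `candidate_report` (see [run_pipeline()]).
#' @export
report_from_trio <- function(trio, depth = NULL, transcript = NULL,
                             domains = NULL, population_cnv = NULL,
                             config = trio_config()) {
  if (is.character(transcript)) transcript <- read_transcript_gff(transcript)
  if (is.character(domains)) domains <- read_domain_map(domains)
  if (is.character(population_cnv))
    population_cnv <- read_population_cnv(population_cnv)

  fc <- filter_cascade(trio, config)

  auto <- fc[is_autosome(fc$chrom), , drop = FALSE]
  all_regions <- detect_runs(auto$chrom, auto$pos, auto$gt_proband,
                             config$roh_het_tolerance)
  regions <- filter_large_regions(all_regions, config$roh_min_length_mb)
  regions <- cross_sample_roh(regions, auto$chrom, auto$pos, auto$gt_mother)

  cnv <- NULL
  qc <- NULL
  if (!is.null(depth)) {
    if (is.character(depth)) depth <- read_depth_table(depth)
    pool_cols <- setdiff(colnames(depth$depths),
                         c("proband", "mother", "father"))
    stopifnot("proband" %in% colnames(depth$depths), length(pool_cols) >= 1)
    cnv <- cnv_screen(depth$depths[, "proband"],
                      depth$depths[, pool_cols, drop = FALSE],
                      depth$targets, population = population_cnv,
                      config = config)
    qc <- depth_qc_summary(depth$depths[, "proband"], depth$targets)
  }

  consistency <- consistency_summary(fc, config)

  cand <- fc[fc$pass & fc$model_proband != "none" & is_autosome(fc$chrom), ,
             drop = FALSE]
  ridx <- annotate_in_region(cand$chrom, cand$pos, regions)
  cand$in_roh <- !is.na(ridx)
  cand$roh_length_mb <- ifelse(is.na(ridx), NA_real_,
                               regions$length_mb[ridx])
  cand$cnv_overlap <- rep(FALSE, nrow(cand))
  if (!is.null(cnv) && nrow(cnv$calls) > 0 && nrow(cand) > 0) {
    gr_v <- GenomicRanges::GRanges(cand$chrom,
                                   IRanges::IRanges(cand$pos, cand$pos))
    gr_c <- GenomicRanges::GRanges(cnv$calls$chrom,
                                   IRanges::IRanges(cnv$calls$start + 1L,
                                                    cnv$calls$end))
    cand$cnv_overlap <- suppressWarnings(
      GenomicRanges::countOverlaps(gr_v, gr_c)) > 0
  }

  truncations <- list()
  if (!is.null(transcript) && !is.null(domains) && nrow(cand) > 0) {
    hit <- which(cand$consequence == "nonsense" &
                   cand$gene == transcript$gene & !is.na(cand$cds_pos))
    for (i in hit) {
      key <- paste0(cand$chrom[i], ":", cand$pos[i])
      truncations[[key]] <- truncation_report(
        cand$cds_pos[i], "nonsense", transcript, domains, config)
    }
  }

  if (nrow(cand) > 0) {
    min_freq <- apply(cand[, FREQ_COLUMNS, drop = FALSE], 1,
                      function(x) if (all(is.na(x))) Inf
                      else min(x, na.rm = TRUE))
    ord <- order(!cand$in_roh,
                 cand$model_proband != "hom_proband_only",
                 min_freq)
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
  }

  structure(list(
    candidates = cand,
    strict_candidates = fc[fc$pass & fc$model_trio != "none" &
                             is_autosome(fc$chrom), , drop = FALSE],
    regions = regions,
    all_regions = all_regions,
    cnv = cnv,
    qc = qc,
    consistency = consistency,
    truncations = truncations,
    config = config
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report\n")
  cat(sprintf("  strict trio-recessive candidates: %d\n",
              nrow(x$strict_candidates)))
  cat(sprintf("  proband-only candidates: %d (%d homozygous, %d compound het)\n",
              nrow(x$candidates),
              sum(x$candidates$model_proband == "hom_proband_only"),
              sum(x$candidates$model_proband == "comp_het_proband_only")))
  cat(sprintf("  large homozygous regions (> %.5g Mb): %d\n",
              x$config$roh_min_length_mb, nrow(x$regions)))
  if (!is.null(x$cnv))
    cat(sprintf("  CNV calls after common-variant exclusion: %d (pool correlation %.3f)\n",
                nrow(x$cnv$calls), x$cnv$correlation))
  cat(sprintf("  paternity questioned (advisory): %s\n",
              x$consistency$paternity_questioned))
  if (nrow(x$candidates) > 0) {
    top <- x$candidates[1, ]
    cat(sprintf("  top candidate: %s %s:%s %s (%s), in_roh=%s\n",
                top$gene, top$chrom, format(top$pos, scientific = FALSE),
                top$consequence, top$model_proband, top$in_roh))
  }
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' @param report A `candidate_report`.
#' @param path Output TSV for the candidate table.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  write.table(report$candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
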