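# Synthetic trio-WES generator with planted ground truth. Defaults emulate
# the scale of a real trio exome: ~50,000 autosomal sites (a published trio
# carried 54,125 SNVs plus ~4,000 indels), one multi-Mb autozygous segment
# carrying a homozygous nonsense variant, Y-chromosome markers, and
# per-target capture depths around 80x.

# Approximate autosome lengths in Mb (GRCh37 scale).
AUTOSOME_MB <- c(249.3, 243.2, 198.0, 191.2, 180.9, 171.1, 159.1, 146.4,
                 141.2, 135.5, 135.0, 133.9, 115.2, 107.3, 102.5, 90.4,
                 81.2, 78.1, 59.1, 63.0, 48.1, 51.3)
names(AUTOSOME_MB) <- as.character(1:22)

#' Simulation specification
#'
#' Declares everything the generator plants: the site map, allele-frequency
#' distribution, the autozygous (homozygous-by-descent) segment, the
#' homozygous nonsense variant inside it, the father mode, genotype error
#' rate, Y markers, and the depth model with planted copy-number changes.
#'
#' @param n_sites Autosomal variant sites.
#' @param beta_shape1,beta_shape2 Beta parameters of the per-site allele
#'   frequency distribution (defaults skew towards rare alleles, as variant
#'   tables do).
#' @param planted_roh List of segments, each
#'   `list(chrom =, start_mb =, length_mb =)`.
#' @param planted_variant `list(chrom =, pos =, gene =, cds_pos =, af_exac =)`
#'   — a homozygous nonsense variant; must lie inside a planted segment.
#' @param father_mode `"true_father"` or `"unrelated"`.
#' @param genotype_error_rate Per-call probability of replacing a genotype
#'   with one of the two other non-missing states (uniformly).
#' @param n_y_markers Y-chromosome markers carried in the trio table.
#' @param sites_per_gene Consecutive sites grouped into one synthetic gene
#'   (enables compound-heterozygous grouping).
#' @param db_alleles Effective number of alleles behind each annotation
#'   database: a variant is present in a database with probability
#'   `1 - (1 - f)^db_alleles`, so rare variants are often unknown (`NA`)
#'   while common ones are always annotated.
#' @param n_targets,target_length_bp,mean_depth Depth model: number of
#'   capture targets, their length, and the genome-wide mean depth.
#' @param depth_noise `"nbinom"` (default) or `"poisson"`. For the negative
#'   binomial, `dispersion` is the fractional extra-Poisson variance:
#'   `Var = mu * (1 + dispersion)`.
#' @param dispersion See `depth_noise`.
#' @param intensity_sdlog Log-sd of the shared lognormal per-target capture
#'   intensity profile (exome targets differ widely in capture efficiency).
#' @param intensity_min Lower truncation of the relative capture intensity:
#'   targets below it are assumed excluded by the panel's coverage QC.
#' @param n_pool Reference-pool samples for the CNV screen.
#' @param planted_cnv List of `list(target =, ratio =)` copy-ratio changes
#'   planted in the proband (0.5 = heterozygous deletion, 1.5 =
#'   heterozygous duplication).
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_sites = 50000,
                            beta_shape1 = 0.8,
                            beta_shape2 = 2,
                            planted_roh = list(list(chrom = "3",
                                                    start_mb = 40,
                                                    length_mb = 40)),
                            planted_variant = list(chrom = "3",
                                                   pos = 50200000,
                                                   gene = "GNAT1",
                                                   cds_pos = 963,
                                                   af_exac = 8.3e-06),
                            father_mode = c("true_father", "unrelated"),
                            genotype_error_rate = 1e-04,
                            n_y_markers = 10,
                            sites_per_gene = 8,
                            db_alleles = 2000,
                            n_targets = 200,
                            target_length_bp = 120,
                            mean_depth = 80,
                            depth_noise = c("nbinom", "poisson"),
                            dispersion = 0.05,
                            intensity_sdlog = 0.9,
                            intensity_min = 0.5,
                            n_pool = 10,
                            planted_cnv = list(),
                            seed = 1L) {
  father_mode <- match.arg(father_mode)
  depth_noise <- match.arg(depth_noise)
  stopifnot(n_sites > 0, beta_shape1 > 0, beta_shape2 > 0,
            genotype_error_rate >= 0, genotype_error_rate < 1,
            n_pool >= 1, mean_depth > 0, dispersion >= 0)
  for (r in planted_roh) {
    len <- AUTOSOME_MB[[as.character(r$chrom)]]
    if (is.null(len)) stop("planted ROH on unknown chromosome ", r$chrom)
    if (r$start_mb < 0 || r$start_mb + r$length_mb > len)
      stop("planted ROH overlaps the end of chromosome ", r$chrom)
  }
  if (!is.null(planted_variant)) {
    inside <- any(vapply(planted_roh, function(r) {
      r$chrom == planted_variant$chrom &&
        planted_variant$pos >= r$start_mb * 1e6 &&
        planted_variant$pos <= (r$start_mb + r$length_mb) * 1e6
    }, logical(1)))
    if (!inside) stop("planted variant must lie inside a planted ROH")
  }
  structure(as.list(environment()), class = "simulation_spec")
}

sample_other_state <- function(state, u) {
  # replace a state with one of the two other non-missing states, chosen
  # by a pre-drawn uniform in [0,1) (symmetric error model)
  others <- setdiff(c("hom_ref", "het", "hom_alt"), state)
  others[1 + (u >= 0.5)]
}

states_from_dosage <- function(d) {
  c("hom_ref", "het", "hom_alt")[d + 1L]
}

#' Simulate a trio genotype table with planted truth
#'
#' Parents are drawn from Hardy--Weinberg proportions at each site; the
#' child receives one transmitted haplotype from each parent, except inside
#' planted homozygous-by-descent segments where both child alleles are
#' copies of the transmitted maternal allele (and, in `true_father` mode,
#' the father's transmitted haplotype is forced to the same allele,
#' modelling shared ancestry, which preserves Mendelian closure). In
#' `unrelated` mode the observed father column is drawn independently of
#' the haplotypes actually transmitted to the child, and the Y-chromosome
#' haplotypes of father and son are independent. The planted nonsense
#' variant is written homozygous-alternate in the child with a carrier
#' mother. Genotype errors are then applied symmetrically at the configured
#' rate.
#'
#' @param spec A [simulation_spec()].
#' @return List with `trio` (trio table, autosomal sites then Y markers)
#'   and `truth` (per-site allele frequencies, error-free genotype states,
#'   the homozygous-by-descent indicator, the planted variant coordinates,
#'   and the spec) — sufficient to compute every expected stage output.
#' @export
simulate_trio <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  n <- spec$n_sites

  chrom_idx <- sample.int(22, n, replace = TRUE, prob = AUTOSOME_MB)
  chrom <- names(AUTOSOME_MB)[chrom_idx]
  pos <- floor(runif(n, 1, AUTOSOME_MB[chrom_idx] * 1e6))
  ord <- order(chrom_rank(chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  f <- pmin(pmax(rbeta(n, spec$beta_shape1, spec$beta_shape2), 1e-4), 0.9999)

  in_roh <- rep(FALSE, n)
  for (r in spec$planted_roh) {
    in_roh <- in_roh | (chrom == as.character(r$chrom) &
                          pos >= r$start_mb * 1e6 &
                          pos <= (r$start_mb + r$length_mb) * 1e6)
  }

  # maternal haplotypes and transmission
  a1 <- rbinom(n, 1, f); a2 <- rbinom(n, 1, f)
  mat_pick <- rbinom(n, 1, 0.5)
  m_allele <- ifelse(mat_pick == 1, a1, a2)

  # true (transmitting) father; the observed father column may differ
  t1 <- rbinom(n, 1, f); t2 <- rbinom(n, 1, f)
  pat_pick <- rbinom(n, 1, 0.5)
  p_allele <- ifelse(pat_pick == 1, t1, t2)

  # planted variant: overwrite the nearest same-chromosome site
  planted_i <- NA_integer_
  pv <- spec$planted_variant
  if (!is.null(pv)) {
    cand <- which(chrom == as.character(pv$chrom))
    planted_i <- cand[which.min(abs(pos[cand] - pv$pos))]
    pos[planted_i] <- pv$pos
    f[planted_i] <- pv$af_exac
    a1[planted_i] <- 1; a2[planted_i] <- 0; mat_pick[planted_i] <- 1
    m_allele[planted_i] <- 1
    t1[planted_i] <- 0; t2[planted_i] <- 0; p_allele[planted_i] <- 0
    # keep the map sorted in case the overwrite crossed a neighbour
    ord2 <- order(chrom_rank(chrom), pos)
    relabel <- function(x) x[ord2]
    chrom <- relabel(chrom); pos <- relabel(pos); f <- relabel(f)
    in_roh <- relabel(in_roh)
    a1 <- relabel(a1); a2 <- relabel(a2); mat_pick <- relabel(mat_pick)
    m_allele <- relabel(m_allele)
    t1 <- relabel(t1); t2 <- relabel(t2); p_allele <- relabel(p_allele)
    planted_i <- which(chrom == as.character(pv$chrom) & pos == pv$pos)[1]
  }

  # autozygosity: both child alleles copy the transmitted maternal allele;
  # in true-father mode the father's transmitted haplotype carries it too
  if (spec$father_mode == "true_father") {
    idx <- which(in_roh & pat_pick == 1); t1[idx] <- m_allele[idx]
    idx <- which(in_roh & pat_pick == 0); t2[idx] <- m_allele[idx]
    p_allele[in_roh] <- m_allele[in_roh]
  }
  child_dos <- ifelse(in_roh, 2L * m_allele, m_allele + p_allele)
  mother_dos <- a1 + a2
  father_dos <- if (spec$father_mode == "true_father") {
    t1 + t2
  } else {
    rbinom(n, 1, f) + rbinom(n, 1, f)
  }
  if (!is.null(pv)) {
    # observed father never carries the planted allele
    father_dos[planted_i] <- if (spec$father_mode == "true_father") 1L else 0L
    child_dos[planted_i] <- 2L
    mother_dos[planted_i] <- 1L
  }

  true_states <- list(proband = states_from_dosage(child_dos),
                      mother = states_from_dosage(mother_dos),
                      father = states_from_dosage(father_dos))

  # symmetric genotype errors
  observed <- true_states
  e <- spec$genotype_error_rate
  if (e > 0) {
    for (who in names(observed)) {
      hit <- which(runif(n) < e)
      if (length(hit) > 0) {
        u <- runif(length(hit))
        observed[[who]][hit] <- mapply(sample_other_state,
                                       observed[[who]][hit], u)
      }
    }
  }

  # annotations
  csq <- sample(CONSEQUENCE_CLASSES, n, replace = TRUE,
                prob = c(0.02, 0.30, 0.05, 0.05, 0.05, 0.53))
  gene <- paste0("G", chrom, "_",
                 ave(seq_len(n), chrom,
                     FUN = function(i) ceiling(seq_along(i) /
                                                 spec$sites_per_gene)))
  af <- matrix(rep(f, 4), ncol = 4,
               dimnames = list(NULL, FREQ_COLUMNS))
  # a database misses a variant it never sampled: rare sites are often
  # unknown, common sites are always annotated
  p_missing <- (1 - f)^spec$db_alleles
  af[matrix(runif(4 * n) < rep(p_missing, 4), ncol = 4)] <- NA_real_
  cds_pos <- rep(NA_real_, n)
  if (!is.null(pv)) {
    csq[planted_i] <- "nonsense"
    gene[planted_i] <- pv$gene
    af[planted_i, ] <- c(NA, NA, NA, pv$af_exac)
    cds_pos[planted_i] <- pv$cds_pos
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)

  trio <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     consequence = csq, gene = gene, cds_pos = cds_pos,
                     stringsAsFactors = FALSE)
  for (col in FREQ_COLUMNS) trio[[col]] <- af[, col]
  trio$gt_proband <- observed$proband
  trio$gt_mother <- observed$mother
  trio$gt_father <- observed$father

  # Y-chromosome markers (haploid, encoded hom_ref/hom_alt; mother missing)
  ny <- spec$n_y_markers
  if (ny > 0) {
    fy <- rbinom(ny, 1, 0.5)
    sy <- if (spec$father_mode == "true_father") fy else rbinom(ny, 1, 0.5)
    ytab <- data.frame(chrom = "Y", pos = 2650000 + seq_len(ny) * 100000,
                       ref = "A", alt = "G", consequence = "other",
                       gene = "", cds_pos = NA_real_,
                       stringsAsFactors = FALSE)
    for (col in FREQ_COLUMNS) ytab[[col]] <- NA_real_
    ytab$gt_proband <- ifelse(sy == 1, "hom_alt", "hom_ref")
    ytab$gt_mother <- "missing"
    ytab$gt_father <- ifelse(fy == 1, "hom_alt", "hom_ref")
    trio <- rbind(trio, ytab)
  }
  rownames(trio) <- NULL

  truth <- list(allele_freq = f, in_roh = in_roh,
                true_states = true_states,
                planted_index = planted_i,
                planted_variant = pv,
                spec = spec)
  list(trio = trio, truth = truth)
}

#' Simulate per-target capture depths with planted copy-number changes
#'
#' All samples (trio plus reference pool) share one lognormal per-target
#' capture-intensity profile and an individual library-size factor; counts
#' are drawn per target from the configured noise model around
#' `mean_depth * intensity * copy_ratio`. Planted copy-ratio changes apply
#' to the proband only; pool samples are diploid throughout, so at default
#' noise the pool satisfies the Pearson correlation gate.
#'
#' @param spec A [simulation_spec()].
#' @return List with `targets` (chrom/start/end), `depths` (matrix, targets
#'   x samples: `proband`, `mother`, `father`, `pool01`...), and `truth`
#'   (per-target true copy ratio of the proband, the intensity profile, and
#'   the spec).
#' @export
simulate_depth <- function(spec = simulation_spec()) {
  set.seed(spec$seed + 1L)
  nt <- spec$n_targets
  targets <- data.frame(
    chrom = "1",
    start = seq_len(nt) * 2000L,
    end = seq_len(nt) * 2000L + spec$target_length_bp,
    stringsAsFactors = FALSE
  )
  # lognormal capture intensity truncated below: emulates targets that
  # passed coverage QC (a real design drops persistently weak targets)
  p0 <- stats::plnorm(spec$intensity_min, 0, spec$intensity_sdlog)
  intensity <- stats::qlnorm(runif(nt, p0, 1), 0, spec$intensity_sdlog)
  intensity <- intensity / mean(intensity)

  ratio <- rep(1, nt)
  for (cnv in spec$planted_cnv) ratio[cnv$target] <- cnv$ratio

  samples <- c("proband", "mother", "father",
               sprintf("pool%02d", seq_len(spec$n_pool)))
  libsize <- rlnorm(length(samples), 0, 0.1)
  depths <- matrix(0, nt, length(samples),
                   dimnames = list(NULL, samples))
  draw <- function(mu) {
    if (spec$depth_noise == "poisson" || spec$dispersion == 0) {
      rpois(length(mu), mu)
    } else {
      # Var = mu * (1 + dispersion): NB with size = mu / dispersion
      rnbinom(length(mu), mu = mu, size = mu / spec$dispersion)
    }
  }
  for (j in seq_along(samples)) {
    r <- if (samples[j] == "proband") ratio else rep(1, nt)
    depths[, j] <- draw(spec$mean_depth * intensity * r * libsize[j])
  }
  list(targets = targets, depths = depths,
       truth = list(copy_ratio = ratio, intensity = intensity, spec = spec))
}

#' Write all simulated inputs to a directory
#'
#' Writes `trio.vcf`, `depth.tsv`, `transcript.gff3` (requires rtracklayer),
#' `domains.json`, `population_cnv.tsv` (empty template) and truth tables
#' (`truth_sites.tsv`, `truth_cnv.tsv`).
#'
#' @param sim Output of [simulate_trio()].
#' @param depth_sim Output of [simulate_depth()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, depth_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trio_vcf(sim$trio, file.path(dir, "trio.vcf"))
  write_depth_table(depth_sim$targets, depth_sim$depths,
                    file.path(dir, "depth.tsv"))
  write_transcript_gff(gnat1_transcript(), file.path(dir, "transcript.gff3"))
  file.copy(system.file("extdata", "gnat1_domains.json",
                        package = "triorecess", mustWork = TRUE),
            file.path(dir, "domains.json"), overwrite = TRUE)
  write.table(data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), freq = numeric(0)),
              file.path(dir, "population_cnv.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_auto <- length(sim$truth$allele_freq)
  truth_sites <- data.frame(
    chrom = sim$trio$chrom[seq_len(n_auto)],
    pos = sim$trio$pos[seq_len(n_auto)],
    allele_freq = sim$truth$allele_freq,
    in_roh = sim$truth$in_roh,
    true_proband = sim$truth$true_states$proband,
    true_mother = sim$truth$true_states$mother,
    true_father = sim$truth$true_states$father)
  write.table(truth_sites, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_cnv <- cbind(depth_sim$targets,
                     copy_ratio = depth_sim$truth$copy_ratio)
  write.table(truth_cnv, file.path(dir, "truth_cnv.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
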