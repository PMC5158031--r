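test_that("run detection on toy chromosomes matches enumeration", {
  # all heterozygous: no regions
  r <- detect_runs(rep("1", 5), 1:5 * 1e6, rep("het", 5))
  expect_equal(nrow(r), 0)

  # H H H E H H at 1..6 Mb, tolerance 0: two runs [1-3] and [5-6] Mb
  st <- c("hom_ref", "hom_alt", "hom_ref", "het", "hom_alt", "hom_alt")
  r <- detect_runs(rep("1", 6), 1:6 * 1e6, st, het_tolerance = 0)
  expect_equal(r$start_pos, c(1e6, 5e6))
  expect_equal(r$end_pos, c(3e6, 6e6))
  expect_equal(r$length_mb, c(2, 1))
  expect_equal(r$n_markers, c(3L, 2L))

  # with tolerance 1 the embedded het is absorbed into one maximal run
  r1 <- detect_runs(rep("1", 6), 1:6 * 1e6, st, het_tolerance = 1)
  expect_equal(r1$start_pos, 1e6)
  expect_equal(r1$end_pos, 6e6)
  expect_equal(r1$n_het, 1L)

  # unsorted input is fatal
  expect_error(detect_runs(rep("1", 3), c(2, 1, 3) * 1e6,
                           rep("hom_ref", 3)), "sorted")
})

test_that("runs never span chromosomes and ignore missing calls", {
  chrom <- c("1", "1", "1", "2", "2")
  st <- rep("hom_ref", 5)
  r <- detect_runs(chrom, c(1, 2, 3, 1, 2) * 1e6, st)
  expect_equal(nrow(r), 2)
  expect_equal(r$chrom, c("1", "2"))

  # inserting missing markers anywhere changes nothing
  set.seed(41)
  base_st <- sample(c("hom_ref", "hom_alt", "het"), 30, TRUE,
                    prob = c(5, 4, 2))
  base_pos <- sort(sample(1:1000, 30)) * 1e4
  r0 <- detect_runs(rep("1", 30), base_pos, base_st)
  ins_pos <- sort(c(base_pos, setdiff(sample(1:1000, 10), base_pos / 1e4) * 1e4))
  ins_st <- ifelse(ins_pos %in% base_pos,
                   base_st[match(ins_pos, base_pos)], "missing")
  r1 <- detect_runs(rep("1", length(ins_pos)), ins_pos, ins_st)
  expect_equal(r1, r0)
})

test_that("every interior homozygous marker is covered by some run", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 80
    pos <- sort(sample(1:5000, n)) * 1e3
    st <- sample(c("hom_ref", "hom_alt", "het", "missing"), n, TRUE,
                 prob = c(5, 4, 2, 1))
    r <- detect_runs(rep("1", n), pos, st)
    obs <- which(st != "missing")
    hom <- st[obs] %in% c("hom_ref", "hom_alt")
    interior <- which(hom & c(FALSE, head(hom, -1)) &
                        c(tail(hom, -1), FALSE))
    for (i in interior) {
      p <- pos[obs[i]]
      expect_true(any(r$start_pos <= p & r$end_pos >= p))
    }
  }
})

test_that("run finder matches the exhaustive oracle", {
  set.seed(43)
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    pos <- sort(sample(1:10000, n)) * 1e3
    st <- sample(c("hom_ref", "hom_alt", "het", "missing"), n, TRUE,
                 prob = c(4, 3, 2, 1))
    k <- sample(0:2, 1)
    got <- detect_runs(rep("1", n), pos, st, het_tolerance = k)
    want <- oracle_runs(rep("1", n), pos, st, k)
    expect_equal(got[, c("chrom", "start_pos", "end_pos")], want,
                 ignore_attr = TRUE)
  }
})

test_that("large-region filter is strict, as in 'more than 30 Mb'", {
  regions <- data.frame(chrom = "1", start_pos = 0,
                        end_pos = c(5, 29, 30, 31, 43.6, 60) * 1e6)
  regions$length_mb <- (regions$end_pos - regions$start_pos) / 1e6
  kept <- filter_large_regions(regions, 30)
  expect_equal(kept$length_mb, c(31, 43.6, 60)) # exactly 30.0 is dropped
})

test_that("variant-in-region annotation matches exhaustive containment", {
  regions <- data.frame(chrom = c("1", "1", "2"),
                        start_pos = c(10, 100, 50) * 1e6,
                        end_pos = c(20, 150, 90) * 1e6)
  expect_equal(annotate_in_region("1", 15e6, regions), 1L)
  expect_equal(annotate_in_region("3", 15e6, regions), NA_integer_)
  expect_equal(annotate_in_region(c("1", "2"), c(100e6, 60e6), regions),
               c(2L, 3L))

  set.seed(44)
  for (rep in 1:20) {
    nr <- 5
    regions <- data.frame(chrom = sample(c("1", "2"), nr, TRUE),
                          start_pos = sample(1:100, nr) * 1e6)
    regions$end_pos <- regions$start_pos + sample(1:30, nr) * 1e6
    chrom <- sample(c("1", "2", "3"), 20, TRUE)
    pos <- sample(1:130, 20) * 1e6
    # oracle picks the first containing region, as does the annotation
    expect_equal(annotate_in_region(chrom, pos, regions),
                 oracle_containment(chrom, pos, regions))
  }
})

test_that("a planted autozygous segment is recovered at its full span", {
  spec <- simulation_spec(
    n_sites = 20000, seed = 8, genotype_error_rate = 0,
    planted_roh = list(list(chrom = "3", start_mb = 40, length_mb = 43.6)),
    planted_variant = list(chrom = "3", pos = 50200000, gene = "GNAT1",
                           cds_pos = 963, af_exac = 8.3e-06))
  sim <- simulate_trio(spec)
  auto <- sim$trio[is_autosome(sim$trio$chrom), ]
  runs <- detect_runs(auto$chrom, auto$pos, auto$gt_proband)
  large <- filter_large_regions(runs, 30)
  expect_equal(nrow(large), 1)
  expect_equal(large$chrom, "3")
  # boundaries within one marker spacing of the planted segment
  on3 <- auto$pos[auto$chrom == "3"]
  spacing <- max(diff(sort(on3)))
  expect_lt(abs(large$start_pos - 40e6), spacing)
  expect_lt(abs(large$end_pos - 83.6e6), spacing)
  expect_gt(large$length_mb, 40)

  # the planted variant localizes inside it
  idx <- annotate_in_region("3", 50200000, large)
  expect_equal(idx, 1L)
})

test_that("a carrier mother stays heterozygous across the child's segment", {
  spec <- simulation_spec(n_sites = 20000, seed = 9,
                          genotype_error_rate = 0)
  sim <- simulate_trio(spec)
  auto <- sim$trio[is_autosome(sim$trio$chrom), ]
  runs <- filter_large_regions(
    detect_runs(auto$chrom, auto$pos, auto$gt_proband), 30)
  ann <- cross_sample_roh(runs, auto$chrom, auto$pos, auto$gt_mother)
  expect_equal(nrow(ann), 1)
  # inside an identical-by-descent segment the mother's het rate is the
  # population rate; check against the generator's truth with a 95% band
  f <- sim$truth$allele_freq[sim$truth$in_roh]
  p <- mean(2 * f * (1 - f))
  n <- ann$mother_n_markers
  expect_gt(n, 100)
  expect_lt(abs(ann$mother_het_fraction - p), 2 * sqrt(p * (1 - p) / n))

  # all-missing mother inside the span: fraction undefined
  ann2 <- cross_sample_roh(runs, "3", 50e6, "missing")
  expect_true(is.na(ann2$mother_het_fraction))
})
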