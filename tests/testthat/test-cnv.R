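test_that("correlation gate validates self-comparison and rejects noise", {
  d <- c(80, 120, 60, 100, 90)
  self <- reference_correlation(d, matrix(d, ncol = 1))
  expect_equal(self$correlation, 1.0)
  expect_true(self$valid)

  # noise scaled so the directly computed correlation sits below the gate
  set.seed(21)
  pool <- matrix(rep(rlnorm(200, log(80), 0.6), 5), ncol = 5)
  pool <- pool * matrix(rlnorm(1000, 0, 0.02), ncol = 5)
  # direct computation of the definition: per-target median of the
  # library-size-normalized pool
  med <- apply(sweep(pool, 2, colSums(pool), "/"), 1, median)
  noisy <- med * rlnorm(200, 0, 0.34)
  r_direct <- cor(noisy, med)
  expect_lt(r_direct, 0.97)
  gate <- reference_correlation(noisy, pool)
  expect_equal(gate$correlation, r_direct)
  expect_false(gate$valid)

  # zero-variance sample: undefined correlation, invalid comparison
  flat <- reference_correlation(rep(50, 200), pool)
  expect_true(is.na(flat$correlation))
  expect_false(flat$valid)
})

test_that("copy score is the double-normalized depth ratio", {
  med <- c(100, 50, 200, 80)
  pool <- matrix(rep(med, 3), ncol = 3)
  expect_equal(copy_score(med, pool), rep(1, 4))

  # one target at half the normalized reference depth scores 0.5
  sample2 <- med * c(1, 1, 1, 0.5)
  sc <- copy_score(sample2, pool)
  expect_equal(sc[4] / sc[1], 0.5, tolerance = 1e-12)

  # scale invariance: library size cancels
  expect_equal(copy_score(sample2 * 7.3, pool), sc)

  # zero pool median target: undefined score with a warning
  pool0 <- pool; pool0[2, ] <- 0
  expect_warning(s0 <- copy_score(med, pool0), "zero pool median")
  expect_true(is.na(s0[2]))
  expect_false(anyNA(s0[-2]))
})

test_that("threshold caller flags exactly the inclusive-threshold targets", {
  targets <- data.frame(chrom = "1", start = c(0, 100, 200),
                        end = c(100, 200, 300))
  calls <- call_cnv(c(0.4, 1.0, 1.6), targets)
  expect_equal(calls$call, c("deletion", "duplication"))
  expect_equal(calls$target_index, c(1L, 3L))

  # boundary: score exactly 0.5 is a suspected deletion
  expect_equal(call_cnv(0.5, targets[1, ])$call, "deletion")
  expect_equal(call_cnv(1.5, targets[1, ])$call, "duplication")
  # everything strictly inside (0.5, 1.5): no calls
  expect_equal(nrow(call_cnv(c(0.51, 1.0, 1.49), targets)), 0)
})

test_that("caller matches the elementwise oracle on random scores", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(1:200, 1)
    scores <- c(runif(n - 1, 0, 2), NA)[sample.int(n)]
    targets <- data.frame(chrom = "1", start = (seq_len(n) - 1) * 100,
                          end = seq_len(n) * 100)
    calls <- call_cnv(scores, targets)
    oracle <- oracle_cnv_calls(scores, 0.5, 1.5)
    expect_equal(calls$target_index, which(!is.na(oracle)))
    expect_equal(calls$call, oracle[!is.na(oracle)])
  }
})

test_that("common-CNV exclusion removes only known-common overlaps", {
  calls <- data.frame(chrom = "1", start = c(0, 500, 1000),
                      end = c(100, 600, 1100),
                      target_index = 1:3, score = c(0.4, 0.3, 1.7),
                      call = c("deletion", "deletion", "duplication"))
  pop <- data.frame(chrom = "1", start = c(50, 550, 1050),
                    end = c(80, 580, 1080), freq = c(0.01, 0.001, NA))
  kept <- filter_common_cnv(calls, pop)
  # 1% overlap removed; 0.1% and unknown-frequency overlaps retained
  expect_equal(kept$target_index, c(2L, 3L))

  set.seed(23)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    calls <- data.frame(chrom = sample(c("1", "2"), n, TRUE),
                        start = sample(0:1000, n), target_index = seq_len(n),
                        score = runif(n, 0, 2), call = "deletion")
    calls$end <- calls$start + sample(50:200, n, TRUE)
    pop <- data.frame(chrom = sample(c("1", "2"), 3, TRUE),
                      start = sample(0:1000, 3),
                      freq = c(runif(2, 0, 0.02), NA))
    pop$end <- pop$start + sample(50:300, 3, TRUE)
    expect_equal(filter_common_cnv(calls, pop)$target_index,
                 oracle_common_filter(calls, pop, 0.005)$target_index)
  }
})

test_that("depth QC summary is length-weighted", {
  targets <- data.frame(chrom = "1", start = c(0, 100), end = c(100, 200))
  qc <- depth_qc_summary(c(5, 30), targets)
  expect_equal(unname(qc$fraction_at), c(0.5, 0.5))
  expect_equal(qc$mean_depth, 17.5)

  qc82 <- depth_qc_summary(rep(82, 5),
                           data.frame(chrom = "1", start = 0:4 * 10,
                                      end = 0:4 * 10 + 7))
  expect_equal(unname(qc82$fraction_at), c(1, 1))
  expect_equal(qc82$mean_depth, 82)

  expect_warning(qc0 <- depth_qc_summary(numeric(0),
                                         data.frame(chrom = character(0),
                                                    start = integer(0),
                                                    end = integer(0))),
                 "empty")
  expect_true(is.na(qc0$mean_depth))

  # seeded profile equals a brute-force per-base recount
  set.seed(24)
  n <- 1000
  targets <- data.frame(chrom = "1", start = (seq_len(n) - 1) * 500)
  targets$end <- targets$start + sample(50:250, n, TRUE)
  depths <- rpois(n, 80)
  qc <- depth_qc_summary(depths, targets, thresholds = c(10, 25))
  oracle <- oracle_qc(depths, targets, c(10, 25))
  expect_equal(unname(qc$fraction_at), oracle$fraction_at)
  expect_equal(qc$mean_depth, oracle$mean_depth)
})

test_that("a planted heterozygous deletion scores near 0.5 in noisy data", {
  scores_at <- function(seed) {
    d <- simulate_depth(simulation_spec(
      seed = seed, planted_cnv = list(list(target = 101, ratio = 0.5))))
    pool <- d$depths[, grep("pool", colnames(d$depths))]
    copy_score(d$depths[, "proband"], pool)
  }
  for (seed in 31:35) {
    sc <- scores_at(seed)
    expect_gt(sc[101], 0.3)
    expect_lt(sc[101], 0.7)
    expect_gt(median(sc), 0.95)
    expect_lt(median(sc), 1.05)
  }
})
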