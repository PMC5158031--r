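test_that("consequence gate keeps damaging classes only", {
  expect_true(consequence_filter("nonsense"))
  expect_true(consequence_filter("small_deletion"))
  expect_false(consequence_filter("other"))
  expect_equal(consequence_filter(c("missense", "other", "splice_site",
                                    "small_insertion")),
               c(TRUE, FALSE, TRUE, TRUE))
  expect_error(consequence_filter("synonymous"), "unknown consequence")
})

test_that("MAF gate is inclusive and unknown frequencies pass", {
  expect_true(maf_filter(c(exac = 0.0000083), 0.005))
  expect_false(maf_filter(c(kg = 0.01), 0.005))
  expect_true(maf_filter(c(a = NA, b = NA), 0.005))
  expect_true(maf_filter(c(a = 0.005), 0.005)) # boundary passes, as printed

  # 10-variant toy table: frequencies evaluated one by one against the
  # inclusive bound; 4 values pass plus the unknown = 5
  freqs <- c(0, 0.001, 0.004, 0.005, 0.0051, 0.01, 0.05, 0.1, 0.5, NA)
  expected <- vapply(freqs, function(f) is.na(f) || f <= 0.005, logical(1))
  expect_equal(sum(expected), 5)
  expect_equal(maf_filter(matrix(freqs, ncol = 1), 0.005), expected)
})

test_that("strict trio model requires hom_alt child with two carrier parents", {
  expect_equal(tag_inheritance_trio(make_trio("hom_alt", "het", "het")),
               "recessive_hom_trio")
  # the motivating failure: allele absent in the father
  expect_equal(tag_inheritance_trio(make_trio("hom_alt", "het", "hom_ref")),
               "none")
  expect_equal(tag_inheritance_trio(make_trio("het", "het", "het")), "none")
  # missing parent is non-disqualifying by default, disqualifying when not
  t_miss <- make_trio("hom_alt", "het", "missing")
  expect_equal(tag_inheritance_trio(t_miss, missing_ok = TRUE),
               "recessive_hom_trio")
  expect_equal(tag_inheritance_trio(t_miss, missing_ok = FALSE), "none")
})

test_that("trio compound heterozygotes need one allele from each parent", {
  trio <- make_trio(gt_p = c("het", "het"),
                    gt_m = c("het", "hom_ref"),
                    gt_f = c("hom_ref", "het"),
                    gene = "GENE1")
  expect_equal(tag_inheritance_trio(trio),
               c("compound_het_trio", "compound_het_trio"))
  # both from the mother: cis-compatible, not compound het
  cis <- make_trio(gt_p = c("het", "het"),
                   gt_m = c("het", "het"),
                   gt_f = c("hom_ref", "hom_ref"),
                   gene = "GENE1")
  expect_equal(tag_inheritance_trio(cis), c("none", "none"))
  # different genes never pair
  tg <- make_trio(gt_p = c("het", "het"),
                  gt_m = c("het", "hom_ref"),
                  gt_f = c("hom_ref", "het"),
                  gene = c("GENE1", "GENE2"))
  expect_equal(tag_inheritance_trio(tg), c("none", "none"))
})

test_that("proband-only fallback ignores parental genotypes", {
  expect_equal(tag_inheritance_proband_only(
    make_trio("hom_alt", "het", "hom_ref")), "hom_proband_only")
  expect_equal(tag_inheritance_proband_only(
    make_trio("het", "hom_ref", "hom_ref", gene = "G1")), "none")
  pair <- make_trio(gt_p = c("het", "het"), gt_m = c("het", "het"),
                    gt_f = c("hom_ref", "hom_ref"), gene = "G1")
  expect_equal(tag_inheritance_proband_only(pair),
               c("comp_het_proband_only", "comp_het_proband_only"))
})

test_that("a planted panel yields the planted survivor counts", {
  # 1000-variant panel: 35 planted proband-homozygous survivors and five
  # genes with a planted heterozygous pair (10 variants), everything else
  # failing a gate or carrying a non-recessive genotype
  set.seed(42)
  n <- 1000
  trio <- random_trio(n, n_genes = 400)
  trio$gene <- sprintf("BG%04d", seq_len(n)) # background: no accidental pairs
  trio$gt_proband <- sample(c("hom_ref", "het"), n, TRUE)
  trio$consequence <- "other" # background fails the consequence gate
  hom_idx <- 1:35
  trio$consequence[hom_idx] <- "missense"
  trio[hom_idx, c("af_evs", "af_hapmap", "af_1kg", "af_exac")] <- 0.001
  trio$gt_proband[hom_idx] <- "hom_alt"
  pair_idx <- 36:45
  trio$consequence[pair_idx] <- "missense"
  trio[pair_idx, c("af_evs", "af_hapmap", "af_1kg", "af_exac")] <- 0.0001
  trio$gt_proband[pair_idx] <- "het"
  trio$gene[pair_idx] <- rep(sprintf("CH%d", 1:5), each = 2)

  fc <- filter_cascade(trio)
  expect_equal(sum(fc$model_proband == "hom_proband_only"), 35)
  expect_equal(sum(fc$model_proband == "comp_het_proband_only"), 10)
})

test_that("lowering the MAF threshold never grows the surviving set", {
  set.seed(11)
  for (rep in 1:20) {
    trio <- random_trio(40)
    thresholds <- sort(runif(4, 0, 0.2))
    prev <- NULL
    for (th in rev(thresholds)) { # decreasing
      surv <- which(consequence_filter(trio$consequence) &
                      maf_filter(trio[, c("af_evs", "af_hapmap",
                                          "af_1kg", "af_exac")], th))
      if (!is.null(prev)) expect_true(all(surv %in% prev))
      prev <- surv
    }
  }
})

test_that("strict-trio homozygous candidates are proband-only candidates", {
  set.seed(12)
  for (rep in 1:20) {
    fc <- filter_cascade(random_trio(60))
    strict <- which(fc$model_trio == "recessive_hom_trio")
    fallback <- which(fc$model_proband == "hom_proband_only")
    expect_true(all(strict %in% fallback))
  }
})

test_that("cascade matches the brute-force evaluation of its definitions", {
  set.seed(13)
  for (rep in 1:25) {
    trio <- random_trio(sample(1:50, 1))
    th <- sample(c(0.005, 0.01, 0.1), 1)
    fc <- filter_cascade(trio, trio_config(maf_threshold = th))
    expect_equal(fc$pass, oracle_cascade_pass(trio, th))
  }
})
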