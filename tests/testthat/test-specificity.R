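test_that("module score is zero for constant data and linear in a shift", {
  set.seed(20)
  n <- 40; g <- 60
  # all genes identical constant expression -> every score 0
  const <- toy_norm(matrix(2, n, g))
  sc <- score_module(const, colnames(const$values)[1:5], n_bins = 1,
                     n_ctrl = 30, seed = 1)
  expect_equal(unname(sc$score), rep(0, n))
  # shifting signature genes by c moves every score by exactly c
  vals <- matrix(abs(rnorm(n * g)), n, g)
  norm <- toy_norm(vals)
  sig <- norm$gene_symbols[1:5]
  sc1 <- score_module(norm, sig, n_bins = 1, n_ctrl = 50, seed = 2)
  shifted <- vals
  shifted[, 1:5] <- shifted[, 1:5] + 0.7
  sc2 <- score_module(toy_norm(shifted), sig, n_bins = 1, n_ctrl = 50,
                      seed = 2)
  expect_equal(sc2$score, sc1$score + 0.7, tolerance = 1e-10)
  # deterministic for a fixed seed; absent genes dropped with warning
  sc3 <- score_module(norm, sig, n_bins = 1, n_ctrl = 50, seed = 2)
  expect_identical(sc1$score, sc3$score)
  expect_warning(score_module(norm, c(sig, "NOPE"), n_bins = 1, seed = 1),
                 "absent")
  expect_error(score_module(norm, c("NOPE"), seed = 1), "none")
})

test_that("AUC equals brute-force pair counting and behaves at extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6),
                       c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  # perfectly separated -> 1; all tied -> 0.5
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "nonempty")
  # oracle equivalence and the complement identity, n <= 50
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    expect_equal(roc_auc(s, lab), pairwise_auc(s, lab), tolerance = 1e-12)
    tie_free <- rank(s, ties.method = "random") / n
    expect_equal(roc_auc(tie_free, lab) + roc_auc(-tie_free, lab), 1,
                 tolerance = 1e-12)
  }
})

test_that("log2FC profiles agree with cluster_marker_stats exactly", {
  set.seed(22)
  vals <- matrix(abs(rnorm(200 * 30)), 200, 30)
  vals[1:50, 1:5] <- vals[1:50, 1:5] + 2
  norm <- toy_norm(vals)
  lab <- stats::setNames(rep(c("hot", "cold", "warm", "cool"), each = 50),
                         norm$barcodes)
  prof <- log2fc_profiles(norm, lab)
  st <- cluster_marker_stats(norm, lab, "hot")
  expect_equal(unname(prof[["hot"]]), st$avg_log2FC, tolerance = 1e-12)
  # two identical clusters -> log2FC ~ 0
  same <- toy_norm(matrix(rep(abs(rnorm(30)), each = 100), 100, 30))
  lab2 <- stats::setNames(rep(c("x", "y"), 50), same$barcodes)
  expect_true(all(abs(log2fc_profiles(same, lab2)[["x"]]) < 1e-12))
  expect_error(log2fc_profiles(norm, stats::setNames(rep("z", 200),
                                                     norm$barcodes)),
               "2 clusters")
})

test_that("profile Spearman correlation matches hand-ranked values", {
  sig <- paste0("g", 1:5)
  a <- stats::setNames(c(1, 2, 3, 4, 5), sig)
  b <- stats::setNames(c(3, 1, 2, 5, 4), sig)
  expect_equal(profile_correlation(a, b, sig), 0.6, tolerance = 1e-12)
  expect_equal(profile_correlation(a, a, sig), 1)
  expect_equal(profile_correlation(a, rev(stats::setNames(a, rev(sig))),
                                   sig), -1)
  # pairwise dropping with warning; error below 3 shared genes
  b_short <- b[1:4]
  expect_warning(r <- profile_correlation(a, b_short, sig), "dropped")
  expect_equal(r, cor(1:4, c(3, 1, 2, 5)[1:4], method = "spearman"))
  expect_error(suppressWarnings(profile_correlation(a, b[1:2], sig)),
               "fewer than 3")
})

test_that("specificity margin implements the printed-value convention", {
  rho <- c(BAT = 0.8, ZF = 0.4, ZG = 0.4, medulla = 0.4, CTWAT = -0.8)
  expect_equal(specificity_margin(rho, "BAT"), 0.4)
  expect_equal(specificity_margin(c(a = 0.5, b = 0.5), "a"), 0)
  expect_lt(specificity_margin(rho, "ZF"), 0)       # not maximal
  expect_error(specificity_margin(c(a = 1), "a"), "2 clusters")
  expect_error(specificity_margin(rho, "nope"), "not in")
})

test_that("permutation test: formula, monotonicity, determinism", {
  genes <- paste0("g", 1:100)
  set.seed(23)
  ref <- stats::setNames(rnorm(100), genes)
  tgt <- stats::setNames(rnorm(100), genes)
  pt <- permutation_test(ref, tgt, observed_rho = 2, set_size = 10,
                         n_perm = 200, seed = 5)
  expect_equal(pt$empirical_p, 0)          # rho cannot reach 2
  pt_lo <- permutation_test(ref, tgt, observed_rho = -2, set_size = 10,
                            n_perm = 200, seed = 5)
  expect_equal(pt_lo$empirical_p, 1)       # observed below all permutations
  expect_length(pt$perm_rhos, 200)
  expect_identical(pt$perm_rhos,
                   permutation_test(ref, tgt, 2, 10, 200, seed = 5)$perm_rhos)
  # p is k/n on the grid and monotone non-increasing in the observed value
  obs <- seq(-1, 1, length.out = 9)
  ps <- vapply(obs, function(o) empirical_p(pt$perm_rhos, o), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(abs(ps * 200 - round(ps * 200)) < 1e-9))
  # add-one estimator and background checks
  expect_equal(empirical_p(c(0.1, 0.5, 0.9), 0.6, add_one = TRUE), 2 / 4)
  expect_error(permutation_test(ref[1:5], tgt[1:5], 0.5, set_size = 10,
                                n_perm = 10), "smaller than set_size")
})

test_that("the full specificity analysis flags the planted cluster", {
  sim <- simulate_two_species(tiny_sim_config(seed = 24))
  na <- log_normalize(filter_genes_min_fraction(
    filter_spots_in_tissue(sim$a)))
  nb <- log_normalize(apply_ortholog_map(
    filter_genes_min_fraction(filter_spots_in_tissue(sim$b)),
    sim$ortholog_map))
  zl <- function(n) stats::setNames(
    sim$spot_truth$zone[match(n$barcodes, sim$spot_truth$barcode)],
    n$barcodes)
  expect_warning(
    rep <- conservation_specificity(na, nb, zl(na), zl(nb), sim$signature,
                                    target_cluster = "INNER",
                                    n_perm = 300, seed = 24),
    "absent")
  # the tiny fixture plants only 6 signature genes, too few for a stable
  # rank correlation -- the calibrated delta-rho / empirical-p claims run
  # on the full-size world in test-acceptance.R
  expect_equal(names(which.max(rep$median_scores)), "INNER")
  expect_gt(rep$auc, 0.9)
  expect_gt(rep$delta_rho, 0)
  expect_gte(rep$empirical_p, 0)
  expect_lte(rep$empirical_p, 1)
  expect_equal(rep$delta_rho,
               specificity_margin(rep$rho, "INNER"), tolerance = 1e-12)
  # report serializes to JSON + TSV
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_specificity_report(rep, jf, tf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$auc, rep$auc, tolerance = 1e-9)
  expect_equal(nrow(read.delim(tf)), 300)
})
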