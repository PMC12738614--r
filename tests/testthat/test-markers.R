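test_that("exact rank-sum p equals exhaustive enumeration (sizes <= 8)", {
  # clean separation: (5,6,7,8) vs (1,2,3,4) -> two-sided p = 2/70
  x <- c(5, 6, 7, 8, 1, 2, 3, 4)
  grp <- rep(c(TRUE, FALSE), each = 4)
  expect_equal(rank_sum_test(x, grp), 2 / 70, tolerance = 1e-12)
  expect_equal(enum_rank_sum_p(x, grp), 2 / 70, tolerance = 1e-12)
  # grid of group sizes with ties, against the enumeration oracle
  set.seed(10)
  for (n1 in c(1, 2, 3, 5, 8)) {
    for (n2 in c(1, 3, 5, 8)) {
      x <- sample(0:3, n1 + n2, replace = TRUE)   # heavy ties
      grp <- c(rep(TRUE, n1), rep(FALSE, n2))
      expect_equal(rank_sum_test(x, grp), enum_rank_sum_p(x, grp),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
      y <- rnorm(n1 + n2)                         # tie-free
      expect_equal(rank_sum_test(y, grp), enum_rank_sum_p(y, grp),
                   tolerance = 1e-12)
    }
  }
  expect_error(rank_sum_test(1:4, rep(TRUE, 4)), "nonempty")
})

test_that("large-sample p matches the tie-corrected normal approximation", {
  set.seed(11)
  x <- c(rnorm(40, 1), rnorm(60))
  grp <- rep(c(TRUE, FALSE), c(40, 60))
  ours <- rank_sum_test(x, grp)
  ref <- wilcox.test(x[grp], x[!grp], exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
  # with ties
  x2 <- sample(0:5, 100, replace = TRUE)
  ours2 <- rank_sum_test(x2, grp)
  ref2 <- wilcox.test(x2[grp], x2[!grp], exact = FALSE,
                      correct = TRUE)$p.value
  expect_equal(ours2, ref2, tolerance = 1e-10)
})

test_that("cluster marker statistics: detection, fold change, null", {
  # pct and log2FC by hand: cluster of 4 spots, 3 detected -> pct_1 = 0.75
  vals <- rbind(c(log(3 + 1), 1), c(2, 0), c(1.5, 0), c(0, 1),
                c(0.1, 0), c(0, 2), c(0.2, 0), c(0, 1))
  norm <- toy_norm(vals)
  lab <- stats::setNames(rep(c("in", "out"), each = 4), norm$barcodes)
  st <- cluster_marker_stats(norm, lab, "in")
  expect_equal(st$pct_1[1], 0.75)
  expect_equal(st$pct_2[1], 0.5)
  # expm1-means 3 in / 1 out -> log2FC = log2(4/2) = 1
  v2 <- cbind(g = log1p(c(3, 3, 3, 3, 1, 1, 1, 1)))
  n2 <- toy_norm(v2)
  st2 <- cluster_marker_stats(n2, lab, "in")
  expect_equal(st2$avg_log2FC, 1, tolerance = 1e-12)
  # adjusted p is Bonferroni over tested genes
  expect_equal(st$p_val_adj, pmin(1, st$p_val * nrow(st)))
  expect_error(cluster_marker_stats(norm, lab, "nope"), "unknown")
  # null world: identical distributions in and out at n = 500 spots;
  # modest value scale keeps the fold-change noise floor well below 0.1
  set.seed(12)
  nv <- matrix(runif(500 * 20, 0, 0.5), nrow = 500)
  nn <- toy_norm(nv)
  nlab <- stats::setNames(rep(c("a", "b"), 250), nn$barcodes)
  stn <- cluster_marker_stats(nn, nlab, "a")
  expect_gte(median(stn$p_val), 0.3)
  expect_true(all(abs(stn$avg_log2FC) < 0.1))
})

test_that("Tippett combination matches the closed form and its bounds", {
  # p = (0.01, 0.04) -> 1 - 0.99^2 = 0.0199
  expect_equal(tippett_min_p(0.01, 0.04), 0.0199, tolerance = 1e-12)
  expect_equal(tippett_min_p(1, 1), 1)
  expect_equal(tippett_min_p(0.3), 0.3)  # k = 1 identity
  # bound: min p <= combined <= min(1, 2 min p), over random pairs
  set.seed(13)
  pa <- runif(200); pb <- runif(200)
  comb <- tippett_min_p(pa, pb)
  mn <- pmin(pa, pb)
  expect_true(all(comb >= mn - 1e-12))
  expect_true(all(comb <= pmin(1, 2 * mn) + 1e-12))
  # clipped away from zero
  expect_gte(tippett_min_p(0, 0), 1e-300)
})

test_that("combine_conserved pairs species stats on shared genes", {
  sa <- data.frame(gene = c("X", "Y", "Z"), cluster = "1",
                   p_val = c(0.01, 0.2, 0.5), avg_log2FC = c(2, 1, 0),
                   pct_1 = c(0.9, 0.5, 0.1), pct_2 = c(0.1, 0.2, 0.1),
                   p_val_adj = c(0.03, 0.6, 1))
  sb <- data.frame(gene = c("Y", "X", "W"), cluster = "1",
                   p_val = c(0.3, 0.04, 0.9), avg_log2FC = c(1.5, 2.5, 0),
                   pct_1 = c(0.6, 0.8, 0.2), pct_2 = c(0.3, 0.2, 0.2),
                   p_val_adj = c(0.9, 0.12, 1))
  rec <- combine_conserved(sa, sb, "hs", "mm")
  expect_setequal(rec$gene, c("X", "Y"))  # Z, W not shared
  xr <- rec[rec$gene == "X", ]
  expect_equal(xr$max_pval, 0.04)
  expect_equal(xr$minimump_p_val, 1 - 0.99^2, tolerance = 1e-12)
  expect_equal(xr$mm_pct_1, 0.8)
})

test_that("filter_and_rank applies both-species cutoffs and sorts by rang", {
  mk <- function(gene, lfc_a, lfc_b, pct_a, pct_b, minp) {
    out <- data.frame(gene = gene, cluster = "1",
                      a_p_val = minp, a_avg_log2FC = lfc_a,
                      a_pct_1 = pct_a, a_pct_2 = 0.1, a_p_val_adj = minp,
                      b_p_val = minp, b_avg_log2FC = lfc_b,
                      b_pct_1 = pct_b, b_pct_2 = 0.1, b_p_val_adj = minp,
                      max_pval = minp, minimump_p_val = minp)
    attr(out, "species") <- c("a", "b")
    out
  }
  rec <- rbind(mk("pass", 2, 2, 0.8, 0.7, 0.25),
               mk("one_sided", 1.2, 0.9, 0.8, 0.7, 1e-10),
               mk("low_pct", 2, 2, 0.05, 0.7, 1e-10),
               mk("edge_lfc", 1, 2, 0.8, 0.7, 1e-10),   # strict >
               mk("edge_pct", 2, 2, 0.1, 0.7, 1e-10))   # strict >
  attr(rec, "species") <- c("a", "b")
  ranked <- filter_and_rank(rec)
  expect_identical(ranked$gene, "pass")
  # minimump = 0.25, sum = 1.5, sumLog = 2 -> rang = 2 * 1.5 * 2 = 6
  expect_equal(ranked$sum, 1.5)
  expect_equal(ranked$sumLog, 2)
  expect_equal(ranked$rang, 6, tolerance = 1e-12)
  # minimump = 1 -> rang = 0, sorts last
  rec2 <- rbind(mk("strong", 2, 2, 0.8, 0.7, 0.01),
                mk("null_p", 2, 2, 0.8, 0.7, 1))
  attr(rec2, "species") <- c("a", "b")
  r2 <- filter_and_rank(rec2)
  expect_identical(r2$gene, c("strong", "null_p"))
  expect_equal(r2$rang[2], 0)
  # rang invariant under swapping the species labels
  swapped <- mk("pass", 2, 2, 0.7, 0.8, 0.25)  # b-values as a-values
  attr(swapped, "species") <- c("a", "b")
  expect_equal(filter_and_rank(swapped)$rang, ranked$rang)
})

test_that("rang_score floors the combined p at 1e-300", {
  expect_equal(rang_score(0.25, 1.5, 2), 6)
  expect_equal(rang_score(0, 1, 1), -log2(1e-300))
  expect_true(is.finite(rang_score(0, 2, 3)))
})

test_that("dotplot table caps genes and matches an independent recount", {
  sim <- simulate_two_species(tiny_sim_config(seed = 14))
  na <- log_normalize(filter_spots_in_tissue(sim$a))
  lab_a <- stats::setNames(
    sim$spot_truth$zone[match(na$barcodes, sim$spot_truth$barcode)],
    na$barcodes)
  ranked <- data.frame(gene = na$gene_symbols[1:50])
  tab <- export_dotplot_table(ranked, list(A = na), list(A = lab_a),
                              top_n = 40)
  expect_equal(length(unique(tab$gene)), 40)
  # recount one cell by brute force
  g <- tab$gene[1]; cl <- tab$cluster[1]
  sel <- lab_a == cl
  dense <- as.matrix(na$values[sel, g, drop = FALSE])
  expect_equal(tab$pct_detected[1], 100 * mean(dense > 0))
  expect_equal(tab$mean_expression[1], mean(dense))
  # empty ranked list -> empty table with the full header
  empty <- export_dotplot_table(data.frame(gene = character(0)),
                                list(A = na), list(A = lab_a))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("gene", "cluster", "species", "mean_expression",
                        "pct_detected"))
})
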