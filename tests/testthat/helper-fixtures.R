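# Shared fixtures and independent oracles for the test suite.  Everything
# is built in code; nothing is read from disk.

# Small lattice / panel for fast end-to-end runs (~300 in-tissue spots).
tiny_sim_config <- function(seed = 42L, ...) {
  sim_config(n_rows = 21, n_cols = 21, center = c(10, 10),
             radii = c(3, 5, 7, 9, 10), bat_patch = c(0, 2, 0, 2),
             n_genes_total = 300, n_markers_per_zone = 10,
             n_conserved_per_zone = 6, seed = seed, ...)
}

# Build a normalized_matrix directly from a dense value matrix (spots x
# genes); used by tests that probe a statistic, not the normalization.
toy_norm <- function(values, species = "toy") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("BC-%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%03d", seq_len(ncol(values)))
  structure(list(values = methods::as(Matrix::Matrix(values, sparse = TRUE),
                                      "generalMatrix"),
                 barcodes = rownames(values),
                 gene_symbols = colnames(values),
                 species = species, scale_factor = 1e4, positions = NULL),
            class = "normalized_matrix")
}

# A hand-sized spot_matrix with positions, for the I/O tests.
tiny_spot_matrix <- function() {
  counts <- rbind(c(5, 0, 2, 0),
                  c(0, 1, 0, 0),
                  c(7, 0, 0, 3),
                  c(0, 0, 0, 0),
                  c(1, 2, 3, 4))
  pos <- data.frame(barcode = sprintf("BC-%d", 1:5),
                    in_tissue = c(1L, 0L, 1L, 1L, 0L),
                    array_row = 0:4, array_col = c(0L, 1L, 0L, 1L, 2L),
                    pxl_row = (0:4) * 10, pxl_col = c(0, 10, 0, 10, 20))
  spot_matrix(counts, sprintf("BC-%d", 1:5), c("GA", "GB", "GC", "GD"),
              species = "toy", positions = pos)
}

# --- independent oracles ------------------------------------------------

# Two-sided rank-sum p by full enumeration of group assignments.
enum_rank_sum_p <- function(x, in_group) {
  r <- rank(x)
  n1 <- sum(in_group)
  sums <- utils::combn(length(x), n1, function(idx) sum(r[idx]))
  w <- sum(r[in_group])
  eps <- 1e-9
  p_le <- mean(sums <= w + eps)
  p_ge <- mean(sums >= w - eps)
  min(1, 2 * min(p_le, p_ge))
}

# AUC by exhaustive pair counting.
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Zone counts by a brute-force loop over every lattice point.
brute_force_zone_counts <- function(n_rows, n_cols, center, radii) {
  counts <- c(MEDULLA = 0, INNER = 0, ZF = 0, ZG = 0, CTWAT = 0, NONE = 0)
  for (i in seq_len(n_rows) - 1) {
    for (j in seq_len(n_cols) - 1) {
      d <- sqrt((i - center[1])^2 + (j - center[2])^2)
      z <- if (d < radii[1]) "MEDULLA" else if (d < radii[2]) "INNER"
      else if (d < radii[3]) "ZF" else if (d < radii[4]) "ZG"
      else if (d < radii[5]) "CTWAT" else "NONE"
      counts[z] <- counts[z] + 1
    }
  }
  counts
}
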