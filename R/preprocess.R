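#' Library-size log-normalization
#'
#' Counts are scaled to a common library size and log-transformed:
#' `value(s, g) = ln(1 + count(s, g) / total(s) * scale_factor)`, the
#' standard depth-correction for spot data.  Spots with zero total counts
#' become all-zero rows (with a warning).
#'
#' @param matrix a [spot_matrix()].
#' @param scale_factor target library size, default 10,000 (counts per 10k).
#' @return a `normalized_matrix`: list with sparse `values` (spots x
#'   genes, natural-log scale), `barcodes`, `gene_symbols`, `species`,
#'   `scale_factor` and the `positions` table.
#' @export
log_normalize <- function(matrix, scale_factor = 1e4) {
  counts <- matrix$counts
  if (any(counts@x < 0)) stop("negative counts")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    warning(sum(totals == 0), " spot(s) have zero total counts; ",
            "their normalized rows are all zero")
  inv <- ifelse(totals > 0, scale_factor / totals, 0)
  values <- Diagonal(x = inv) %*% counts
  values@x <- log1p(values@x)
  values <- methods::as(values, "CsparseMatrix")
  dimnames(values) <- dimnames(counts)
  structure(list(values = values, barcodes = matrix$barcodes,
                 gene_symbols = matrix$gene_symbols,
                 species = matrix$species, scale_factor = scale_factor,
                 positions = matrix$positions),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix [%s]: %d spots x %d genes (CP%g, ln)\n",
              x$species, nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their normalized values standardized
#' against a fitted mean--variance trend: a loess fit of log10 variance on
#' log10 mean predicts each gene's expected variance, values are
#' standardized by the expected standard deviation and clipped at
#' `sqrt(n_spots)`, and the variance of the clipped standardized values is
#' the ranking score.  With too few positive-variance genes for a stable
#' trend fit the raw variance is used.  Ties break by symbol order.
#'
#' @param norm a `normalized_matrix`.
#' @param n_top how many genes to return.
#' @param loess_span span of the trend fit.
#' @return character vector of gene symbols, highest variability first.
#' @export
select_variable_genes <- function(norm, n_top, loess_span = 0.3) {
  if (n_top < 1) stop("n_top must be >= 1")
  v <- norm$values
  n <- nrow(v)
  mu <- Matrix::colSums(v) / n
  ex2 <- Matrix::colSums(v^2) / n
  varg <- (ex2 - mu^2) * n / max(n - 1, 1)
  score <- numeric(ncol(v))
  pos <- which(varg > 0 & mu > 0)
  fit_ok <- FALSE
  if (length(pos) >= 10) {
    fit <- tryCatch(
      loess(log10(varg[pos]) ~ log10(mu[pos]), span = loess_span,
            degree = 2),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      exp_sd <- sqrt(10^predict(fit))
      clip <- sqrt(n)
      dense <- as.matrix(v[, pos, drop = FALSE])
      z <- sweep(dense, 2, mu[pos], "-")
      z <- sweep(z, 2, exp_sd, "/")
      z[z > clip] <- clip
      z[z < -clip] <- -clip
      score[pos] <- apply(z, 2, var)
      fit_ok <- TRUE
    }
  }
  if (!fit_ok) score <- varg
  if (n_top > length(score)) {
    warning("n_top exceeds the number of genes; returning all genes")
    n_top <- length(score)
  }
  ord <- order(-score, norm$gene_symbols)
  norm$gene_symbols[ord][seq_len(n_top)]
}

#' Joint embedding of two species over shared genes
#'
#' Embeds the spots of both species in one low-dimensional space so that a
#' single graph clustering can be run -- the package's stand-in for
#' anchor-based integration.  Each gene is centered and unit-scaled
#' (standardized values clipped at `clip`) before the decomposition.
#'
#' With `method = "cca"` (the default) genes are standardized within each
#' species and the cross-species covariance matrix over the shared genes
#' is decomposed by SVD (a diagonal canonical correlation analysis): the
#' left/right singular vectors embed the two species' spots in directions
#' of *shared* covariation, so species-private expression programs cannot
#' separate the species.  With `method = "pca"` the two matrices are
#' stacked, genes are standardized across the stacked matrix and a plain
#' PCA is taken; this is simpler but leaves strong species-specific
#' signal in the embedding.
#'
#' @param norm_a,norm_b `normalized_matrix` objects sharing gene symbols.
#' @param genes character vector of shared genes to use (e.g. from
#'   [select_variable_genes()]).
#' @param n_components number of components to keep (default 30).
#' @param clip absolute ceiling for standardized values before the
#'   decomposition.
#' @param method `"cca"` or `"pca"` (see above).
#' @return an `embedding`: list with `coordinates` (spots x components,
#'   rownames prefixed by species, columns mutually orthogonal and
#'   weighted by component strength), `explained_variance`
#'   (non-increasing), `species` per row and `n_components`.
#' @export
joint_pca <- function(norm_a, norm_b, genes, n_components = 30, clip = 10,
                      method = c("cca", "pca")) {
  method <- match.arg(method)
  genes <- intersect(genes, intersect(norm_a$gene_symbols,
                                      norm_b$gene_symbols))
  if (!length(genes)) stop("no shared genes to embed")
  xa <- as.matrix(norm_a$values[, genes, drop = FALSE])
  xb <- as.matrix(norm_b$values[, genes, drop = FALSE])
  rn <- c(paste0(norm_a$species, ":", norm_a$barcodes),
          paste0(norm_b$species, ":", norm_b$barcodes))
  standardize <- function(x) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    x[x > clip] <- clip
    x[x < -clip] <- -clip
    x
  }
  if (method == "cca") {
    max_nc <- min(nrow(xa), nrow(xb), length(genes))
    if (n_components > max_nc) {
      warning("reducing n_components from ", n_components, " to ", max_nc)
      n_components <- max_nc
    }
    za <- standardize(xa)
    zb <- standardize(xb)
    sv <- svd(za %*% t(zb), nu = n_components, nv = n_components)
    # canonical scores: weight the singular vectors by the singular
    # values so strongly shared components dominate distances, exactly as
    # PCA scores weight principal axes by their standard deviations
    d <- sv$d[seq_len(n_components)]
    coords <- (rbind(sv$u, sv$v) %*% diag(d, n_components)) / sqrt(2)
    expl <- d^2
  } else {
    x <- rbind(xa, xb)
    max_nc <- min(nrow(x) - 1L, ncol(x))
    if (n_components > max_nc) {
      warning("reducing n_components from ", n_components, " to ", max_nc)
      n_components <- max_nc
    }
    x <- standardize(x)
    pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
    coords <- pc$x[, seq_len(n_components), drop = FALSE]
    expl <- pc$sdev[seq_len(n_components)]^2
  }
  rownames(coords) <- rn
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(coordinates = coords,
                 explained_variance = expl,
                 species = c(rep(norm_a$species, nrow(xa)),
                             rep(norm_b$species, nrow(xb))),
                 n_components = n_components, method = method),
            class = "embedding")
}

#' Shared-nearest-neighbor graph with Jaccard weights
#'
#' For each spot the k nearest Euclidean neighbors in the embedding are
#' found (the spot itself counts as a neighbor); the edge weight between
#' two spots is the Jaccard similarity of their neighbor sets, and edges
#' below `prune` are removed.
#'
#' @param embedding an `embedding` (or a plain coordinate matrix with row
#'   names).
#' @param k neighborhood size (default 20).
#' @param prune Jaccard cutoff below which edges are dropped (default
#'   1/15).
#' @return an undirected weighted [igraph::graph] with one vertex per spot.
#' @export
build_snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  coords <- if (inherits(embedding, "embedding"))
    embedding$coordinates else as.matrix(embedding)
  n <- nrow(coords)
  if (is.null(rownames(coords)))
    rownames(coords) <- sprintf("spot-%d", seq_len(n))
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of spots")
  d <- as.matrix(stats::dist(coords))
  # neighbor membership matrix: row i marks N(i), self included
  nb_idx <- apply(d, 1, function(row) order(row)[seq_len(k)])
  A <- sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(nb_idx),
                    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  trip <- Matrix::summary(methods::as(shared, "TsparseMatrix"))
  keepmask <- trip$i < trip$j
  i <- trip$i[keepmask]; j <- trip$j[keepmask]; s <- trip$x[keepmask]
  w <- s / (2 * k - s)
  keep <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::V(g)$barcode <- rownames(coords)
  g
}

#' Graph community detection at a fixed resolution
#'
#' Louvain modularity optimization on the SNN graph.  Cluster ids are
#' renumbered by decreasing size (1 = largest); the run is deterministic
#' for a fixed seed.
#'
#' @param graph weighted undirected graph from [build_snn_graph()].
#' @param resolution modularity resolution (default 0.4).
#' @param seed integer seed.
#' @return a `cluster_labels` data.frame with columns `barcode` and
#'   `cluster`, and the resolution stored as an attribute.
#' @export
cluster_graph <- function(graph, resolution = 0.4, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  renum <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- data.frame(
    barcode = igraph::V(graph)$barcode,
    cluster = as.integer(renum[as.character(memb)]),
    stringsAsFactors = FALSE)
  attr(labels, "resolution") <- resolution
  class(labels) <- c("cluster_labels", "data.frame")
  labels
}
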