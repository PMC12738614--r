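#' @importFrom Matrix Matrix Diagonal rowSums colSums t sparseMatrix
#' @importFrom stats rnbinom rlnorm runif rbinom prcomp loess predict
#'   wilcox.test pnorm p.adjust cor median quantile sd var rnorm ks.test
#' @importFrom utils read.delim write.table packageVersion head
NULL

# Anatomical zone labels used by the synthetic generator and expected in
# truth tables.  INNER stands for ZR in species A (human-like) and BAT in
# species B (mouse-like); CTWAT is connective tissue / white adipose tissue.
ZONE_LEVELS <- c("MEDULLA", "INNER", "ZF", "ZG", "CTWAT")
ZONE_NONE <- "NONE"

#' Construct a spot-by-gene count matrix
#'
#' The basic container of the package: raw integer counts for one species
#' with spot barcodes, gene symbols and an optional tissue-positions table.
#' Counts are stored sparse (spots in rows, genes in columns), matching the
#' orientation used by every downstream operation; the on-disk MatrixMarket
#' file keeps the 10x genes-by-barcodes orientation.
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   spots in rows, genes in columns.
#' @param barcodes character vector of unique spot barcodes (row names).
#' @param gene_symbols character vector of unique gene symbols (col names).
#' @param species single string tag, e.g. `"human"` or `"A"`.
#' @param positions optional data.frame with columns `barcode`, `in_tissue`,
#'   `array_row`, `array_col`, `pxl_row`, `pxl_col` (extra columns kept).
#' @return an object of class `spot_matrix`.
#' @export
spot_matrix <- function(counts, barcodes, gene_symbols, species,
                        positions = NULL) {
  counts <- methods::as(methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(barcodes))
    stop("counts has ", nrow(counts), " rows but ", length(barcodes),
         " barcodes were given")
  if (ncol(counts) != length(gene_symbols))
    stop("counts has ", ncol(counts), " columns but ", length(gene_symbols),
         " gene symbols were given")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  if (anyDuplicated(gene_symbols)) stop("gene symbols must be unique")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(barcodes, gene_symbols)
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    req <- c("barcode", "in_tissue", "array_row", "array_col")
    miss <- setdiff(req, names(positions))
    if (length(miss))
      stop("positions table is missing column(s): ",
           paste(miss, collapse = ", "))
    positions <- positions[match(barcodes, positions$barcode), , drop = FALSE]
    if (anyNA(positions$barcode))
      stop("positions table does not cover all matrix barcodes")
    rownames(positions) <- NULL
  }
  structure(
    list(counts = counts, barcodes = as.character(barcodes),
         gene_symbols = as.character(gene_symbols),
         species = as.character(species), positions = positions),
    class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix [%s]: %d spots x %d genes", x$species,
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$positions))
    cat(sprintf("; %d in-tissue", sum(x$positions$in_tissue > 0)))
  cat("\n")
  invisible(x)
}

#' @export
dim.spot_matrix <- function(x) dim(x$counts)

# Subset a spot_matrix by spot and/or gene index, keeping metadata in sync.
subset_spot_matrix <- function(x, spots = NULL, genes = NULL) {
  if (is.null(spots)) spots <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  pos <- x$positions
  if (!is.null(pos)) pos <- pos[spots, , drop = FALSE]
  spot_matrix(x$counts[spots, genes, drop = FALSE],
              x$barcodes[spots], x$gene_symbols[genes], x$species, pos)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to renaming), around 0 for independent
#' ones.  Used to compare inferred clusters with planted zones.
#'
#' @param a,b vectors of equal length with cluster labels.
#' @return a single number, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Resolve a cluster-label argument into a character vector aligned with
# `barcodes`.  Accepts a named vector or a data.frame(barcode, cluster).
resolve_labels <- function(labels, barcodes) {
  if (is.data.frame(labels)) {
    if (!all(c("barcode", "cluster") %in% names(labels)))
      stop("label data.frame needs columns 'barcode' and 'cluster'")
    out <- as.character(labels$cluster)[match(barcodes, labels$barcode)]
  } else {
    if (is.null(names(labels)))
      stop("cluster labels must be named by barcode or given as a data.frame")
    out <- as.character(labels[barcodes])
  }
  if (anyNA(out))
    stop("cluster labels are missing for ", sum(is.na(out)), " spot(s)")
  out
}
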