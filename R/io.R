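# Locate a file under `dir` trying plain and gzipped names.
find_10x_file <- function(dir, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(s, ext))
    if (file.exists(f)) return(f)
  }
  stop("missing file in '", dir, "': expected one of ",
       paste(stems, collapse = " / "), " (optionally .gz)")
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

# Minimal MatrixMarket coordinate reader (integer/real, general).  The 10x
# convention stores genes in rows and barcodes in columns.
read_mtx <- function(path) {
  lines <- read_lines_maybe_gz(path)
  if (!length(lines) || !startsWith(lines[1], "%%MatrixMarket"))
    stop("'", path, "': not a MatrixMarket file")
  body <- lines[!startsWith(lines, "%")]
  hdr <- scan(text = body[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 3) stop("'", path, "': malformed size line")
  nr <- hdr[1]; nc <- hdr[2]; nnz <- hdr[3]
  if (length(body) - 1 != nnz)
    stop("'", path, "': expected ", nnz, " entries, found ",
         length(body) - 1)
  if (nnz == 0) {
    m <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(nr, nc))
    return(m)
  }
  trip <- matrix(scan(text = body[-1], what = numeric(), quiet = TRUE),
                 ncol = 3, byrow = TRUE)
  sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
               dims = c(nr, nc))
}

#' Read a 10x-style spatial directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (each optionally
#' gzipped) and, if present, a `tissue_positions_list.csv` /
#' `tissue_positions.csv` table.  The MatrixMarket file is stored genes x
#' barcodes (the 10x convention) and is transposed on read; the features
#' file may have 1--3 columns (id, symbol, type) -- the symbol column is
#' used, falling back to the id.
#'
#' @param path directory path.
#' @param species species tag recorded on the result (default: directory
#'   base name).
#' @return a [spot_matrix()] with spots in rows.
#' @export
read_10x_dir <- function(path, species = basename(path)) {
  if (!dir.exists(path)) stop("directory not found: '", path, "'")
  mtx <- read_mtx(find_10x_file(path, "matrix.mtx"))
  barcodes <- read_lines_maybe_gz(find_10x_file(path, "barcodes.tsv"))
  feat_lines <- read_lines_maybe_gz(find_10x_file(path, "features.tsv"))
  feats <- read.delim(text = feat_lines, header = FALSE,
                      stringsAsFactors = FALSE)
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (nrow(mtx) != length(symbols) || ncol(mtx) != length(barcodes))
    stop("matrix dimensions (", nrow(mtx), " x ", ncol(mtx),
         ") do not match features (", length(symbols), ") / barcodes (",
         length(barcodes), ")")
  if (anyDuplicated(symbols)) symbols <- make.unique(symbols)
  positions <- NULL
  for (s in c("tissue_positions_list.csv", "tissue_positions.csv")) {
    for (ext in c("", ".gz")) {
      f <- file.path(path, paste0(s, ext))
      if (file.exists(f)) positions <- read_tissue_positions(f)
    }
  }
  spot_matrix(Matrix::t(mtx), barcodes, symbols, species, positions)
}

#' Read a tissue-positions table
#'
#' Accepts the 6-column CSV dialect `barcode, in_tissue, array_row,
#' array_col, pxl_row, pxl_col`; a header line is auto-detected.
#'
#' @param path CSV path (optionally gzipped).
#' @return data.frame with the canonical column names.
#' @export
read_tissue_positions <- function(path) {
  lines <- read_lines_maybe_gz(path)
  if (!length(lines)) stop("empty tissue positions file: '", path, "'")
  first <- strsplit(lines[1], ",")[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(
    as.numeric(first[2])))
  df <- read.delim(text = lines, sep = ",", header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    stop("tissue positions file must have 6 columns, found ", ncol(df))
  names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pxl_row", "pxl_col")
  df
}

#' Write a spot matrix as a 10x-style directory
#'
#' Emits `matrix.mtx` (coordinate integer general, genes x barcodes,
#' 1-based), `barcodes.tsv`, `features.tsv` (id, symbol, type) and, when
#' positions are attached, `tissue_positions_list.csv` with a header.
#'
#' @param matrix a [spot_matrix()].
#' @param path output directory (created if needed).
#' @param gzip write the matrix gzipped as `matrix.mtx.gz`.
#' @return `path`, invisibly.
#' @export
write_10x_dir <- function(matrix, path, gzip = FALSE) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory '", path, "'")
  m <- Matrix::t(matrix$counts)  # genes x barcodes on disk
  trip <- Matrix::summary(m)
  mtx_file <- file.path(path, if (gzip) "matrix.mtx.gz" else "matrix.mtx")
  con <- if (gzip) gzfile(mtx_file, "wt") else file(mtx_file, "wt")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), nrow(trip))), con)
  if (nrow(trip))
    writeLines(paste(trip$i, trip$j, as.integer(trip$x)), con)
  close(con)
  writeLines(matrix$barcodes, file.path(path, "barcodes.tsv"))
  write.table(data.frame(matrix$gene_symbols, matrix$gene_symbols,
                         "Gene Expression"),
              file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(matrix$positions)) {
    pos <- matrix$positions[, c("barcode", "in_tissue", "array_row",
                                "array_col", "pxl_row", "pxl_col")]
    write.table(pos, file.path(path, "tissue_positions_list.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Keep only in-tissue spots
#'
#' @param matrix a [spot_matrix()] with a positions table carrying
#'   `in_tissue` flags.
#' @return the filtered [spot_matrix()], spot order preserved.
#' @export
filter_spots_in_tissue <- function(matrix) {
  if (is.null(matrix$positions))
    stop("no positions table attached; cannot filter on tissue presence")
  keep <- which(matrix$positions$in_tissue > 0)
  if (!length(keep)) stop("no in-tissue spots remain after filtering")
  subset_spot_matrix(matrix, spots = keep)
}

#' Drop genes detected in too few spots
#'
#' A gene is retained iff it has a nonzero count in at least
#' `min_fraction` of the spots (inclusive boundary).  Apply after
#' [filter_spots_in_tissue()] so the denominator is the in-tissue spot
#' count.
#'
#' @param matrix a [spot_matrix()].
#' @param min_fraction detection threshold, default 1% of spots.
#' @return the filtered [spot_matrix()].
#' @export
filter_genes_min_fraction <- function(matrix, min_fraction = 0.01) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  n_detect <- Matrix::colSums(matrix$counts > 0)
  keep <- which(n_detect >= min_fraction * nrow(matrix$counts))
  subset_spot_matrix(matrix, genes = keep)
}

#' Harmonize gene symbols through an ortholog map
#'
#' Replaces each gene symbol by its mapped target symbol; genes without a
#' mapping are dropped (cross-species comparison needs shared symbols).
#' When several sources map to one target, the second and subsequent
#' occurrences (in input gene order) receive deterministic `.1`, `.2`, ...
#' suffixes so identifiers stay unique; counts are never merged.
#'
#' @param matrix a [spot_matrix()].
#' @param map data.frame with columns `source` and `target` (an HGNC
#'   symbol-update table works the same way).
#' @return the relabelled [spot_matrix()].
#' @export
apply_ortholog_map <- function(matrix, map) {
  if (anyDuplicated(map$source)) stop("ortholog map sources must be unique")
  tgt <- map$target[match(matrix$gene_symbols, map$source)]
  keep <- which(!is.na(tgt))
  if (!length(keep)) {
    warning("ortholog map covers none of the matrix genes; ",
            "returning an empty matrix")
  }
  out <- subset_spot_matrix(matrix, genes = keep)
  out$gene_symbols <- make.unique(tgt[keep], sep = ".")
  colnames(out$counts) <- out$gene_symbols
  out
}

#' Read / write an ortholog map TSV
#'
#' Two or three tab-separated columns: source symbol, target symbol and an
#' optional duplicate-target flag.  A header is auto-detected.
#'
#' @param path TSV path.
#' @return data.frame with columns `source`, `target`,
#'   `is_duplicate_target`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("ortholog map not found: '", path, "'")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) %in% c("source", "source_symbol"))
    df <- df[-1, , drop = FALSE]
  out <- data.frame(source = df[[1]], target = df[[2]],
                    stringsAsFactors = FALSE)
  out$is_duplicate_target <- if (ncol(df) >= 3)
    as.logical(df[[3]]) else duplicated(out$target)
  out
}

#' @rdname read_ortholog_map
#' @param map ortholog map data.frame.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
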