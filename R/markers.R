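# Exact two-sided rank-sum p-value via the distribution of the group-1
# scaled-rank sum over all subsets, computed by dynamic programming.
# Handles ties (average ranks are doubled to stay integral).  Count arrays
# stay below 2^53 for the supported sizes, so the arithmetic is exact.
exact_rank_sum_p <- function(r, in_group) {
  s <- as.integer(round(2 * r))
  n1 <- sum(in_group)
  w_obs <- sum(s[in_group])
  smax <- sum(s)
  # f[j+1, t+1] = number of size-j subsets with scaled-rank sum t
  f <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (v in s) {
    jmax <- min(n1, nrow(f) - 1)
    for (j in jmax:1) {
      nzero <- which(f[j, ] > 0)
      if (length(nzero))
        f[j + 1, nzero + v] <- f[j + 1, nzero + v] + f[j, nzero]
    }
  }
  dist <- f[n1 + 1, ]
  total <- sum(dist)
  p_le <- sum(dist[seq_len(w_obs + 1)]) / total
  p_ge <- sum(dist[(w_obs + 1):length(dist)]) / total
  min(1, 2 * min(p_le, p_ge))
}

# Normal-approximation rank-sum p with tie and continuity corrections,
# matching the classic large-sample two-sided test.
approx_rank_sum_p <- function(r, in_group, tie_term) {
  n1 <- sum(in_group)
  n2 <- length(r) - n1
  N <- n1 + n2
  U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- z - sign(z) * 0.5  # continuity correction
  2 * pnorm(-abs(z) / sqrt(sigma2))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' The workhorse of per-cluster differential expression.  Uses exact
#' enumeration of the rank-sum distribution (tie-aware, via dynamic
#' programming) when both groups have at most `exact_max` observations, and
#' the tie- and continuity-corrected normal approximation otherwise.
#'
#' @param x numeric values.
#' @param in_group logical vector marking group 1.
#' @param exact_max exact-mode size cap per group (default 25).
#' @return the two-sided p-value.
#' @export
rank_sum_test <- function(x, in_group, exact_max = 25) {
  n1 <- sum(in_group)
  n2 <- length(x) - n1
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(x)
  if (n1 <= exact_max && n2 <= exact_max)
    return(exact_rank_sum_p(r, in_group))
  tl <- table(x)
  approx_rank_sum_p(r, in_group, sum(tl^3 - tl))
}

# log2 fold change of de-logged mean expression, pseudocount on both means.
# Shared by cluster_marker_stats and log2fc_profiles so profiles and marker
# tables agree exactly.
log2_fold_change <- function(mean_in, mean_out, pseudocount = 1) {
  log2((mean_in + pseudocount) / (mean_out + pseudocount))
}

#' One-vs-rest marker statistics for a cluster in one species
#'
#' For every gene, compares normalized values of spots in `cluster` against
#' all other spots: a two-sided Wilcoxon rank-sum p-value (exact for small
#' groups, normal approximation with tie and continuity corrections
#' otherwise), the log2 fold change of de-logged means with pseudocount
#' `pseudocount`, detection fractions inside (`pct_1`) and outside
#' (`pct_2`) the cluster, and a multiplicity-adjusted p-value.
#'
#' @param norm a `normalized_matrix`.
#' @param labels cluster labels (named vector or data.frame with `barcode`
#'   and `cluster`).
#' @param cluster the cluster id to test.
#' @param pseudocount pseudocount inside the fold-change ratio (default 1;
#'   values are on the counts-per-10k scale, so 1 is a mild regularizer).
#' @param adjust multiplicity adjustment over tested genes: `"bonferroni"`
#'   (default, the ecosystem convention) or `"BH"`.
#' @param exact_max per-group size cap for the exact rank-sum mode.
#' @return data.frame with one row per gene: `gene`, `cluster`, `p_val`,
#'   `avg_log2FC`, `pct_1`, `pct_2`, `p_val_adj`.
#' @export
cluster_marker_stats <- function(norm, labels, cluster, pseudocount = 1,
                                 adjust = c("bonferroni", "BH"),
                                 exact_max = 25) {
  adjust <- match.arg(adjust)
  lab <- resolve_labels(labels, norm$barcodes)
  in_group <- lab == as.character(cluster)
  if (!any(in_group)) stop("unknown or empty cluster: '", cluster, "'")
  if (all(in_group)) stop("cluster '", cluster, "' has an empty complement")
  v <- norm$values
  n1 <- sum(in_group); n2 <- sum(!in_group)
  expm1_v <- v
  expm1_v@x <- expm1(expm1_v@x)
  mean_in <- Matrix::colSums(expm1_v[in_group, , drop = FALSE]) / n1
  mean_out <- Matrix::colSums(expm1_v[!in_group, , drop = FALSE]) / n2
  pct_1 <- Matrix::colSums(v[in_group, , drop = FALSE] > 0) / n1
  pct_2 <- Matrix::colSums(v[!in_group, , drop = FALSE] > 0) / n2
  exact <- n1 <= exact_max && n2 <= exact_max
  dense <- as.matrix(v)
  p <- vapply(seq_len(ncol(dense)), function(j) {
    x <- dense[, j]
    if (exact) {
      exact_rank_sum_p(rank(x), in_group)
    } else {
      tl <- tabulate(match(x, unique(x)))
      approx_rank_sum_p(rank(x), in_group, sum(tl^3 - tl))
    }
  }, numeric(1))
  data.frame(
    gene = norm$gene_symbols, cluster = as.character(cluster),
    p_val = p,
    avg_log2FC = log2_fold_change(mean_in, mean_out, pseudocount),
    pct_1 = as.numeric(pct_1), pct_2 = as.numeric(pct_2),
    p_val_adj = p.adjust(p, method = adjust),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Tippett minimum-p combination of two p-values
#'
#' `1 - (1 - min(p))^k` with `k = 2` studies, clipped to `[1e-300, 1]`.
#' With a single p-value (`k = 1`) the input is returned unchanged.
#'
#' @param ... one or two numeric vectors of p-values (recycled).
#' @return combined p-value vector.
#' @export
tippett_min_p <- function(...) {
  ps <- list(...)
  k <- length(ps)
  pmin_v <- if (k == 1) ps[[1]] else do.call(pmin, ps)
  out <- 1 - (1 - pmin_v)^k
  pmin(pmax(out, 1e-300), 1)
}

#' Pair two species' marker statistics into conserved-marker records
#'
#' Restricted to genes tested in both species (symbols are assumed
#' ortholog-harmonized).  Adds the meta-analytic minimum-p combination
#' (`minimump_p_val`, Tippett over the two raw p-values) and the maximum of
#' the two raw p-values (`max_pval`).
#'
#' @param stats_a,stats_b outputs of [cluster_marker_stats()] for the same
#'   (mapped) cluster in each species.
#' @param species_a,species_b column-prefix tags for the output.
#' @return data.frame with `gene`, `cluster`, per-species stats columns
#'   (`<tag>_p_val`, `<tag>_avg_log2FC`, `<tag>_pct_1`, `<tag>_pct_2`,
#'   `<tag>_p_val_adj`), `max_pval` and `minimump_p_val`.
#' @export
combine_conserved <- function(stats_a, stats_b, species_a = "a",
                              species_b = "b") {
  shared <- intersect(stats_a$gene, stats_b$gene)
  a <- stats_a[match(shared, stats_a$gene), ]
  b <- stats_b[match(shared, stats_b$gene), ]
  out <- data.frame(gene = shared, cluster = a$cluster,
                    stringsAsFactors = FALSE)
  for (col in c("p_val", "avg_log2FC", "pct_1", "pct_2", "p_val_adj")) {
    out[[paste0(species_a, "_", col)]] <- a[[col]]
    out[[paste0(species_b, "_", col)]] <- b[[col]]
  }
  out$max_pval <- pmax(a$p_val, b$p_val)
  out$minimump_p_val <- tippett_min_p(a$p_val, b$p_val)
  attr(out, "species") <- c(species_a, species_b)
  out
}

#' Conservation ranking score
#'
#' `rang = (-log2(minimump_p_val)) * sum * sumLog`, where `sum` is the
#' two species' in-cluster detection fractions added together and `sumLog`
#' their mean log2 fold change.  The combined p is floored at 1e-300 so the
#' logarithm stays finite.
#'
#' @param minimump_p_val combined p-value(s).
#' @param sum sum of the two `pct_1` values.
#' @param sumLog mean of the two `avg_log2FC` values.
#' @return numeric ranking score(s).
#' @export
rang_score <- function(minimump_p_val, sum, sumLog) {
  (-log2(pmax(minimump_p_val, 1e-300))) * sum * sumLog
}

#' Apply conservation filters and rank conserved markers
#'
#' Keeps records whose log2 fold change exceeds `lfc_threshold` in both
#' species and whose in-cluster detection fraction exceeds `pct_threshold`
#' in both species (strict inequalities), then computes `sum`, `sumLog` and
#' the `rang` score and sorts by decreasing `rang` (ties broken by gene
#' symbol, ascending).
#'
#' @param records output of [combine_conserved()].
#' @param lfc_threshold log2 fold-change cutoff (default 1).
#' @param pct_threshold in-cluster detection cutoff (default 0.1).
#' @return the filtered, ranked data.frame with `sum`, `sumLog`, `rang`
#'   columns appended.
#' @export
filter_and_rank <- function(records, lfc_threshold = 1,
                            pct_threshold = 0.1) {
  sp <- attr(records, "species")
  if (is.null(sp)) stop("records must come from combine_conserved()")
  lfc_a <- records[[paste0(sp[1], "_avg_log2FC")]]
  lfc_b <- records[[paste0(sp[2], "_avg_log2FC")]]
  pct_a <- records[[paste0(sp[1], "_pct_1")]]
  pct_b <- records[[paste0(sp[2], "_pct_1")]]
  keep <- lfc_a > lfc_threshold & lfc_b > lfc_threshold &
    pct_a > pct_threshold & pct_b > pct_threshold
  out <- records[keep, , drop = FALSE]
  out$sum <- (pct_a + pct_b)[keep]
  out$sumLog <- ((lfc_a + lfc_b) / 2)[keep]
  out$rang <- rang_score(out$minimump_p_val, out$sum, out$sumLog)
  out <- out[order(-out$rang, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species") <- sp
  out
}

#' Conserved markers for every cluster of a two-species dataset
#'
#' Convenience wrapper: runs [cluster_marker_stats()] per cluster and
#' species, pairs the results with [combine_conserved()] and ranks them
#' with [filter_and_rank()].
#'
#' @param norm_a,norm_b `normalized_matrix` objects with harmonized
#'   symbols.
#' @param labels_a,labels_b cluster labels per species (same cluster ids).
#' @param clusters cluster ids to process (default: all shared ids).
#' @param ... passed to [cluster_marker_stats()] and [filter_and_rank()].
#' @return named list of ranked conserved-marker data.frames, one per
#'   cluster.
#' @export
conserved_markers <- function(norm_a, norm_b, labels_a, labels_b,
                              clusters = NULL, lfc_threshold = 1,
                              pct_threshold = 0.1, ...) {
  la <- resolve_labels(labels_a, norm_a$barcodes)
  lb <- resolve_labels(labels_b, norm_b$barcodes)
  if (is.null(clusters))
    clusters <- intersect(unique(la), unique(lb))
  # a cluster is testable only if nonempty with a nonempty complement in
  # both species
  ok <- vapply(clusters, function(cl) {
    any(la == cl) && !all(la == cl) && any(lb == cl) && !all(lb == cl)
  }, logical(1))
  if (any(!ok))
    warning("skipping cluster(s) without a nonempty group and complement ",
            "in both species: ",
            paste(clusters[!ok], collapse = ", "))
  clusters <- clusters[ok]
  out <- lapply(clusters, function(cl) {
    sa <- cluster_marker_stats(norm_a, stats::setNames(la, norm_a$barcodes),
                               cl, ...)
    sb <- cluster_marker_stats(norm_b, stats::setNames(lb, norm_b$barcodes),
                               cl, ...)
    rec <- combine_conserved(sa, sb, species_a = norm_a$species,
                             species_b = norm_b$species)
    filter_and_rank(rec, lfc_threshold, pct_threshold)
  })
  stats::setNames(out, as.character(clusters))
}

#' Dot-plot table for the top conserved markers
#'
#' For each of the top `top_n` ranked genes, each cluster and each species:
#' the mean normalized expression and the detection percentage -- the
#' numbers behind a marker dot plot, emitted as a plain table.
#'
#' @param ranked a ranked conserved-marker data.frame.
#' @param norm_list named list of `normalized_matrix` objects (one per
#'   species).
#' @param labels_list matching named list of cluster labels.
#' @param top_n gene cap (default 40).
#' @param path optional TSV output path.
#' @return data.frame with columns `gene`, `cluster`, `species`,
#'   `mean_expression`, `pct_detected`.
#' @export
export_dotplot_table <- function(ranked, norm_list, labels_list,
                                 top_n = 40, path = NULL) {
  genes <- head(ranked$gene, top_n)
  rows <- list()
  for (sp in names(norm_list)) {
    norm <- norm_list[[sp]]
    lab <- resolve_labels(labels_list[[sp]], norm$barcodes)
    present <- intersect(genes, norm$gene_symbols)
    if (!length(present)) next
    for (cl in sort(unique(lab))) {
      sel <- lab == cl
      sub <- norm$values[sel, present, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = present, cluster = cl, species = sp,
        mean_expression = as.numeric(Matrix::colSums(sub)) / sum(sel),
        pct_detected = 100 * as.numeric(Matrix::colSums(sub > 0)) / sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), cluster = character(0),
               species = character(0), mean_expression = numeric(0),
               pct_detected = numeric(0))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Write a ranked conserved-marker table as TSV
#'
#' Column layout mirrors the conventional conserved-marker export: per-
#' species raw p, log2FC, pct.1, pct.2, adjusted p, then `max_pval`,
#' `minimump_p_val`, `sum`, `sumLog`, `rang`.
#'
#' @param ranked a ranked conserved-marker data.frame.
#' @param path output TSV path.
#' @export
write_marker_table <- function(ranked, path) {
  df <- ranked
  names(df) <- sub("_pct_1$", "_pct.1", names(df))
  names(df) <- sub("_pct_2$", "_pct.2", names(df))
  names(df)[names(df) == "gene"] <- "Gene"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
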