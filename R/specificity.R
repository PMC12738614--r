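#' Gene-set module score with bin-matched control genes
#'
#' Per-spot signature score in the style of the standard single-cell
#' module-scoring procedure: genes are ranked by their mean normalized
#' expression over all spots and cut into `n_bins` equal-frequency bins;
#' for every signature gene, `n_ctrl` control genes are drawn (with
#' replacement, seeded) from the same bin, excluding signature genes; the
#' score of a spot is the mean of its signature-gene values minus the mean
#' of its pooled control-gene values.
#'
#' @param norm a `normalized_matrix`.
#' @param signature character vector of gene symbols; absent genes are
#'   dropped with a warning.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return a `signature_score`: list with `score` (named per spot),
#'   `signature` (genes used), `control_genes`, `n_bins`, `n_ctrl`,
#'   `seed`.
#' @export
score_module <- function(norm, signature, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  present <- intersect(signature, norm$gene_symbols)
  if (!length(present))
    stop("none of the signature genes are present in the matrix")
  if (length(present) < length(signature))
    warning(length(signature) - length(present),
            " signature gene(s) absent from the matrix; dropped")
  v <- norm$values
  n_genes <- ncol(v)
  gene_means <- Matrix::colSums(v) / nrow(v)
  # equal-frequency bins over the mean-expression ranking
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk * n_bins / n_genes)
  names(bin) <- norm$gene_symbols
  set.seed(seed)
  ctrl <- character(0)
  for (g in present) {
    candidates <- norm$gene_symbols[bin == bin[g]]
    candidates <- setdiff(candidates, present)
    if (!length(candidates)) {
      warning("bin of gene '", g, "' holds only signature genes; ",
              "sampling controls from the full bin")
      candidates <- norm$gene_symbols[bin == bin[g]]
    }
    ctrl <- c(ctrl, sample(candidates, n_ctrl, replace = TRUE))
  }
  sig_mean <- Matrix::rowSums(v[, present, drop = FALSE]) / length(present)
  ctrl_mean <- Matrix::rowSums(v[, ctrl, drop = FALSE]) / length(ctrl)
  structure(list(score = stats::setNames(as.numeric(sig_mean - ctrl_mean),
                                         norm$barcodes),
                 signature = present, control_genes = ctrl,
                 n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = "signature_score")
}

#' ROC AUC by pair counting
#'
#' Area under the ROC curve computed as the normalized Mann--Whitney
#' statistic: the fraction of (positive, negative) pairs in which the
#' positive scores higher, ties counting one half.
#'
#' @param scores numeric scores or a `signature_score`.
#' @param positive logical vector (aligned with scores) or a character
#'   vector of positive-spot names.
#' @return the AUC, a number in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  if (inherits(scores, "signature_score")) scores <- scores$score
  if (is.character(positive)) positive <- names(scores) %in% positive
  if (length(positive) != length(scores))
    stop("scores and class labels differ in length")
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be nonempty")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest log2 fold-change profiles for every cluster
#'
#' For each cluster, the log2 fold change of de-logged mean expression
#' in-cluster vs all other spots, per gene -- the same definition (and
#' code path) as [cluster_marker_stats()], without the rank tests.
#'
#' @param norm a `normalized_matrix`.
#' @param labels cluster labels.
#' @param pseudocount pseudocount inside the ratio (default 1).
#' @return named list mapping cluster id to a named numeric vector of
#'   log2 fold changes per gene.
#' @export
log2fc_profiles <- function(norm, labels, pseudocount = 1) {
  lab <- resolve_labels(labels, norm$barcodes)
  ids <- sort(unique(lab))
  if (length(ids) < 2) stop("need at least 2 clusters for profiles")
  expm1_v <- norm$values
  expm1_v@x <- expm1(expm1_v@x)
  out <- lapply(ids, function(cl) {
    sel <- lab == cl
    mean_in <- Matrix::colSums(expm1_v[sel, , drop = FALSE]) / sum(sel)
    mean_out <- Matrix::colSums(expm1_v[!sel, , drop = FALSE]) / sum(!sel)
    stats::setNames(log2_fold_change(mean_in, mean_out, pseudocount),
                    norm$gene_symbols)
  })
  stats::setNames(out, ids)
}

#' Spearman correlation between two fold-change profiles over a signature
#'
#' Spearman's rank correlation (average ranks for ties) between the two
#' profiles restricted to the signature genes.  Genes missing from either
#' profile are dropped pairwise with a warning; at least 3 shared genes are
#' required.
#'
#' @param ref_profile,cluster_profile named numeric vectors of log2 fold
#'   changes.
#' @param signature character vector of gene symbols.
#' @return Spearman's rho.
#' @export
profile_correlation <- function(ref_profile, cluster_profile, signature) {
  shared <- signature[signature %in% names(ref_profile) &
                      signature %in% names(cluster_profile)]
  if (length(shared) < length(signature))
    warning(length(signature) - length(shared),
            " signature gene(s) missing from a profile; dropped pairwise")
  if (length(shared) < 3)
    stop("fewer than 3 signature genes shared between the profiles")
  cor(ref_profile[shared], cluster_profile[shared], method = "spearman")
}

#' Specificity margin between the target cluster and its runner-up
#'
#' `delta_rho = rho(target) - max(rho(non-target))`; negative when the
#' target cluster is not the best-correlated one.
#'
#' @param rho named numeric vector of per-cluster correlations.
#' @param target name of the target cluster.
#' @return the margin, a single number.
#' @export
specificity_margin <- function(rho, target) {
  if (!target %in% names(rho)) stop("target cluster '", target,
                                    "' not in the correlation map")
  if (length(rho) < 2) stop("need at least 2 clusters")
  as.numeric(rho[target] - max(rho[names(rho) != target]))
}

#' Random-gene-set permutation test for profile correlation
#'
#' In each of `n_perm` iterations, `set_size` genes are sampled without
#' replacement from the background and the Spearman correlation between the
#' two profiles over that set is recorded.  The empirical p-value is the
#' proportion of permuted correlations greater than or equal to the
#' observed one (`k / n_perm`; the `(k + 1) / (n + 1)` estimator is
#' available via `add_one`).
#'
#' @param ref_profile,target_profile named log2 fold-change vectors.
#' @param observed_rho the observed signature correlation.
#' @param set_size genes per random set (default 18).
#' @param n_perm number of iterations (default 5000).
#' @param background character vector of background (expressed) genes;
#'   defaults to the genes shared by both profiles.
#' @param seed integer seed.
#' @param add_one use the `(k + 1) / (n + 1)` estimator.
#' @return list with `perm_rhos` (length `n_perm`) and `empirical_p`.
#' @export
permutation_test <- function(ref_profile, target_profile, observed_rho,
                             set_size = 18, n_perm = 5000,
                             background = NULL, seed = 1L,
                             add_one = FALSE) {
  if (is.null(background))
    background <- intersect(names(ref_profile), names(target_profile))
  background <- background[background %in% names(ref_profile) &
                           background %in% names(target_profile)]
  if (length(background) < set_size)
    stop("background (", length(background),
         ") is smaller than set_size (", set_size, ")")
  set.seed(seed)
  rp <- ref_profile[background]
  tp <- target_profile[background]
  nb <- length(background)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nb, set_size)
    cor(rp[idx], tp[idx], method = "spearman")
  }, numeric(1))
  list(perm_rhos = perm,
       empirical_p = empirical_p(perm, observed_rho, add_one = add_one))
}

#' Empirical p-value from a permutation distribution
#'
#' The proportion of permuted statistics greater than or equal to the
#' observed value.
#'
#' @param perm numeric vector of permuted statistics.
#' @param observed observed statistic.
#' @param add_one use `(k + 1) / (n + 1)` instead of `k / n`.
#' @return the empirical p-value.
#' @export
empirical_p <- function(perm, observed, add_one = FALSE) {
  k <- sum(perm >= observed)
  if (add_one) (k + 1) / (length(perm) + 1) else k / length(perm)
}

#' Full conservation-specificity analysis
#'
#' Quantifies how specifically a cross-species signature marks one cluster
#' of the scored species: per-cluster module-score medians, ROC AUC of the
#' score for the target cluster, Spearman correlations between the
#' reference species' target-cluster log2FC profile and every scored-
#' species cluster profile over the signature, the specificity margin, and
#' a random-gene-set permutation null for the target correlation.
#'
#' @param norm_ref `normalized_matrix` of the reference species (the one
#'   contributing the reference fold-change profile).
#' @param norm_score `normalized_matrix` of the scored species (module
#'   scores and per-cluster profiles are computed here).
#' @param labels_ref,labels_score cluster labels per species.
#' @param signature character vector of signature genes (shared symbols).
#' @param target_cluster cluster id whose conservation is being tested
#'   (must exist in both species' labels).
#' @param n_bins,n_ctrl module-score control parameters.
#' @param set_size,n_perm permutation parameters.
#' @param background background gene set for the permutation; defaults to
#'   genes present in both profiles (i.e. expressed genes that survived
#'   QC in both species).
#' @param seed integer seed (controls and permutations).
#' @return a `specificity_report` list: `median_scores`, `auc`, `rho`,
#'   `delta_rho`, `perm_rhos`, `empirical_p`, `observed_rho`, plus the
#'   parameters used.
#' @export
conservation_specificity <- function(norm_ref, norm_score, labels_ref,
                                     labels_score, signature,
                                     target_cluster, n_bins = 24,
                                     n_ctrl = 100, set_size = 18,
                                     n_perm = 5000, background = NULL,
                                     seed = 1L) {
  lab_s <- resolve_labels(labels_score, norm_score$barcodes)
  scores <- score_module(norm_score, signature, n_bins = n_bins,
                         n_ctrl = n_ctrl, seed = seed)
  med <- tapply(scores$score, lab_s, median)
  med <- stats::setNames(as.numeric(med), names(med))
  auc <- roc_auc(scores$score, lab_s == as.character(target_cluster))
  prof_ref <- log2fc_profiles(norm_ref, labels_ref)
  prof_score <- log2fc_profiles(norm_score, labels_score)
  ref <- prof_ref[[as.character(target_cluster)]]
  if (is.null(ref))
    stop("target cluster '", target_cluster,
         "' absent from the reference species' labels")
  sig_used <- intersect(scores$signature, names(ref))
  rho <- vapply(prof_score, profile_correlation, numeric(1),
                ref_profile = ref, signature = sig_used)
  delta_rho <- specificity_margin(rho, as.character(target_cluster))
  observed <- rho[[as.character(target_cluster)]]
  perm <- permutation_test(ref, prof_score[[as.character(target_cluster)]],
                           observed, set_size = set_size, n_perm = n_perm,
                           background = background, seed = seed)
  structure(list(median_scores = med, auc = auc, rho = rho,
                 delta_rho = delta_rho, observed_rho = observed,
                 perm_rhos = perm$perm_rhos,
                 empirical_p = perm$empirical_p,
                 signature = sig_used, target_cluster = target_cluster,
                 set_size = set_size, n_perm = n_perm, n_bins = n_bins,
                 n_ctrl = n_ctrl, seed = seed),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("specificity_report\n")
  cat(sprintf("  target cluster : %s\n", x$target_cluster))
  cat(sprintf("  AUC            : %.3f\n", x$auc))
  cat(sprintf("  observed rho   : %.3f\n", x$observed_rho))
  cat(sprintf("  delta rho      : %.3f\n", x$delta_rho))
  cat(sprintf("  empirical p    : %g (%d permutations)\n",
              x$empirical_p, x$n_perm))
  invisible(x)
}

#' Serialize a specificity report
#'
#' Scalars and per-cluster tables as JSON; the permutation distribution as
#' a one-column TSV next to it.
#'
#' @param report a `specificity_report`.
#' @param json_path output JSON path.
#' @param perm_path optional TSV path for the permutation distribution.
#' @export
write_specificity_report <- function(report, json_path, perm_path = NULL) {
  payload <- list(
    target_cluster = report$target_cluster,
    auc = report$auc, observed_rho = report$observed_rho,
    delta_rho = report$delta_rho, empirical_p = report$empirical_p,
    median_scores = as.list(report$median_scores),
    rho = as.list(report$rho),
    signature = report$signature,
    params = list(set_size = report$set_size, n_perm = report$n_perm,
                  n_bins = report$n_bins, n_ctrl = report$n_ctrl,
                  seed = report$seed))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(perm_path))
    write.table(data.frame(perm_rho = report$perm_rhos), perm_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}
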