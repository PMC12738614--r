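#' Default pipeline configuration
#'
#' All numeric defaults follow the analysis constants of the workflow:
#' genes kept when detected in at least 1% of filtered spots, 30 principal
#' components, clustering resolution 0.4, conservation filters log2FC > 1
#' and pct > 0.1, and a specificity block with an 18-gene set permuted
#' 5000 times (module scoring with 24 bins and 100 controls per gene).
#'
#' @param ... named overrides; nested keys as `specificity.<key>` for the
#'   specificity block and `sim.<key>` for [sim_config()] overrides used
#'   when inputs are simulated (the seed always follows the pipeline
#'   seed).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input_a = "simulate", input_b = "simulate",
    ortholog_map = NULL,           # path; NULL with simulate = generated
    species_a = "speciesA", species_b = "speciesB",
    labels = "cluster",            # "cluster", "truth", or a TSV path
    scale_factor = 1e4,
    min_gene_fraction = 0.01,
    n_hvg = 2000,
    n_components = 30,
    knn_k = 20,
    prune = 1 / 15,
    resolution = 0.4,
    lfc_threshold = 1,
    pct_threshold = 0.1,
    top_n_dotplot = 40,
    specificity = list(signature = NULL, set_size = 18, n_perm = 5000,
                       n_bins = 24, n_ctrl = 100,
                       target_cluster = NULL, scoring_species = "b"),
    sim = list(),
    seed = 1L,
    out_dir = NULL)
  ov <- list(...)
  for (key in names(ov)) {
    if (grepl("^specificity\\.", key)) {
      cfg$specificity[[sub("^specificity\\.", "", key)]] <- ov[[key]]
    } else if (key == "specificity" && is.list(ov[[key]])) {
      cfg$specificity <- utils::modifyList(cfg$specificity, ov[[key]])
    } else if (grepl("^sim\\.", key)) {
      cfg$sim[[sub("^sim\\.", "", key)]] <- ov[[key]]
    } else if (key == "sim" && is.list(ov[[key]])) {
      cfg$sim <- utils::modifyList(cfg$sim, ov[[key]])
    } else {
      cfg[[key]] <- ov[[key]]
    }
  }
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  req <- c("input_a", "input_b", "min_gene_fraction", "resolution", "seed")
  miss <- req[!req %in% names(cfg) | vapply(cfg[req], is.null, logical(1))]
  if (length(miss))
    stop("pipeline config is missing required key(s): ",
         paste(miss, collapse = ", "))
  if (cfg$min_gene_fraction < 0 || cfg$min_gene_fraction > 1)
    stop("min_gene_fraction must lie in [0, 1]")
  if (cfg$lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (cfg$pct_threshold < 0 || cfg$pct_threshold > 1)
    stop("pct_threshold must lie in [0, 1]")
  if (cfg$resolution <= 0) stop("resolution must be positive")
  invisible(cfg)
}

coerce_config_value <- function(x) {
  if (x %in% c("true", "TRUE", "True")) return(TRUE)
  if (x %in% c("false", "FALSE", "False")) return(FALSE)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  x
}

#' Read a flat key = value pipeline config file
#'
#' One `key = value` pair per line, `#` comments, one nesting level via
#' dotted keys (`specificity.n_perm = 5000`).  Values are coerced to
#' numeric or logical when they parse as such.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- lapply(trimws(vapply(kv, `[`, character(1), 3)),
                 coerce_config_value)
  do.call(pipeline_config, stats::setNames(vals, keys))
}

# Map inferred cluster ids to planted zones by majority vote over the
# truth table.  Returns a named character vector cluster -> zone.
#' Match inferred clusters to planted zones by majority vote
#'
#' @param labels a `cluster_labels` data.frame (barcodes prefixed
#'   `species:barcode` as produced by the pipeline, or bare barcodes).
#' @param spot_truth data.frame with `barcode` and `zone` columns.
#' @return named character vector mapping cluster id to zone.
#' @export
match_clusters_to_zones <- function(labels, spot_truth) {
  bc <- sub("^[^:]*:", "", labels$barcode)
  zone <- spot_truth$zone[match(bc, spot_truth$barcode)]
  tab <- table(labels$cluster, zone)
  zones <- colnames(tab)[apply(tab, 1, which.max)]
  stats::setNames(zones, rownames(tab))
}

pipeline_log <- function(state, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!state$quiet) message(msg)
  if (!is.null(state$log_con)) writeLines(msg, state$log_con)
  invisible(msg)
}

#' Run the full cross-species pipeline
#'
#' Executes, in order: data simulation (or reading of two 10x
#' directories), tissue-presence and minimum-detection QC, ortholog symbol
#' harmonization of species B, log-normalization, joint PCA + SNN graph +
#' Louvain clustering (or user/truth labels), per-cluster conserved-marker
#' detection, and -- when a signature is available -- the conservation-
#' specificity analysis.  All tables, a specificity JSON, a run manifest
#' and a log file are written to `out_dir` when one is configured; reruns
#' with the same config and seed are byte-identical (timestamps live only
#' in the log).
#'
#' @param config a `pipeline_config` (or path to a config file).
#' @param out_dir output directory, overriding `config$out_dir`; `NULL`
#'   writes nothing.
#' @param quiet suppress console messages.
#' @return invisibly, a list with the harmonized matrices, labels,
#'   cluster-to-zone map (simulated data), ranked markers per cluster,
#'   the specificity report and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  state <- new.env()
  state$quiet <- quiet
  state$log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    state$log_con <- file(file.path(out_dir, "run.log"), "wt")
    on.exit(close(state$log_con), add = TRUE)
    writeLines(paste("# run started", format(Sys.time())), state$log_con)
  }
  manifest <- list(package = "orthomark",
                   version = as.character(packageVersion("orthomark")),
                   seed = config$seed,
                   config = unclass(config), stages = list())
  stage_dim <- function(name, x)
    manifest$stages[[name]] <<- list(spots = nrow(x$counts %||% x$values),
                                     genes = ncol(x$counts %||% x$values))

  # ---- stage: input --------------------------------------------------
  sim <- NULL
  if (identical(config$input_a, "simulate")) {
    sim_cfg <- do.call(sim_config,
                       c(config$sim, list(seed = config$seed)))
    sim <- simulate_two_species(sim_cfg)
    sm_a <- sim$a; sm_b <- sim$b
    omap <- sim$ortholog_map
    pipeline_log(state, "simulate: %d + %d spots, %d genes/panel",
                 nrow(sm_a$counts), nrow(sm_b$counts),
                 ncol(sm_a$counts))
  } else {
    sm_a <- read_10x_dir(config$input_a, species = config$species_a)
    sm_b <- read_10x_dir(config$input_b, species = config$species_b)
    if (is.null(config$ortholog_map))
      stop("pipeline config is missing required key(s): ortholog_map")
    omap <- read_ortholog_map(config$ortholog_map)
    pipeline_log(state, "read: %d + %d spots", nrow(sm_a$counts),
                 nrow(sm_b$counts))
  }
  stage_dim("input_a", sm_a); stage_dim("input_b", sm_b)

  # ---- stage: QC -----------------------------------------------------
  sm_a <- filter_spots_in_tissue(sm_a)
  sm_b <- filter_spots_in_tissue(sm_b)
  sm_a <- filter_genes_min_fraction(sm_a, config$min_gene_fraction)
  sm_b <- filter_genes_min_fraction(sm_b, config$min_gene_fraction)
  pipeline_log(state,
               "qc: %d/%d in-tissue spots, %d/%d genes past the %g%% filter",
               nrow(sm_a$counts), nrow(sm_b$counts), ncol(sm_a$counts),
               ncol(sm_b$counts), 100 * config$min_gene_fraction)
  stage_dim("qc_a", sm_a); stage_dim("qc_b", sm_b)

  # ---- stage: ortholog harmonization ---------------------------------
  sm_b <- apply_ortholog_map(sm_b, omap)
  pipeline_log(state, "orthologs: %d species-B genes mapped",
               ncol(sm_b$counts))
  stage_dim("mapped_b", sm_b)

  # ---- stage: normalization ------------------------------------------
  norm_a <- log_normalize(sm_a, config$scale_factor)
  norm_b <- log_normalize(sm_b, config$scale_factor)

  # ---- stage: labels -------------------------------------------------
  shared <- intersect(norm_a$gene_symbols, norm_b$gene_symbols)
  if (identical(config$labels, "cluster")) {
    hvg_a <- select_variable_genes(norm_a, min(config$n_hvg,
                                               ncol(norm_a$values)))
    hvg_b <- select_variable_genes(norm_b, min(config$n_hvg,
                                               ncol(norm_b$values)))
    genes <- intersect(intersect(hvg_a, hvg_b), shared)
    emb <- joint_pca(norm_a, norm_b, genes,
                     n_components = config$n_components)
    graph <- build_snn_graph(emb, k = config$knn_k, prune = config$prune)
    labels <- cluster_graph(graph, resolution = config$resolution,
                            seed = config$seed)
    pipeline_log(state, "cluster: %d clusters at resolution %g over %d HVGs",
                 length(unique(labels$cluster)), config$resolution,
                 length(genes))
  } else if (identical(config$labels, "truth")) {
    if (is.null(sim)) stop("labels = 'truth' requires simulated input")
    bc <- c(paste0(norm_a$species, ":", norm_a$barcodes),
            paste0(norm_b$species, ":", norm_b$barcodes))
    zone <- sim$spot_truth$zone[match(c(norm_a$barcodes, norm_b$barcodes),
                                      sim$spot_truth$barcode)]
    labels <- data.frame(barcode = bc, cluster = zone,
                         stringsAsFactors = FALSE)
  } else {
    labels <- read.delim(config$labels, stringsAsFactors = FALSE)
    if (!all(c("barcode", "cluster") %in% names(labels)))
      stop("label file needs columns 'barcode' and 'cluster'")
  }
  pref_a <- paste0(norm_a$species, ":", norm_a$barcodes)
  pref_b <- paste0(norm_b$species, ":", norm_b$barcodes)
  lab_all <- stats::setNames(as.character(labels$cluster), labels$barcode)
  labels_a <- stats::setNames(lab_all[pref_a], norm_a$barcodes)
  labels_b <- stats::setNames(lab_all[pref_b], norm_b$barcodes)
  zone_map <- if (!is.null(sim)) match_clusters_to_zones(labels,
                                                         sim$spot_truth)
  manifest$cluster_sizes <- as.list(table(labels$cluster))
  if (!is.null(zone_map)) manifest$cluster_zone_map <- as.list(zone_map)

  # ---- stage: conserved markers --------------------------------------
  clusters <- intersect(unique(labels_a), unique(labels_b))
  markers <- conserved_markers(norm_a, norm_b, labels_a, labels_b,
                               clusters = clusters,
                               lfc_threshold = config$lfc_threshold,
                               pct_threshold = config$pct_threshold)
  for (cl in names(markers))
    pipeline_log(state, "markers: cluster %s -> %d conserved genes",
                 cl, nrow(markers[[cl]]))
  manifest$n_conserved <- lapply(markers, nrow)

  # ---- stage: specificity --------------------------------------------
  spec_cfg <- config$specificity
  report <- NULL
  signature <- spec_cfg$signature
  if (is.character(signature) && length(signature) == 1 &&
      file.exists(signature))
    signature <- readLines(signature)
  target <- spec_cfg$target_cluster
  if (is.null(signature) && !is.null(sim)) {
    # default on simulated data: planted shared signature, INNER target
    signature <- sim$signature
    if (is.null(target)) {
      target <- if (!is.null(zone_map) && "INNER" %in% zone_map)
        names(zone_map)[zone_map == "INNER"][1] else "INNER"
    }
  }
  if (!is.null(signature) && !is.null(target) &&
      target %in% labels_a && target %in% labels_b) {
    scoring_b <- !identical(spec_cfg$scoring_species, "a")
    report <- conservation_specificity(
      norm_ref = if (scoring_b) norm_a else norm_b,
      norm_score = if (scoring_b) norm_b else norm_a,
      labels_ref = if (scoring_b) labels_a else labels_b,
      labels_score = if (scoring_b) labels_b else labels_a,
      signature = signature, target_cluster = target,
      n_bins = spec_cfg$n_bins, n_ctrl = spec_cfg$n_ctrl,
      set_size = spec_cfg$set_size, n_perm = spec_cfg$n_perm,
      seed = config$seed)
    pipeline_log(state,
                 "specificity: AUC %.3f, rho %.3f, delta rho %.3f, p %g",
                 report$auc, report$observed_rho, report$delta_rho,
                 report$empirical_p)
  } else {
    pipeline_log(state, "specificity: skipped (no signature/target)")
  }

  # ---- stage: outputs ------------------------------------------------
  if (!is.null(out_dir)) {
    write.table(labels, file.path(out_dir, "cluster_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (cl in names(markers))
      write_marker_table(markers[[cl]],
                         file.path(out_dir,
                                   sprintf("markers_%s.tsv", cl)))
    ranked_all <- if (length(markers)) do.call(rbind, markers) else
      data.frame(gene = character(0), rang = numeric(0))
    ranked_all <- ranked_all[order(-ranked_all$rang, ranked_all$gene), ]
    export_dotplot_table(
      ranked_all,
      stats::setNames(list(norm_a, norm_b),
                      c(norm_a$species, norm_b$species)),
      stats::setNames(list(labels_a, labels_b),
                      c(norm_a$species, norm_b$species)),
      top_n = config$top_n_dotplot,
      path = file.path(out_dir, "dotplot.tsv"))
    if (!is.null(report))
      write_specificity_report(report,
                               file.path(out_dir, "specificity.json"),
                               file.path(out_dir, "perm_rhos.tsv"))
    if (!is.null(sim)) {
      write.table(sim$gene_truth, file.path(out_dir, "gene_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(sim$spot_truth, file.path(out_dir, "spot_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(norm_a = norm_a, norm_b = norm_b, labels = labels,
                 labels_a = labels_a, labels_b = labels_b,
                 zone_map = zone_map, markers = markers,
                 specificity = report, sim = sim, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a spatial feature table for one gene
#'
#' The plot-ready table behind a spatial feature map: barcode, lattice and
#' pixel coordinates and the normalized expression value over in-tissue
#' spots.
#'
#' @param norm a `normalized_matrix` with a positions table.
#' @param gene gene symbol.
#' @param path optional TSV output path.
#' @return data.frame with columns `barcode`, `array_row`, `array_col`,
#'   `pxl_row`, `pxl_col`, `value`.
#' @export
export_spatial_feature <- function(norm, gene, path = NULL) {
  if (!gene %in% norm$gene_symbols) {
    near <- norm$gene_symbols[order(utils::adist(gene,
                                                 norm$gene_symbols))][1:3]
    stop("unknown gene '", gene, "'; nearest symbols: ",
         paste(near, collapse = ", "))
  }
  if (is.null(norm$positions)) stop("no positions table attached")
  pos <- norm$positions
  keep <- pos$in_tissue > 0
  out <- data.frame(barcode = pos$barcode[keep],
                    array_row = pos$array_row[keep],
                    array_col = pos$array_col[keep],
                    pxl_row = pos$pxl_row[keep],
                    pxl_col = pos$pxl_col[keep],
                    value = as.numeric(norm$values[keep, gene]),
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Evaluate conserved-marker recovery against simulation truth
#'
#' Precision and recall of the detected conserved markers per zone,
#' against the generator's planted conserved genes, plus how many planted
#' species-specific markers slipped through the both-species filter.
#'
#' @param markers named list of ranked marker tables (cluster id ->
#'   data.frame), as returned inside [run_pipeline()].
#' @param gene_truth the generator's gene-truth table.
#' @param zone_map named vector mapping cluster ids to zones (identity for
#'   truth labels).
#' @return list with `precision`, `recall`, `n_species_specific_passed`,
#'   and the per-zone counts.
#' @export
evaluate_marker_recovery <- function(markers, gene_truth, zone_map) {
  tp <- 0L; fp <- 0L; fn <- 0L; specific_passed <- 0L
  per_zone <- list()
  for (cl in names(markers)) {
    zone <- zone_map[[cl]]
    if (is.null(zone) || is.na(zone)) next
    found <- markers[[cl]]$gene
    planted <- gene_truth$symbol_a[gene_truth$status == "conserved" &
                                   gene_truth$home_zone == zone]
    specific <- gene_truth$symbol_a[gene_truth$status %in%
                                    c("species_a", "species_b")]
    tp_z <- sum(found %in% planted)
    tp <- tp + tp_z
    fp <- fp + sum(!found %in% planted)
    fn <- fn + sum(!planted %in% found)
    specific_passed <- specific_passed + sum(found %in% specific)
    per_zone[[zone]] <- c(found = length(found), planted = length(planted),
                          true_positive = tp_z)
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       n_species_specific_passed = specific_passed,
       per_zone = per_zone)
}
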