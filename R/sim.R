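#' Configuration for the two-species synthetic dataset
#'
#' Describes a Visium-like lattice with concentric anatomical zones around a
#' center (medulla innermost, then the inner cortical zone -- ZR in species A,
#' BAT in species B -- then ZF, ZG, and a connective tissue / white adipose
#' rim), a gene panel with zone-enriched markers planted per species, and a
#' negative-binomial count model.  Defaults give roughly 1000 in-tissue spots
#' per species, mimicking one capture area per species at desk scale.
#'
#' @param n_rows,n_cols lattice size (spots are lattice points).
#' @param center lattice coordinates of the gland center.
#' @param radii strictly increasing distance thresholds delimiting, from the
#'   center outwards, MEDULLA, INNER, ZF, ZG and CTWAT; beyond the last
#'   radius spots are off-tissue.
#' @param bat_patch integer vector `(row0, row1, col0, col1)` of an
#'   off-gland rectangle that species B carves out as INNER (brown adipose
#'   tissue lying outside the gland); `NULL` disables it.
#' @param n_genes_total panel size per species (panels are index-paired via
#'   the synthetic ortholog map).
#' @param n_markers_per_zone planted markers per zone and species.
#' @param n_conserved_per_zone how many of those are conserved, i.e. planted
#'   in the same zone of both species; the remainder is split into
#'   species-A-only and species-B-only markers (`n_markers_per_zone -
#'   n_conserved_per_zone` of each).
#' @param fold_range multiplicative fold-change range for planted markers;
#'   draws are uniform on this interval.  Zonal markers in tissue data show
#'   strong enrichment, so the default spans 4--16.
#' @param fold_jitter_sdlog log-normal sigma of the per-species divergence
#'   applied to a conserved marker's shared fold change; 0.2 keeps the two
#'   species' effect sizes similar but not identical.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for
#'   background gene baseline means (counts per spot at unit library size).
#' @param marker_meanlog,marker_sdlog log-normal parameters for marker gene
#'   baselines; markers are modelled as moderately-to-well expressed genes.
#' @param dispersion negative-binomial size parameter (shared across genes).
#' @param libsize_sdlog log-normal sigma of per-spot library-size factors.
#' @param offtissue_factor library-size multiplier for off-tissue spots.
#' @param ortholog_missing_rate probability that a species-B gene has no
#'   ortholog mapping.
#' @param ortholog_duplicate_rate probability that a species-B gene's target
#'   symbol additionally receives a second species-B source gene.
#' @param signature_size number of conserved INNER markers reported as the
#'   planted cross-species signature (18 by default).
#' @param seed integer seed recorded in the truth tables and used by
#'   [simulate_two_species()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 41, n_cols = 41, center = c(20, 20),
                       radii = c(5, 9, 13, 16, 18),
                       bat_patch = c(0, 6, 0, 6),
                       n_genes_total = 1200,
                       n_markers_per_zone = 30,
                       n_conserved_per_zone = 20,
                       fold_range = c(4, 16),
                       baseline_meanlog = log(0.5), baseline_sdlog = 1,
                       marker_meanlog = log(2), marker_sdlog = 0.5,
                       fold_jitter_sdlog = 0.2,
                       dispersion = 2,
                       libsize_sdlog = 0.3,
                       offtissue_factor = 0.2,
                       ortholog_missing_rate = 0.05,
                       ortholog_duplicate_rate = 0.02,
                       signature_size = 18,
                       seed = 1L) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols, center = center,
              radii = radii, bat_patch = bat_patch,
              n_genes_total = n_genes_total,
              n_markers_per_zone = n_markers_per_zone,
              n_conserved_per_zone = n_conserved_per_zone,
              fold_range = fold_range,
              fold_jitter_sdlog = fold_jitter_sdlog,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              marker_meanlog = marker_meanlog,
              marker_sdlog = marker_sdlog,
              dispersion = dispersion, libsize_sdlog = libsize_sdlog,
              offtissue_factor = offtissue_factor,
              ortholog_missing_rate = ortholog_missing_rate,
              ortholog_duplicate_rate = ortholog_duplicate_rate,
              signature_size = signature_size, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$radii) != 5 || any(diff(cfg$radii) <= 0))
    stop("radii must be 5 strictly increasing distance thresholds")
  if (cfg$n_rows < 1 || cfg$n_cols < 1) stop("lattice must be nonempty")
  rates <- c(cfg$ortholog_missing_rate, cfg$ortholog_duplicate_rate)
  if (any(rates < 0 | rates > 1)) stop("ortholog rates must lie in [0, 1]")
  if (any(cfg$fold_range < 1)) stop("fold_range must be >= 1")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$n_conserved_per_zone > cfg$n_markers_per_zone)
    stop("n_conserved_per_zone cannot exceed n_markers_per_zone")
  n_spec <- cfg$n_markers_per_zone - cfg$n_conserved_per_zone
  need <- length(ZONE_LEVELS) * (cfg$n_conserved_per_zone + 2 * n_spec)
  if (need > cfg$n_genes_total)
    stop("gene panel too small for the requested markers (needs >= ",
         need, ")")
  invisible(cfg)
}

#' Lay out concentric anatomical zones on a spot lattice
#'
#' Assigns each lattice point to a zone by Euclidean distance from the
#' configured center: `d < r1` MEDULLA, `r1 <= d < r2` INNER, `r2 <= d < r3`
#' ZF, `r3 <= d < r4` ZG, `r4 <= d < r5` CTWAT, `d >= r5` off-tissue.
#' Species `"B"` additionally marks the configured off-gland rectangle as
#' in-tissue INNER (brown adipose tissue sitting next to the gland).
#'
#' @param config a [sim_config()].
#' @param species `"A"` or `"B"`.
#' @return data.frame with columns `spot_id`, `array_row`, `array_col`,
#'   `pxl_row`, `pxl_col`, `in_tissue`, `zone`.
#' @export
build_zone_layout <- function(config, species = c("A", "B")) {
  species <- match.arg(species)
  validate_sim_config(config)
  grid <- expand.grid(array_row = seq_len(config$n_rows) - 1L,
                      array_col = seq_len(config$n_cols) - 1L,
                      KEEP.OUT.ATTRS = FALSE)
  d <- sqrt((grid$array_row - config$center[1])^2 +
            (grid$array_col - config$center[2])^2)
  r <- config$radii
  zone <- rep(ZONE_NONE, nrow(grid))
  zone[d < r[5]] <- "CTWAT"
  zone[d < r[4]] <- "ZG"
  zone[d < r[3]] <- "ZF"
  zone[d < r[2]] <- "INNER"
  zone[d < r[1]] <- "MEDULLA"
  if (species == "B" && !is.null(config$bat_patch)) {
    p <- config$bat_patch
    in_patch <- grid$array_row >= p[1] & grid$array_row <= p[2] &
      grid$array_col >= p[3] & grid$array_col <= p[4]
    zone[in_patch] <- "INNER"
  }
  data.frame(
    spot_id = sprintf("SP%s-%05d", species, seq_len(nrow(grid))),
    array_row = grid$array_row, array_col = grid$array_col,
    pxl_row = grid$array_row * 100 + 50,
    pxl_col = grid$array_col * 100 + 50,
    in_tissue = as.integer(zone != ZONE_NONE),
    zone = zone, stringsAsFactors = FALSE)
}

#' Draw the ground-truth gene table for a simulation
#'
#' Gene panels of the two species are index-paired: gene `i` carries symbol
#' `GAxxxx` in species A and `gbxxxx` in species B.  Markers occupy the
#' leading indices, grouped by zone; a conserved marker is planted (fold
#' drawn from `fold_range`, independently per species) in the same home zone
#' of both species, a species-specific marker in one species only.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return data.frame with one row per gene: `symbol_a`, `symbol_b`,
#'   `status` (conserved / species_a / species_b / background), `home_zone`,
#'   `fold_a`, `fold_b`, `baseline_mean`.
#' @export
simulate_gene_truth <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_genes_total
  n_spec <- config$n_markers_per_zone - config$n_conserved_per_zone
  status <- rep("background", N)
  home <- rep(NA_character_, N)
  ptr <- 1L
  take <- function(n) {
    if (n == 0) return(integer(0))
    idx <- ptr:(ptr + n - 1L); ptr <<- ptr + n; idx
  }
  for (z in ZONE_LEVELS) {
    i <- take(config$n_conserved_per_zone)
    status[i] <- "conserved"; home[i] <- z
    i <- take(n_spec); status[i] <- "species_a"; home[i] <- z
    i <- take(n_spec); status[i] <- "species_b"; home[i] <- z
  }
  is_marker <- status != "background"
  baseline <- numeric(N)
  baseline[is_marker] <- rlnorm(sum(is_marker), config$marker_meanlog,
                                config$marker_sdlog)
  baseline[!is_marker] <- rlnorm(sum(!is_marker), config$baseline_meanlog,
                                 config$baseline_sdlog)
  fold_a <- rep(1, N); fold_b <- rep(1, N)
  # Conserved markers share one effect size across species, diverged by a
  # mild log-normal jitter -- that shared ordering is what makes the
  # planted signature's cross-species fold-change profiles correlate.
  cons <- status == "conserved"
  base_fold <- runif(sum(cons), config$fold_range[1], config$fold_range[2])
  jitter <- function(n) exp(rnorm(n, 0, config$fold_jitter_sdlog))
  fold_a[cons] <- pmax(base_fold * jitter(sum(cons)), 1)
  fold_b[cons] <- pmax(base_fold * jitter(sum(cons)), 1)
  only_a <- status == "species_a"
  only_b <- status == "species_b"
  fold_a[only_a] <- runif(sum(only_a), config$fold_range[1],
                          config$fold_range[2])
  fold_b[only_b] <- runif(sum(only_b), config$fold_range[1],
                          config$fold_range[2])
  data.frame(
    symbol_a = sprintf("GA%04d", seq_len(N)),
    symbol_b = sprintf("gb%04d", seq_len(N)),
    status = status, home_zone = home,
    fold_a = fold_a, fold_b = fold_b,
    baseline_mean = baseline, stringsAsFactors = FALSE)
}

#' Simulate negative-binomial counts for one species
#'
#' Count of gene g in spot s is drawn from a negative binomial with mean
#' `baseline_mean(g) * library_factor(s) * fold(g, s)` and size
#' `dispersion`, where the fold is the planted fold change when the spot's
#' zone is the gene's home zone and 1 otherwise.  Off-tissue spots get a
#' reduced library factor (`offtissue_factor`) and never match a home zone.
#'
#' @param layout a zone layout from [build_zone_layout()].
#' @param truth a gene-truth table from [simulate_gene_truth()].
#' @param config a [sim_config()].
#' @param species `"A"` or `"B"`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return a [spot_matrix()] covering every lattice spot (QC filtering is
#'   the consumer's job), with the positions table attached.
#' @export
simulate_species_counts <- function(layout, truth, config,
                                    species = c("A", "B"), seed = NULL) {
  species <- match.arg(species)
  if (nrow(layout) == 0) stop("empty layout")
  if (!is.null(seed)) set.seed(seed)
  fold <- if (species == "A") truth$fold_a else truth$fold_b
  planted <- fold > 1
  if (any(planted & !(truth$home_zone %in% c(layout$zone, NA))))
    stop("a planted marker's home zone is absent from the layout")
  n <- nrow(layout); g <- nrow(truth)
  lib <- rlnorm(n, 0, config$libsize_sdlog)
  lib[layout$in_tissue == 0] <- lib[layout$in_tissue == 0] *
    config$offtissue_factor
  # spots x genes mean matrix: outer baseline*lib, then zone-matched folds
  mu <- outer(lib, truth$baseline_mean)
  for (j in which(planted)) {
    hit <- layout$zone == truth$home_zone[j]
    mu[hit, j] <- mu[hit, j] * fold[j]
  }
  counts <- matrix(rnbinom(n * g, mu = as.vector(mu),
                           size = config$dispersion), nrow = n)
  symbols <- if (species == "A") truth$symbol_a else truth$symbol_b
  positions <- data.frame(barcode = layout$spot_id,
                          in_tissue = layout$in_tissue,
                          array_row = layout$array_row,
                          array_col = layout$array_col,
                          pxl_row = layout$pxl_row,
                          pxl_col = layout$pxl_col,
                          stringsAsFactors = FALSE)
  spot_matrix(counts, layout$spot_id, symbols,
              species = paste0("species_", species), positions = positions)
}

#' Build a synthetic ortholog map with missing and duplicated targets
#'
#' Each species-B gene maps to its index-paired species-A symbol with
#' probability `1 - ortholog_missing_rate`.  Independently, with probability
#' `ortholog_duplicate_rate` per gene, a second species-B gene (drawn from
#' the non-event genes, overriding its own mapping) is pointed at the same
#' species-A symbol and flagged as a duplicate target -- emulating
#' many-to-one ortholog relationships.
#'
#' @param truth a gene-truth table from [simulate_gene_truth()].
#' @param config a [sim_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return data.frame with columns `source` (species-B symbol), `target`
#'   (species-A symbol) and `is_duplicate_target`.
#' @export
build_synthetic_ortholog_map <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(truth)
  target <- truth$symbol_a
  mapped <- runif(N) >= config$ortholog_missing_rate
  dup_flag <- rep(FALSE, N)
  events <- which(runif(N) < config$ortholog_duplicate_rate)
  pool <- setdiff(seq_len(N), events)
  if (length(events) > length(pool)) {
    warning("not enough genes to host all duplicate-target events; capping")
    events <- events[seq_along(pool)]
  }
  if (length(events)) {
    j <- if (length(pool) == 1) pool else sample(pool, length(events))
    target[j] <- truth$symbol_a[events]
    mapped[j] <- TRUE
    dup_flag[j] <- TRUE
  }
  data.frame(source = truth$symbol_b[mapped], target = target[mapped],
             is_duplicate_target = dup_flag[mapped],
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-species dataset
#'
#' Runs the full generator under a single seeded RNG stream: gene truth,
#' both zone layouts, both count matrices and the ortholog map.  The
#' planted cross-species signature is the first `signature_size` conserved
#' INNER markers (species-A symbols).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_data` with elements `a`, `b` (spot matrices),
#'   `ortholog_map`, `gene_truth`, `spot_truth` (barcode, species, zone),
#'   `signature` and `config`.
#' @export
simulate_two_species <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  truth <- simulate_gene_truth(config)
  layout_a <- build_zone_layout(config, "A")
  layout_b <- build_zone_layout(config, "B")
  sm_a <- simulate_species_counts(layout_a, truth, config, "A")
  sm_b <- simulate_species_counts(layout_b, truth, config, "B")
  omap <- build_synthetic_ortholog_map(truth, config)
  spot_truth <- rbind(
    data.frame(barcode = layout_a$spot_id, species = sm_a$species,
               zone = layout_a$zone, stringsAsFactors = FALSE),
    data.frame(barcode = layout_b$spot_id, species = sm_b$species,
               zone = layout_b$zone, stringsAsFactors = FALSE))
  sig_pool <- truth$symbol_a[truth$status == "conserved" &
                             truth$home_zone == "INNER"]
  signature <- head(sig_pool, config$signature_size)
  structure(list(a = sm_a, b = sm_b, ortholog_map = omap,
                 gene_truth = truth, spot_truth = spot_truth,
                 signature = signature, config = config),
            class = "sim_data")
}

#' Write a simulated dataset to disk in 10x-style formats
#'
#' Emits `speciesA/` and `speciesB/` 10x triplet directories (plus tissue
#' positions), the ortholog map, both truth tables as TSV and the config as
#' a flat `key = value` file.
#'
#' @param sim a `sim_data` object from [simulate_two_species()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x_dir(sim$a, file.path(dir, "speciesA"))
  write_10x_dir(sim$b, file.path(dir, "speciesB"))
  write_ortholog_map(sim$ortholog_map, file.path(dir, "ortholog_map.tsv"))
  write.table(sim$gene_truth, file.path(dir, "gene_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$spot_truth, file.path(dir, "spot_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  keys <- names(cfg)
  vals <- vapply(cfg, function(v) paste(format(v, digits = 15),
                                        collapse = ","), character(1))
  writeLines(paste(keys, "=", vals), file.path(dir, "config.txt"))
  invisible(dir)
}
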