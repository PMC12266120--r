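# Synthetic four-group parabiosis scRNA-seq generator.
#
# Counts are gamma-Poisson (negative binomial) with a single global
# inverse-dispersion and log-normal per-cell depth. Group/type effects are
# additive on log2 mean expression *before* depth scaling, so every planted
# effect is directly interpretable as an expected log2 fold change:
#   Yiso = baseline
#   Aiso = baseline + aging effect
#   Ahet = Aiso - rescue_magnitude * aging effect   (rescued subset only)
#   Yhet = Yiso + accel_magnitude * aging effect    (accelerated subset only)

# Baseline abundance tiers (relative units, rescaled to mean_libsize).
# Aging programs and markers are planted only in tiers >= 1 so planted
# effects are identifiable at the study's sequencing depth.
BASE_TIERS <- c(0.1, 0.3, 1, 3, 10, 30)
BASE_TIER_PROBS <- c(0.35, 0.25, 0.18, 0.12, 0.07, 0.03)

#' Parameters of the synthetic parabiosis dataset generator
#'
#' @param n_cell_types Number of planted cell types (labelled `T1`, `T2`, ...).
#' @param cells_per_group_per_type Cells simulated for each (group, type).
#' @param n_genes Total genes.
#' @param markers_per_type Marker genes per type, up-regulated only in their
#'   own type (zero cross-type leakage).
#' @param marker_log2_effect Marker up-shift (log2 units).
#' @param program_size Aging-program genes per cell type.
#' @param aging_effect Magnitude of each planted aging effect (log2 units);
#'   sign is per gene, up with probability `prop_up`.
#' @param prop_up Fraction of program genes up-regulated in aging.
#' @param rescue_fraction Fraction of each type's aging program reverted in
#'   Ahet; scalar or one value per cell type.
#' @param rescue_magnitude Fraction of the aging effect reverted on rescued
#'   genes (1 = full reversion to the young mean).
#' @param accel_fraction,accel_magnitude Analogous acceleration of the young
#'   heterochronic group toward the aged state.
#' @param hub_gene Symbol of a designated recurrent-rescue gene, planted
#'   (and rescued) in `hub_n_types` cell types' aging programs.
#' @param hub_n_types Number of cell types whose program carries the hub gene.
#' @param dispersion Negative-binomial inverse-dispersion (`size`);
#'   variance = mu + mu^2 / dispersion.
#' @param mean_libsize Expected total counts per cell.
#' @param libsize_sigma Log-normal sd of per-cell depth factors.
#' @param mito_fraction Fraction of genes carrying the `mt-` prefix; their
#'   abundance is set so mitochondrial counts average ~8% of each cell.
#' @param qc_fail_fraction Fraction of cells forced to detect fewer than 200
#'   genes, to exercise the QC filter.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n_cell_types = 3,
                             cells_per_group_per_type = 200,
                             n_genes = 1000,
                             markers_per_type = 20,
                             marker_log2_effect = 2,
                             program_size = 60,
                             aging_effect = 1,
                             prop_up = 0.5,
                             rescue_fraction = 0.5,
                             rescue_magnitude = 1,
                             accel_fraction = 0.5,
                             accel_magnitude = 1,
                             hub_gene = "Adipor1",
                             hub_n_types = min(3L, n_cell_types),
                             dispersion = 5,
                             mean_libsize = 2000,
                             libsize_sigma = 0.3,
                             mito_fraction = 0.02,
                             qc_fail_fraction = 0,
                             seed = 1L) {
  p <- list(n_cell_types = as.integer(n_cell_types),
            cells_per_group_per_type = as.integer(cells_per_group_per_type),
            n_genes = as.integer(n_genes),
            markers_per_type = as.integer(markers_per_type),
            marker_log2_effect = marker_log2_effect,
            program_size = as.integer(program_size),
            aging_effect = aging_effect,
            prop_up = prop_up,
            rescue_fraction = rep_len(rescue_fraction, n_cell_types),
            rescue_magnitude = rescue_magnitude,
            accel_fraction = rep_len(accel_fraction, n_cell_types),
            accel_magnitude = accel_magnitude,
            hub_gene = hub_gene,
            hub_n_types = as.integer(hub_n_types),
            dispersion = dispersion,
            mean_libsize = mean_libsize,
            libsize_sigma = libsize_sigma,
            mito_fraction = mito_fraction,
            qc_fail_fraction = qc_fail_fraction,
            seed = as.integer(seed))
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  if (p$n_cell_types < 1L || p$cells_per_group_per_type < 1L || p$n_genes < 10L) {
    stop_fmt("counts parameters must be positive (n_genes >= 10)")
  }
  fr <- c(p$rescue_fraction, p$accel_fraction, p$rescue_magnitude,
          p$accel_magnitude, p$prop_up, p$mito_fraction, p$qc_fail_fraction)
  if (any(fr < 0 | fr > 1)) stop_fmt("fractions and magnitudes must lie in [0, 1]")
  if (p$mean_libsize <= 0 || p$dispersion <= 0 || p$libsize_sigma < 0) {
    stop_fmt("mean_libsize and dispersion must be positive; libsize_sigma >= 0")
  }
  if (p$marker_log2_effect < 0 || p$aging_effect < 0) {
    stop_fmt("effect magnitudes must be >= 0 (direction is drawn per gene)")
  }
  if (p$hub_n_types > p$n_cell_types) {
    stop_fmt("hub_n_types (%d) exceeds n_cell_types (%d)",
             p$hub_n_types, p$n_cell_types)
  }
  invisible(p)
}

#' Generate a four-group parabiosis dataset with planted ground truth
#'
#' @param params A [generator_params()] object.
#' @return A list with elements `sce` (a `SingleCellExperiment`, genes x
#'   cells, assay `counts`, annotation in `colData`), `annotation`
#'   (data.frame) and `truth` (a `ground_truth`: `$genes` gene-by-cell-type
#'   grid with membership and planted effects, `$cells`, `$hub`, `$params`).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  validate_generator_params(params)
  with_seed(params$seed, build_dataset(params))
}

build_dataset <- function(p) {
  types <- sprintf("T%d", seq_len(p$n_cell_types))
  genes <- sprintf("g%04d", seq_len(p$n_genes))

  n_mito <- round(p$mito_fraction * p$n_genes)
  mito_idx <- if (n_mito > 0) seq_len(n_mito) else integer(0)
  if (n_mito > 0) genes[mito_idx] <- sprintf("mt-g%04d", mito_idx)

  # baseline abundances: tier grid, mito mass pinned near 8% of the cell
  tier <- sample(BASE_TIERS, p$n_genes, replace = TRUE, prob = BASE_TIER_PROBS)
  if (n_mito > 0) {
    s_other <- sum(tier[-mito_idx])
    tier[mito_idx] <- 0.08 * s_other / (0.92 * n_mito)
  }

  pool <- setdiff(which(tier >= 1), mito_idx)
  need <- p$n_cell_types * p$markers_per_type + p$program_size + 1L
  if (length(pool) < need) {
    stop_fmt("expressed-gene pool too small (%d) for %d markers/type x %d types + program of %d",
             length(pool), p$markers_per_type, p$n_cell_types, p$program_size)
  }

  marker_idx <- matrix(sample(pool, p$n_cell_types * p$markers_per_type),
                       nrow = p$markers_per_type)
  colnames(marker_idx) <- types
  pool <- setdiff(pool, marker_idx)

  hub_idx <- if (p$hub_n_types > 0) sample(pool, 1L) else NA_integer_
  if (!is.na(hub_idx)) genes[hub_idx] <- p$hub_gene
  hub_types <- if (p$hub_n_types > 0) sort(sample(types, p$hub_n_types)) else character(0)

  # per-type aging programs: signed planted effects, rescued/accelerated subsets
  truth_genes <- do.call(rbind, lapply(seq_along(types), function(ti) {
    tp <- types[[ti]]
    g <- data.frame(gene = genes, cell_type = tp, membership = "background",
                    aging_effect = 0, ahet_effect = 0, yhet_effect = 0,
                    rescued = FALSE, accelerated = FALSE,
                    stringsAsFactors = FALSE)
    g$membership[marker_idx[, tp]] <- "marker"
    prog <- integer(0)
    if (p$program_size > 0) {
      draw_pool <- setdiff(pool, hub_idx)
      prog <- sample(draw_pool, p$program_size)
      if (tp %in% hub_types) prog <- c(hub_idx, prog[-1L])
    }
    if (length(prog)) {
      sgn <- ifelse(stats::runif(length(prog)) < p$prop_up, 1, -1)
      if (!is.na(hub_idx) && hub_idx %in% prog) sgn[prog == hub_idx] <- 1
      g$membership[prog] <- "aging"
      g$aging_effect[prog] <- sgn * p$aging_effect
      n_resc <- round(p$rescue_fraction[[ti]] * length(prog))
      resc <- if (n_resc > 0) sample(prog, n_resc) else integer(0)
      if (tp %in% hub_types && !is.na(hub_idx)) resc <- union(resc, hub_idx)
      g$rescued[resc] <- TRUE
      g$ahet_effect[resc] <- -p$rescue_magnitude * g$aging_effect[resc]
      n_acc <- round(p$accel_fraction[[ti]] * length(prog))
      acc <- if (n_acc > 0) sample(prog, n_acc) else integer(0)
      g$accelerated[acc] <- TRUE
      g$yhet_effect[acc] <- p$accel_magnitude * g$aging_effect[acc]
    }
    g
  }))
  rownames(truth_genes) <- NULL

  base <- tier / sum(tier) * p$mean_libsize

  n_per <- p$cells_per_group_per_type
  n_cells <- p$n_cell_types * 4L * n_per
  cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  cell_type <- rep(types, each = 4L * n_per)
  group <- rep(rep(HP_GROUPS, each = n_per), times = p$n_cell_types)
  depth <- stats::rlnorm(n_cells, meanlog = -p$libsize_sigma^2 / 2,
                         sdlog = p$libsize_sigma)

  counts <- matrix(0, nrow = p$n_genes, ncol = n_cells,
                   dimnames = list(genes, cell_id))
  for (tp in types) {
    tg <- truth_genes[truth_genes$cell_type == tp, ]
    for (gr in HP_GROUPS) {
      delta <- p$marker_log2_effect * (tg$membership == "marker")
      if (gr %in% c("Aiso", "Ahet")) delta <- delta + tg$aging_effect
      if (gr == "Ahet") delta <- delta + tg$ahet_effect
      if (gr == "Yhet") delta <- delta + tg$yhet_effect
      cols <- which(cell_type == tp & group == gr)
      mu <- outer(base * 2^delta, depth[cols])
      counts[, cols] <- stats::rnbinom(length(mu), mu = mu, size = p$dispersion)
    }
  }

  qc_fail <- rep(FALSE, n_cells)
  if (p$qc_fail_fraction > 0) {
    fail <- sample(n_cells, round(p$qc_fail_fraction * n_cells))
    qc_fail[fail] <- TRUE
    keep <- utils::head(order(base, decreasing = TRUE), 150L)
    drop <- setdiff(seq_len(p$n_genes), keep)
    counts[drop, fail] <- 0
  }

  ann <- data.frame(cell_id = cell_id, group = group, cell_type = cell_type,
                    stringsAsFactors = FALSE)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(counts, "CsparseMatrix")))
  sce <- set_annotation(sce, ann)

  truth <- structure(list(
    genes = truth_genes,
    cells = data.frame(cell_id = cell_id, group = group, cell_type = cell_type,
                       qc_fail = qc_fail, stringsAsFactors = FALSE),
    hub = list(gene = if (is.na(hub_idx)) NA_character_ else p$hub_gene,
               cell_types = hub_types),
    base_mean = stats::setNames(base, genes),
    params = p), class = "ground_truth")

  list(sce = sce, annotation = ann, truth = truth)
}

#' Generate a null dataset (no planted effects anywhere)
#'
#' Convenience wrapper around [generate_dataset()] with marker and aging
#' effects forced to zero; the returned ground truth marks every gene
#' background and carries no hub gene.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset()].
#' @export
null_dataset <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  p$marker_log2_effect <- 0
  p$aging_effect <- 0
  ds <- generate_dataset(p)
  tg <- ds$truth$genes
  tg$membership <- "background"
  tg$aging_effect <- tg$ahet_effect <- tg$yhet_effect <- 0
  tg$rescued <- tg$accelerated <- FALSE
  ds$truth$genes <- tg
  ds$truth$hub <- list(gene = NA_character_, cell_types = character(0))
  ds
}

#' Marker gene sets of a simulated dataset
#' @param truth A `ground_truth` object.
#' @return A `gene_set_collection` with one marker set per planted cell type.
#' @export
marker_sets <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tg <- truth$genes[truth$genes$membership == "marker", ]
  if (!nrow(tg)) stop_fmt("ground truth contains no marker genes")
  sets <- split(tg$gene, tg$cell_type)
  gene_set_collection("planted_markers", sets[sort(names(sets))])
}

#' Planted aging-program genes of one cell type
#' @param truth A `ground_truth` object.
#' @param cell_type Cell-type label.
#' @param direction `"any"`, `"up"` or `"down"` (by aging direction).
#' @return Character vector of gene symbols.
#' @export
program_genes <- function(truth, cell_type, direction = c("any", "up", "down")) {
  stopifnot(inherits(truth, "ground_truth"))
  direction <- match.arg(direction)
  tg <- truth$genes[truth$genes$cell_type == cell_type &
                      truth$genes$membership == "aging", ]
  if (direction == "up") tg <- tg[tg$aging_effect > 0, ]
  if (direction == "down") tg <- tg[tg$aging_effect < 0, ]
  tg$gene
}

#' Write a simulated dataset bundle to disk
#'
#' Writes the Matrix Market counts bundle, annotation TSV, ground-truth TSV
#' and generator parameters JSON.
#'
#' @param ds Result of [generate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset_bundle <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(ds$sce, dir)
  write_annotation(ds$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(ds$truth$genes, file.path(dir, "ground_truth.tsv"))
  write_tsv(ds$truth$cells, file.path(dir, "ground_truth_cells.tsv"))
  pr <- ds$truth$params
  class(pr) <- NULL
  write_run_meta(pr, file.path(dir, "params.json"))
  invisible(dir)
}

#' Read back a dataset bundle written by [write_dataset_bundle()]
#'
#' Reconstructs the `SingleCellExperiment` (with annotation attached) and
#' the `ground_truth` object, so any downstream stage can be re-run from
#' saved intermediates.
#'
#' @param dir Bundle directory.
#' @return A list `sce`, `annotation`, `truth` as from [generate_dataset()].
#' @export
read_dataset_bundle <- function(dir) {
  sce <- read_counts(file.path(dir, "matrix.mtx"),
                     file.path(dir, "genes.tsv"),
                     file.path(dir, "cells.tsv"))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  sce <- set_annotation(sce, ann)
  genes <- utils::read.delim(file.path(dir, "ground_truth.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "ground_truth_cells.tsv"),
                             stringsAsFactors = FALSE)
  pars <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  hub_types <- sort(unique(genes$cell_type[genes$gene == pars$hub_gene &
                                             genes$membership == "aging"]))
  truth <- structure(list(
    genes = genes, cells = cells,
    hub = list(gene = if (length(hub_types)) pars$hub_gene else NA_character_,
               cell_types = hub_types),
    params = pars), class = "ground_truth")
  list(sce = sce, annotation = ann, truth = truth)
}
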