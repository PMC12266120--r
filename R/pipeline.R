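# End-to-end orchestration: simulate (or load) -> QC -> normalize -> cell
# typing -> three-contrast DEG -> PR/PG rescue classification -> gene-set
# scoring -> prioritization. One global seed fans out to per-stage derived
# seeds; all outputs are deterministic given (config, seed). Logs go to
# stderr only, so written results are byte-stable across identical runs.

#' Default pipeline configuration (demo study)
#'
#' Thresholds marked `"paper"` in the run report (QC bounds, fc 0.25, alpha
#' 0.05, BH, rank-sum) are the published analysis thresholds; the rest are
#' this package's own defaults.
#'
#' @param seed Global run seed.
#' @param out_dir Output directory.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = "results/pipeline") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = NULL,                       # or list(dir = <bundle directory>)
    simulate = list(n_cell_types = 3, cells_per_group_per_type = 200,
                    n_genes = 1000, hub_n_types = 3),
    qc = list(min_genes = 200, max_genes = 4000, max_pct_mito = 20,
              mito_prefix = "mt-"),
    normalize = list(scale = 1e4),
    assign = list(min_margin = 0.05, markers_gmt = NULL),
    deg = list(fc_threshold = 0.25, alpha = 0.05, min_cells = 3,
               contrasts = c("Aged", "Ahet", "Yhet")),
    rescue = list(mode = "strict"),
    score = list(sets_gmt = NULL, n_bins = 25, n_ctrl = 100,
                 pairs = list(c("Aiso", "Yiso"), c("Ahet", "Aiso"),
                              c("Yhet", "Yiso"))),
    prioritize = list(collections_gmt = NULL, contrasts = c("Aged", "Ahet"),
                      synthetic_collection_size = 20),
    write_counts = FALSE
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[parabioRescue] ", fmt), ...))
}

#' Run the full rescue-analysis pipeline
#'
#' Executes every stage, writes all intermediate tables under
#' `cfg$out_dir`, and returns (and writes as `report.json`) a run report
#' with per-stage counts, the responsiveness table, the candidate table,
#' the config hash and the seed. Identical (config, seed) gives
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param cfg Configuration list, see [default_config()].
#' @return The run report (list), invisibly also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash_cfg <- cfg[setdiff(names(cfg), "out_dir")]  # where, not what
  report <- list(schema_version = 1L, seed = cfg$seed,
                 config_hash = fnv1a_hex(jsonlite::toJSON(hash_cfg, auto_unbox = TRUE)),
                 thresholds = list(
                   qc = c(cfg$qc[c("min_genes", "max_genes", "max_pct_mito")],
                          provenance = "paper"),
                   deg = list(fc_threshold = cfg$deg$fc_threshold,
                              alpha = cfg$deg$alpha, provenance = "paper"),
                   score = c(cfg$score[c("n_bins", "n_ctrl")],
                             provenance = "artifact-chosen")),
                 stages = list(), flags = character(0))
  stage <- function(name, code) {
    t <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_stage("%s done in %.1fs", name, as.numeric(Sys.time() - t, units = "secs"))
    res
  }

  truth <- NULL
  ds <- stage("input", {
    if (!is.null(cfg$input)) {
      sce <- read_counts(file.path(cfg$input$dir, "matrix.mtx"),
                         file.path(cfg$input$dir, "genes.tsv"),
                         file.path(cfg$input$dir, "cells.tsv"))
      ann <- read_annotation(file.path(cfg$input$dir, "annotation.tsv"))
      list(sce = set_annotation(sce, ann), annotation = ann, truth = NULL)
    } else {
      pars <- do.call(generator_params,
                      c(cfg$simulate, list(seed = derive_seed(cfg$seed, "simulate"))))
      generate_dataset(pars)
    }
  })
  truth <- ds$truth
  sce <- ds$sce
  report$stages$input <- list(n_cells = ncol(sce), n_genes = nrow(sce))
  if (!is.null(truth)) {
    write_tsv(truth$genes, file.path(cfg$out_dir, "ground_truth.tsv"))
  }
  if (isTRUE(cfg$write_counts)) write_counts(sce, file.path(cfg$out_dir, "counts"))

  sce <- stage("qc", qc_filter(sce, do.call(qc_thresholds, cfg$qc)))
  report$stages$qc <- list(n_cells_pass = ncol(sce))

  sce <- stage("normalize", normalize_counts(sce, scale = cfg$normalize$scale))

  sce <- stage("assign_cell_types", {
    markers <- if (!is.null(cfg$assign$markers_gmt)) {
      read_gmt(cfg$assign$markers_gmt)
    } else if (!is.null(truth)) {
      marker_sets(truth)
    } else stop_fmt("no marker sets: set assign$markers_gmt for external input")
    assign_cell_types(sce, markers, min_margin = cfg$assign$min_margin,
                      seed = derive_seed(cfg$seed, "assign"))
  })
  type_counts <- table(SummarizedExperiment::colData(sce)$cell_type)
  report$stages$assign <- as.list(type_counts)
  write_annotation(get_annotation(sce), file.path(cfg$out_dir, "annotation.tsv"))

  degs <- stage("deg", {
    find_degs_all(sce, contrasts = cfg$deg$contrasts,
                  fc_threshold = cfg$deg$fc_threshold, alpha = cfg$deg$alpha,
                  min_cells = cfg$deg$min_cells)
  })
  write_deg_table(degs, file.path(cfg$out_dir, "degs.tsv"))
  deg_counts <- if (nrow(degs)) {
    as.list(table(paste(degs$cell_type, degs$contrast, sep = "/")))
  } else list()
  report$stages$deg <- list(n_records = nrow(degs), per_stratum = deg_counts)
  if (!nrow(degs)) report$flags <- c(report$flags, "no DEGs")

  rescue <- stage("rescue", {
    cts <- sort(unique(degs$cell_type))
    cls <- lapply(cts, function(tp) {
      d <- function(cn) degs[degs$cell_type == tp & degs$contrast == cn, ,
                             drop = FALSE]
      rescue_classification(d("Aged"), d("Ahet"), d("Yhet"),
                            mode = cfg$rescue$mode)
    })
    names(cls) <- cts
    cls
  })
  resp <- if (length(rescue)) responsiveness(rescue) else
    data.frame(cell_type = character(), n_aged = integer(), n_pr = integer(),
               n_pg = integer(), pct_pr = numeric(), pct_pg = numeric(),
               defined = logical())
  write_tsv(resp, file.path(cfg$out_dir, "responsiveness.tsv"))
  pr_tab <- do.call(rbind, lapply(names(rescue), function(tp) {
    pr <- rescue[[tp]]$pr_degs
    if (nrow(pr)) cbind(cell_type = tp, pr) else NULL
  }))
  if (!is.null(pr_tab)) write_tsv(pr_tab, file.path(cfg$out_dir, "pr_degs.tsv"))
  report$stages$rescue <- list(responsiveness = resp)

  score_tab <- stage("score", {
    sets <- if (!is.null(cfg$score$sets_gmt)) {
      read_gmt(cfg$score$sets_gmt)
    } else if (!is.null(truth) &&
               any(truth$genes$membership == "aging")) {
      # demo sets: each type's up-in-aging program plays the SASP role
      s <- lapply(sort(unique(truth$genes$cell_type)), function(tp) {
        program_genes(truth, tp, direction = "up")
      })
      names(s) <- paste0("aging_up_", sort(unique(truth$genes$cell_type)))
      gene_set_collection("planted_programs", s[lengths(s) > 0])
    } else NULL
    rows <- list()
    for (nm in names(if (is.null(sets)) list() else sets$sets)) {
      for (tp in sort(setdiff(unique(SummarizedExperiment::colData(sce)$cell_type),
                              "unassigned"))) {
        sub <- sce[, SummarizedExperiment::colData(sce)$cell_type == tp]
        sc <- suppressWarnings(
          module_score(sub, set_genes(sets, nm), n_bins = cfg$score$n_bins,
                       n_ctrl = cfg$score$n_ctrl,
                       seed = derive_seed(cfg$seed, paste0("score_", nm)),
                       set_name = nm))
        cmp <- compare_scores(sc, sub, cfg$score$pairs)
        rows[[paste(nm, tp)]] <- cbind(cell_type = tp, cmp)
      }
    }
    if (!length(rows)) NULL else {
      out <- do.call(rbind, rows)
      out$p_adjusted <- bh_adjust(out$p_value)   # BH across the whole stage
      rownames(out) <- NULL
      out
    }
  })
  if (!is.null(score_tab)) {
    write_tsv(score_tab, file.path(cfg$out_dir, "score_comparisons.tsv"))
    report$stages$score <- list(n_comparisons = nrow(score_tab))
  }

  cand <- stage("prioritize", {
    pr_genes <- unique(unlist(lapply(rescue, function(cl) cl$pr_degs$gene)))
    collections <- if (!is.null(cfg$prioritize$collections_gmt)) {
      lapply(cfg$prioritize$collections_gmt, read_gmt)
    } else if (!is.null(truth) && !is.na(truth$hub$gene)) {
      list(synthetic_aging_collection(
        truth, n_extra = cfg$prioritize$synthetic_collection_size,
        seed = derive_seed(cfg$seed, "collection")))
    } else NULL
    if (is.null(collections) || !length(pr_genes)) {
      list(candidates = frequency_rank(character(0), degs), enrichment = NULL)
    } else {
      ov <- overlap_with_collections(pr_genes, collections)
      candidates <- frequency_rank(ov, degs,
                                   contrasts = cfg$prioritize$contrasts)
      universe <- rownames(sce)[Matrix::rowSums(
        SummarizedExperiment::assay(sce, "counts") > 0) >= cfg$deg$min_cells]
      enr <- do.call(rbind, unlist(lapply(collections, function(col) {
        lapply(names(col$sets), function(nm) {
          h <- hypergeom_enrich(intersect(pr_genes, universe),
                                col$sets[[nm]]$genes, universe)
          data.frame(collection = col$name, set = nm,
                     overlap = h$overlap_count, K = h$K, n = h$n, N = h$N,
                     p_value = h$p_value, stringsAsFactors = FALSE)
        })
      }), recursive = FALSE))
      if (!is.null(enr) && nrow(enr)) enr$p_adjusted <- bh_adjust(enr$p_value)
      list(candidates = candidates, enrichment = enr)
    }
  })
  write_tsv(cand$candidates, file.path(cfg$out_dir, "candidates.tsv"))
  if (!is.null(cand$enrichment)) {
    write_tsv(cand$enrichment, file.path(cfg$out_dir, "enrichment.tsv"))
  }
  report$stages$prioritize <- list(
    n_candidates = nrow(cand$candidates),
    top_candidates = utils::head(cand$candidates, 10))

  write_run_meta(report, file.path(cfg$out_dir, "report.json"))
  log_stage("pipeline finished in %.1fs",
            as.numeric(Sys.time() - t0, units = "secs"))
  invisible(report)
}

#' Synthetic aging-database collection for a simulated study
#'
#' Emulates a public aging gene database at demo scale: the planted hub gene
#' plus `n_extra` genes drawn from the whole gene universe. Synthetic —
#' stands in for Aging Atlas / GenAge / CellAge-style lists, which cannot be
#' bundled.
#'
#' @param truth A `ground_truth` with a hub gene.
#' @param n_extra Number of non-hub genes. Default 20.
#' @param seed Draw seed.
#' @return A `gene_set_collection` with one set, `aging_db`.
#' @export
synthetic_aging_collection <- function(truth, n_extra = 20L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.na(truth$hub$gene)) stop_fmt("ground truth has no hub gene")
  all_genes <- unique(truth$genes$gene)
  extra <- with_seed(seed, sample(setdiff(all_genes, truth$hub$gene), n_extra))
  gene_set_collection(
    "synthetic_aging_db",
    list(aging_db = list(description = "synthetic aging-database stand-in",
                         genes = c(truth$hub$gene, sort(extra)))))
}
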