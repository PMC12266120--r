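# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

withr_local_tempfile <- function(fileext = "", env = parent.frame()) {
  withr::local_tempfile(fileext = fileext, .local_envir = env)
}

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# Default-condition simulated study (3 types x 200 cells/group/type).
demo_dataset <- function() {
  cached("demo", generate_dataset(generator_params(seed = 42)))
}

# The same study QC-filtered and normalized (true types kept in colData).
demo_norm <- function() {
  cached("demo_norm", normalize_counts(qc_filter(demo_dataset()$sce)))
}

# Build a SingleCellExperiment from a dense genes x cells count matrix.
tiny_sce <- function(counts, groups = NULL, normalize = TRUE) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")))
  if (!is.null(groups)) {
    SummarizedExperiment::colData(sce)$group <- groups
  }
  if (normalize) sce <- normalize_counts(sce)
  sce
}

# Brute-force two-sided rank-sum p by explicit enumeration of all
# C(m+n, m) assignments (independent oracle for the DP implementation).
enum_ranksum_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  sums <- combn(length(r), m, function(idx) sum(r[idx]))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Independent naive BH step-up (sort ascending, scale, backward min, cap).
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in seq(n - 1, 1)) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Assignment accuracy of predicted cell types against generator truth.
assignment_accuracy <- function(sce, truth) {
  ann <- get_annotation(sce)
  true_ct <- truth$cells$cell_type[match(ann$cell_id, truth$cells$cell_id)]
  mean(ann$cell_type == true_ct)
}

# Planted-truth recovery of one contrast in one cell type.
deg_recovery <- function(degs, truth, cell_type) {
  tg <- truth$genes
  planted <- tg$gene[tg$cell_type == cell_type & tg$membership == "aging"]
  list(sensitivity = mean(planted %in% degs$gene),
       fdr = if (nrow(degs)) mean(!degs$gene %in% planted) else 0)
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
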