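# Wilcoxon/Mann-Whitney rank-sum engine used for all group comparisons.
#
# The exact two-sided p-value is computed from the permutation distribution
# of the rank sum over all C(m+n, m) assignments of the pooled midranks,
# obtained with a generating-function dynamic program (counts of size-m
# subsets by rank sum) rather than explicit enumeration. When the number of
# assignments exceeds `max_exact` the normal approximation with tie and
# continuity correction is used instead.

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks are used for ties. The exact branch is taken when
#' `choose(m + n, m) <= max_exact`; its two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` over the permutation distribution
#' of the rank sum `W` of `x`. Otherwise a normal approximation with tie
#' correction and a 0.5 continuity correction is used.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param max_exact Assignment-count bound for the exact branch. Default 2e5.
#' @return List with `statistic` (rank sum of `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, max_exact = 2e5) {
  if (!length(x) || !length(y)) stop_fmt("rank_sum_test: empty input vector")
  if (anyNA(x) || anyNA(y)) stop_fmt("rank_sum_test: NA values not supported")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  exact_ok <- lchoose(N, m) <= log(max_exact) + 1e-9
  if (exact_ok) {
    p <- exact_ranksum_p(r, m, w)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    mu <- m * (N + 1) / 2
    ties <- tabulate(match(r, unique(r)))
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1, method = "normal"))
    d <- w - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
  }
}

# Exact permutation p via DP over doubled midranks: f[j+1, s+1] counts the
# size-j subsets of the pooled ranks with doubled-rank sum s. Complexity
# O(N * m * max_sum); feasible throughout the exact regime.
exact_ranksum_p <- function(r, m, w) {
  s <- as.integer(round(2 * r))          # doubled midranks are integers
  N <- length(s)
  k <- min(m, N - m)                     # DP over the smaller group
  smax <- sum(sort(s, decreasing = TRUE)[seq_len(k)])
  f <- matrix(0, nrow = k + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (si in s) {
    for (j in seq(k, 1L)) {
      cols <- seq_len(smax + 1L - si)
      f[j + 1L, cols + si] <- f[j + 1L, cols + si] + f[j, cols]
    }
  }
  counts <- f[k + 1L, ]
  total <- sum(counts)
  sums <- (seq_len(smax + 1L) - 1L) / 2  # back to midrank scale
  # if the DP ran over the complementary (smaller) group, reflect the
  # observed statistic: rank sums of the two groups add to N(N+1)/2, and the
  # two-sided p is symmetric under the swap
  wk <- if (k == m) w else N * (N + 1) / 2 - w
  p_le <- sum(counts[sums <= wk + 1e-9]) / total
  p_ge <- sum(counts[sums >= wk - 1e-9]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Log2 fold change of back-transformed normalized expression
#'
#' Inputs are normalized-layer values (natural-log scale); the statistic is
#' `log2((mean(exp(x) - 1) + pseudo) / (mean(exp(y) - 1) + pseudo))`, the
#' common single-cell convention. The pseudocount keeps it finite.
#'
#' @param x_norm,y_norm Normalized expression vectors (case, control).
#' @param pseudo Pseudocount. Default 1.
#' @return Signed log2 fold change.
#' @export
log2_fold_change <- function(x_norm, y_norm, pseudo = 1) {
  if (!length(x_norm) || !length(y_norm)) stop_fmt("log2_fold_change: empty input")
  log2((mean(expm1(x_norm)) + pseudo) / (mean(expm1(y_norm)) + pseudo))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts ascending, scales `p_(i) * n / i`, enforces monotonicity by a
#' cumulative minimum from the largest rank, caps at 1, and returns values in
#' the original order. Tied p-values share their adjusted value.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_fmt("bh_adjust: p-values must lie in [0, 1] and be non-missing")
  }
  n <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(pvals[o] * n / seq(n, 1)))
  q[order(o)]
}

#' Specify a group contrast
#'
#' The three named parabiosis contrasts are `Aged` (Aiso vs Yiso), `Ahet`
#' (Ahet vs Aiso) and `Yhet` (Yhet vs Yiso); arbitrary case/control label
#' pairs are allowed for other designs.
#'
#' @param name Contrast name.
#' @param case,control Group labels; filled in automatically for the three
#'   named contrasts.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(name, case = NULL, control = NULL) {
  known <- list(Aged = c("Aiso", "Yiso"), Ahet = c("Ahet", "Aiso"),
                Yhet = c("Yhet", "Yiso"))
  if (is.null(case) || is.null(control)) {
    if (!name %in% names(known)) {
      stop_fmt("unknown contrast '%s': give case and control explicitly", name)
    }
    case <- known[[name]][1]; control <- known[[name]][2]
  }
  if (identical(case, control)) stop_fmt("contrast case and control must differ")
  structure(list(name = name, case = case, control = control),
            class = "contrast_spec")
}

#' Per-cell-type differential expression for one contrast
#'
#' Tests every gene detected (raw count > 0) in at least `min_cells` cells of
#' either group within the cell type, using [rank_sum_test()] on the
#' normalized layer and [log2_fold_change()]; BH adjustment is applied across
#' the tested genes of this (cell type, contrast) stratum. Records are kept
#' only when `|log2fc| > fc_threshold` and `p_adjusted < alpha`, both strict.
#'
#' @param sce Normalized `SingleCellExperiment` with `group` (and, unless
#'   `cell_type = NULL`, `cell_type`) in `colData`.
#' @param contrast A [contrast_spec()].
#' @param cell_type Cell-type label to analyze, or `NULL` to use all cells.
#' @param fc_threshold Log2 fold-change cutoff (strict). Default 0.25.
#' @param alpha Adjusted-p cutoff (strict). Default 0.05.
#' @param min_cells Minimum cells per group and detection floor. Default 3.
#' @param all_genes If `TRUE`, return every tested gene (no thresholding);
#'   used for diagnostics and calibration.
#' @return A DEG `data.frame` (see [write_deg_table()]).
#' @export
find_degs <- function(sce, contrast, cell_type = NULL, fc_threshold = 0.25,
                      alpha = 0.05, min_cells = 3L, all_genes = FALSE) {
  stopifnot(inherits(contrast, "contrast_spec"))
  require_logcounts(sce, "find_degs")
  cd <- SummarizedExperiment::colData(sce)
  if (!"group" %in% names(cd)) stop_fmt("find_degs: no 'group' column in colData")
  in_type <- if (is.null(cell_type)) rep(TRUE, ncol(sce)) else {
    if (!"cell_type" %in% names(cd)) stop_fmt("find_degs: no 'cell_type' column in colData")
    cd$cell_type == cell_type
  }
  type_label <- if (is.null(cell_type)) "all" else cell_type
  case_idx <- which(in_type & cd$group == contrast$case)
  ctrl_idx <- which(in_type & cd$group == contrast$control)
  for (side in list(c(contrast$case, length(case_idx)),
                    c(contrast$control, length(ctrl_idx)))) {
    if (as.integer(side[[2]]) < min_cells) {
      stop_fmt("insufficient cells: group '%s' has %s cells of type '%s' (need >= %d)",
               side[[1]], side[[2]], type_label, min_cells)
    }
  }
  raw <- SummarizedExperiment::assay(sce, "counts")
  det_case <- Matrix::rowSums(raw[, case_idx, drop = FALSE] > 0)
  det_ctrl <- Matrix::rowSums(raw[, ctrl_idx, drop = FALSE] > 0)
  tested <- which(det_case >= min_cells | det_ctrl >= min_cells)
  if (!length(tested)) return(empty_deg_table())

  ln <- SummarizedExperiment::assay(sce, "logcounts")
  xm <- as.matrix(ln[tested, case_idx, drop = FALSE])
  ym <- as.matrix(ln[tested, ctrl_idx, drop = FALSE])
  lfc <- log2((rowMeans(expm1(xm)) + 1) / (rowMeans(expm1(ym)) + 1))
  pv <- vapply(seq_along(tested), function(i) {
    rank_sum_test(xm[i, ], ym[i, ])$p_value
  }, numeric(1))
  padj <- bh_adjust(pv)

  out <- data.frame(gene = rownames(raw)[tested], cell_type = type_label,
                    contrast = contrast$name, log2fc = lfc, p_value = pv,
                    p_adjusted = padj,
                    direction = ifelse(lfc > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!all_genes) {
    out <- out[abs(out$log2fc) > fc_threshold & out$p_adjusted < alpha, ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_tested") <- length(tested)
  out
}

#' Run the three parabiosis contrasts across cell types
#'
#' @param sce Normalized, annotated `SingleCellExperiment`.
#' @param cell_types Cell types to analyze; defaults to all labels present
#'   except `"unassigned"`. Types with too few cells in any group are skipped
#'   with a message.
#' @param contrasts Contrast names. Default `c("Aged", "Ahet", "Yhet")`.
#' @inheritParams find_degs
#' @return One combined DEG `data.frame`.
#' @export
find_degs_all <- function(sce, cell_types = NULL,
                          contrasts = c("Aged", "Ahet", "Yhet"),
                          fc_threshold = 0.25, alpha = 0.05, min_cells = 3L) {
  cd <- SummarizedExperiment::colData(sce)
  if (is.null(cell_types)) {
    cell_types <- sort(setdiff(unique(cd$cell_type), "unassigned"))
  }
  tabs <- list()
  for (tp in cell_types) {
    for (cn in contrasts) {
      tab <- tryCatch(
        find_degs(sce, contrast_spec(cn), cell_type = tp,
                  fc_threshold = fc_threshold, alpha = alpha,
                  min_cells = min_cells),
        error = function(e) {
          message(sprintf("skipping %s/%s: %s", tp, cn, conditionMessage(e)))
          NULL
        })
      if (!is.null(tab)) tabs[[paste(tp, cn)]] <- tab
    }
  }
  if (!length(tabs)) return(empty_deg_table())
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  order_deg_table(out)
}
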