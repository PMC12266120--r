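# Classification of prorejuvenative (PR) and progeronic (PG) genes.
#
# PR-DEGs are the intersection of Aged-DEGs (Aiso vs Yiso) and Ahet-DEGs
# (Ahet vs Aiso); PG-DEGs the intersection of Aged-DEGs and Yhet-DEGs
# (Yhet vs Yiso). In the default "strict" mode the intersections are
# direction-aware: a PR gene must reverse its aging direction under
# heterochronic exposure, a PG gene must move the young retina in the aging
# direction. "loose" mode is the plain set intersection.

check_one_cell_type <- function(...) {
  tabs <- list(...)
  cts <- unique(unlist(lapply(tabs, function(t) unique(t$cell_type))))
  if (length(cts) > 1L) {
    stop_fmt("DEG tables mix cell types: %s", paste(cts, collapse = ", "))
  }
  invisible(cts)
}

intersect_degs <- function(a, b, opposite) {
  m <- merge(a[c("gene", "direction", "log2fc")],
             b[c("gene", "direction", "log2fc")],
             by = "gene", suffixes = c("_aging", "_hp"))
  if (opposite) m <- m[m$direction_aging != m$direction_hp, , drop = FALSE]
  m <- m[order(m$gene, method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Classify prorejuvenative (PR) genes
#'
#' @param aged Aged-contrast DEG table of one cell type.
#' @param ahet Ahet-contrast DEG table of the same cell type.
#' @param mode `"strict"` (directions must be opposite: the aging change is
#'   reversed under HP) or `"loose"` (any gene in both tables).
#' @return data.frame with `gene`, `direction_aging`, `direction_hp`,
#'   per-table log2 fold changes, and `stratum` (`up`/`down` by the gene's
#'   aging direction).
#' @export
classify_rescued <- function(aged, ahet, mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  check_one_cell_type(aged, ahet)
  out <- intersect_degs(aged, ahet, opposite = (mode == "strict"))
  out$stratum <- out$direction_aging
  out
}

#' Classify progeronic (PG) genes
#'
#' @param aged Aged-contrast DEG table of one cell type.
#' @param yhet Yhet-contrast DEG table of the same cell type.
#' @param mode `"strict"` (directions must be concordant: the young retina
#'   moves toward the aged state) or `"loose"`.
#' @return As [classify_rescued()].
#' @export
classify_progeronic <- function(aged, yhet, mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  check_one_cell_type(aged, yhet)
  m <- merge(aged[c("gene", "direction", "log2fc")],
             yhet[c("gene", "direction", "log2fc")],
             by = "gene", suffixes = c("_aging", "_hp"))
  if (mode == "strict") m <- m[m$direction_aging == m$direction_hp, , drop = FALSE]
  m <- m[order(m$gene, method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  m$stratum <- m$direction_aging
  m
}

#' Full PR/PG classification of one cell type
#'
#' @param aged,ahet,yhet DEG tables of one cell type (Yhet may be `NULL`,
#'   giving an empty PG set).
#' @param mode Intersection mode, see [classify_rescued()].
#' @return A `rescue_classification`: cell type, PR and PG gene tables,
#'   `n_aged`, and responsiveness percentages `pct_pr` / `pct_pg`
#'   (`NA` — flagged undefined — when `n_aged` is 0).
#' @export
rescue_classification <- function(aged, ahet, yhet = NULL,
                                  mode = c("strict", "loose")) {
  mode <- match.arg(mode)
  ct <- check_one_cell_type(aged, ahet,
                            if (is.null(yhet)) empty_deg_table() else yhet)
  pr <- classify_rescued(aged, ahet, mode)
  pg <- if (is.null(yhet)) pr[0, , drop = FALSE] else {
    classify_progeronic(aged, yhet, mode)
  }
  n_aged <- length(unique(aged$gene))
  structure(list(
    cell_type = if (length(ct)) ct else NA_character_,
    mode = mode, pr_degs = pr, pg_degs = pg, n_aged = n_aged,
    pct_pr = if (n_aged > 0) 100 * nrow(pr) / n_aged else NA_real_,
    pct_pg = if (n_aged > 0) 100 * nrow(pg) / n_aged else NA_real_),
    class = "rescue_classification")
}

#' @export
print.rescue_classification <- function(x, ...) {
  cat(sprintf("rescue_classification [%s, %s]: %d Aged-DEGs, %d PR (%.1f%%), %d PG (%.1f%%)\n",
              x$cell_type, x$mode, x$n_aged, nrow(x$pr_degs), x$pct_pr,
              nrow(x$pg_degs), x$pct_pg))
  invisible(x)
}

#' Per-cell-type responsiveness table
#'
#' The percentage of Aged-DEGs that are PR reflects how strongly a cell type
#' is rejuvenated by heterochronic parabiosis; the PG percentage reflects the
#' pro-aging effect on young tissue. Rows are sorted by `pct_pr` descending
#' (ties by cell type); cell types with no Aged-DEGs are flagged
#' (`defined = FALSE`) and listed last.
#'
#' @param classifications List of [rescue_classification()] objects.
#' @return data.frame `cell_type`, `n_aged`, `n_pr`, `n_pg`, `pct_pr`,
#'   `pct_pg`, `defined`.
#' @export
responsiveness <- function(classifications) {
  stopifnot(length(classifications) >= 1L)
  rows <- do.call(rbind, lapply(classifications, function(cl) {
    stopifnot(inherits(cl, "rescue_classification"))
    data.frame(cell_type = cl$cell_type, n_aged = cl$n_aged,
               n_pr = nrow(cl$pr_degs), n_pg = nrow(cl$pg_degs),
               pct_pr = cl$pct_pr, pct_pg = cl$pct_pg,
               defined = cl$n_aged > 0, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(!rows$defined, -replace(rows$pct_pr, is.na(rows$pct_pr), -Inf),
                     rows$cell_type, method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
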