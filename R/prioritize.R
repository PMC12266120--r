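# Candidate-gene prioritization: overlap PR genes with aging/disease
# gene-set collections, rank the overlap by the number of distinct cell
# types in which each gene recurs as a DEG (a hub statistic), and provide a
# hypergeometric over-representation test for arbitrary gene lists.

#' Overlap a gene set with gene-set collections
#'
#' Verbatim, case-sensitive symbol matching against the union of all sets of
#' all collections; every (collection, set) containing a query gene is
#' recorded as provenance.
#'
#' @param query Character vector of gene symbols (e.g. PR-DEGs).
#' @param collections A `gene_set_collection` or list of them.
#' @return data.frame `gene`, `collection`, `set` (one row per hit); zero
#'   rows — with a warning — when the query is empty or nothing overlaps.
#' @export
overlap_with_collections <- function(query, collections) {
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  stopifnot(length(collections) >= 1L,
            all(vapply(collections, inherits, logical(1), "gene_set_collection")))
  if (!length(query)) {
    warning("empty query gene set: returning empty overlap", call. = FALSE)
    return(data.frame(gene = character(), collection = character(),
                      set = character(), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (col in collections) {
    for (nm in names(col$sets)) {
      hit <- intersect(query, col$sets[[nm]]$genes)
      if (length(hit)) {
        rows[[paste(col$name, nm)]] <-
          data.frame(gene = hit, collection = col$name, set = nm,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(), collection = character(), set = character(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene, out$collection, out$set, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank overlap genes by cross-cell-type DEG frequency
#'
#' For each overlap gene, the frequency is the number of distinct cell types
#' in whose DEG tables it appears (a gene hit in several contrasts of one
#' type counts once). Rows are sorted by frequency descending, then by the
#' tie-break score (sum of `|log2fc|` over the gene's DEG records in scope)
#' descending, then gene symbol — a fully deterministic order. The default
#' contrast scope is the PR-relevant pair (`Aged`, `Ahet`).
#'
#' @param overlap Overlap data.frame from [overlap_with_collections()], or a
#'   character vector of genes.
#' @param degs Combined DEG `data.frame` covering one or more cell types.
#' @param contrasts Contrast names counted. Default `c("Aged", "Ahet")`.
#' @return data.frame `gene`, `n_cell_types`, `cell_types`
#'   (comma-separated), `collections_hit` (comma-separated, empty when the
#'   query carried no provenance), `tie_break_score`. Genes with no DEG
#'   record in scope are omitted (frequency would be 0).
#' @export
frequency_rank <- function(overlap, degs, contrasts = c("Aged", "Ahet")) {
  if (is.character(overlap)) {
    g <- unique(overlap)
    overlap <- data.frame(gene = g, collection = character(length(g)),
                          set = character(length(g)), stringsAsFactors = FALSE)
  }
  validate_deg_table(degs)
  scope <- degs[degs$contrast %in% contrasts & degs$gene %in% overlap$gene, ,
                drop = FALSE]
  if (!nrow(scope)) {
    return(data.frame(gene = character(), n_cell_types = integer(),
                      cell_types = character(), collections_hit = character(),
                      tie_break_score = numeric(), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(split(scope, scope$gene), function(d) {
    cts <- sort(unique(d$cell_type))
    data.frame(gene = d$gene[[1]], n_cell_types = length(cts),
               cell_types = paste(cts, collapse = ","),
               tie_break_score = sum(abs(d$log2fc)),
               stringsAsFactors = FALSE)
  }))
  prov <- vapply(rows$gene, function(g) {
    hits <- overlap[overlap$gene == g & nzchar(overlap$collection), ]
    paste(sort(unique(hits$collection)), collapse = ",")
  }, character(1))
  rows$collections_hit <- prov
  rows <- rows[order(-rows$n_cell_types, -rows$tie_break_score, rows$gene,
                     method = "radix"),
               c("gene", "n_cell_types", "cell_types", "collections_hit",
                 "tie_break_score"), drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the observed
#' number of annotation genes in a query of size `n` from a universe of size
#' `N` containing `K` annotation genes, by exact summation of the
#' hypergeometric mass.
#'
#' @param query Gene set tested; must be a subset of `universe`.
#' @param annotation_set Annotation gene set (intersected with the universe
#'   to form `K`).
#' @param universe Background gene set.
#' @return List `overlap_count`, `p_value`, plus `N`, `K`, `n`.
#' @export
hypergeom_enrich <- function(query, annotation_set, universe) {
  query <- unique(query); universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop_fmt("query genes outside the universe: %s",
             paste(utils::head(extra, 10), collapse = ", "))
  }
  N <- length(universe)
  K <- length(intersect(unique(annotation_set), universe))
  n <- length(query)
  k_obs <- length(intersect(query, annotation_set))
  kk <- seq(k_obs, min(K, n))
  p <- sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
  list(overlap_count = k_obs, p_value = min(1, p), N = N, K = K, n = n)
}
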