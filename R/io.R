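#' Read a sparse count bundle (Matrix Market + genes + cells)
#'
#' Reads the common single-cell exchange bundle: a Matrix Market coordinate
#' file storing genes x cells, a gene file and a cell (barcode) file with one
#' identifier per line (first column if tab-separated). Returns a
#' [SingleCellExperiment::SingleCellExperiment] with a `counts` assay
#' (genes x cells).
#'
#' @param matrix_path Path to the `.mtx` file (genes x cells).
#' @param genes_path Path to the gene symbol file.
#' @param cells_path Path to the cell identifier file.
#' @return A `SingleCellExperiment` with assay `counts`.
#' @export
read_counts <- function(matrix_path, genes_path, cells_path) {
  for (p in c(matrix_path, genes_path, cells_path)) {
    if (!file.exists(p)) stop_fmt("file not found: %s", p)
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop_fmt("malformed Matrix Market file '%s': %s",
                                             matrix_path, conditionMessage(e)))
  genes <- read_id_column(genes_path)
  cells <- read_id_column(cells_path)
  if (nrow(m) != length(genes)) {
    stop_fmt("dimension mismatch: matrix header declares %d genes but '%s' lists %d",
             nrow(m), genes_path, length(genes))
  }
  if (ncol(m) != length(cells)) {
    stop_fmt("dimension mismatch: matrix header declares %d cells but '%s' lists %d",
             ncol(m), cells_path, length(cells))
  }
  vals <- m@x
  if (any(vals < 0)) stop_fmt("negative count entries in '%s'", matrix_path)
  if (any(vals != floor(vals))) stop_fmt("non-integer count entries in '%s'", matrix_path)
  if (anyDuplicated(genes)) stop_fmt("duplicate gene symbols in '%s'", genes_path)
  if (anyDuplicated(cells)) stop_fmt("duplicate cell ids in '%s'", cells_path)
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count bundle readable by [read_counts()]
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (matrix, genes, cells).
#' @export
write_counts <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(as(m, "CsparseMatrix"), paths[[1]])
  writeLines(rownames(sce), paths[[2]])
  writeLines(colnames(sce), paths[[3]])
  invisible(setNames(paths, c("matrix", "genes", "cells")))
}

#' Read / write a per-cell annotation table
#'
#' Annotations are TSV with a `cell_id` column plus any of `group`,
#' `cell_type`, `n_genes_detected`, `pct_mito`.
#'
#' @param path TSV path.
#' @param groups Allowed group labels; defaults to the four-group parabiosis
#'   design [HP_GROUPS]. Set to `NULL` to skip the check.
#' @return A `data.frame` with one row per cell.
#' @export
read_annotation <- function(path, groups = HP_GROUPS) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(ann)) stop_fmt("annotation '%s' lacks a cell_id column", path)
  if (anyDuplicated(ann$cell_id)) stop_fmt("duplicate cell_id in annotation '%s'", path)
  if (!is.null(groups) && "group" %in% names(ann)) {
    bad <- setdiff(unique(ann$group), groups)
    if (length(bad)) {
      stop_fmt("annotation '%s' has group labels outside the design: %s",
               path, paste(bad, collapse = ", "))
    }
  }
  ann
}

#' @rdname read_annotation
#' @param ann Annotation `data.frame`.
#' @export
write_annotation <- function(ann, path) {
  write_tsv(ann, path)
  invisible(path)
}

#' Attach an annotation table to a SingleCellExperiment
#'
#' Every cell of `sce` must have exactly one annotation row; rows are matched
#' by `cell_id` and stored in `colData`.
#'
#' @param sce A `SingleCellExperiment`.
#' @param ann Annotation `data.frame` with a `cell_id` column.
#' @return `sce` with annotation columns in `colData`.
#' @export
set_annotation <- function(sce, ann) {
  idx <- match(colnames(sce), ann$cell_id)
  if (anyNA(idx)) {
    stop_fmt("cells missing from annotation: %s",
             paste(head(colnames(sce)[is.na(idx)], 5), collapse = ", "))
  }
  ann <- ann[idx, , drop = FALSE]
  cd <- S4Vectors::DataFrame(ann[setdiff(names(ann), "cell_id")],
                             row.names = colnames(sce))
  SummarizedExperiment::colData(sce) <- cd
  sce
}

#' Extract the annotation data.frame from a SingleCellExperiment
#' @param sce A `SingleCellExperiment`.
#' @return A `data.frame` with `cell_id` first.
#' @export
get_annotation <- function(sce) {
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  data.frame(cell_id = colnames(sce), cd, row.names = NULL,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# ---- GMT gene sets -------------------------------------------------------

#' Construct a gene-set collection
#'
#' A collection is a named list of gene sets; each set keeps a description
#' and a unique (first-occurrence order) character vector of gene symbols.
#' Matching everywhere in the package is verbatim, case-sensitive symbol
#' equality — no alias or ortholog resolution.
#'
#' @param name Collection name.
#' @param sets Named list; each element either a character vector of genes or
#'   a list with `description` and `genes`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(name, sets) {
  stopifnot(is.character(name), length(name) == 1L, is.list(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_fmt("every gene set needs a name")
  }
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", genes = s)
    genes <- unique(as.character(s$genes))
    if (!length(genes)) stop_fmt("empty gene set in collection '%s'", name)
    list(description = as.character(s$description %||% ""), genes = genes)
  })
  structure(list(name = name, sets = sets), class = "gene_set_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets (%s)\n", x$name,
              length(x$sets),
              paste(head(names(x$sets), 5), collapse = ", ")))
  invisible(x)
}

#' Genes of one set in a collection
#' @param collection A `gene_set_collection`.
#' @param set Set name.
#' @return Character vector of gene symbols.
#' @export
set_genes <- function(collection, set) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!set %in% names(collection$sets)) {
    stop_fmt("no set '%s' in collection '%s'", set, collection$name)
  }
  collection$sets[[set]]$genes
}

#' Read / write GMT gene-set files
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are collapsed keeping first occurrence; empty lines
#' are skipped; a line with fewer than three fields is a format error
#' reported with its line number.
#'
#' @param path GMT path.
#' @param name Collection name; defaults to the file name without extension.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, name = sub("\\.gmt$", "", basename(path))) {
  lines <- readLines(path)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_fmt("GMT format error in '%s' line %d: %d field(s), need >= 3",
               path, i, length(fields))
    }
    sets[[fields[[1]]]] <- list(description = fields[[2]],
                                genes = fields[-(1:2)])
  }
  gene_set_collection(name, sets)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- DEG tables ----------------------------------------------------------

deg_columns <- c("gene", "cell_type", "contrast", "log2fc",
                 "p_value", "p_adjusted", "direction")

#' An empty differential-expression record table
#' @return Zero-row `data.frame` with the canonical DEG columns.
#' @export
empty_deg_table <- function() {
  data.frame(gene = character(), cell_type = character(), contrast = character(),
             log2fc = numeric(), p_value = numeric(), p_adjusted = numeric(),
             direction = character(), stringsAsFactors = FALSE)
}

validate_deg_table <- function(records) {
  if (!all(deg_columns %in% names(records))) {
    stop_fmt("DEG table lacks columns: %s",
             paste(setdiff(deg_columns, names(records)), collapse = ", "))
  }
  if (nrow(records)) {
    stopifnot(all(records$p_adjusted >= records$p_value - 1e-12),
              all((records$log2fc > 0) == (records$direction == "up")))
  }
  records[deg_columns]
}

# Deterministic row order so runs are diffable: cell type, contrast
# (Aged < Ahet < Yhet), ascending adjusted p, gene lexicographic.
order_deg_table <- function(records) {
  contrast_rank <- match(records$contrast, c("Aged", "Ahet", "Yhet"))
  contrast_rank[is.na(contrast_rank)] <- 99L
  records[order(records$cell_type, contrast_rank, records$p_adjusted,
                records$gene, method = "radix"), , drop = FALSE]
}

#' Write / read a differential-expression table
#'
#' TSV with fixed header `gene cell_type contrast log2fc p_value p_adjusted
#' direction`; floats carry 15 significant digits so a round-trip preserves
#' them to better than 1e-9 relative; rows ordered by cell type, contrast,
#' ascending adjusted p, then gene.
#'
#' @param records DEG `data.frame` (see [find_degs()]).
#' @param path Output TSV path.
#' @export
write_deg_table <- function(records, path) {
  records <- order_deg_table(validate_deg_table(records))
  write_tsv(records, path)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene = "character",
                                          cell_type = "character",
                                          contrast = "character",
                                          direction = "character"))
  validate_deg_table(tab)
}

# Shared TSV writer: fixed header, no quoting, 15 significant digits for
# doubles so tables are diffable and float round-trips are lossless in
# practice.
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) "NA" else formatC(v, digits = 15, format = "g")
      }, character(1))
    }
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_fmt("cannot write '%s': %s", path,
                                               conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata (seed, config hash, package version) as JSON
#' @param meta Named list.
#' @param path Output path.
#' @export
write_run_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
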