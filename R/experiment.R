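#' Construct a single-cell expression experiment
#'
#' The central container: a sparse non-negative genes-by-cells matrix of
#' normalized expression values with gene identifiers, cell barcodes and
#' provenance. Categories (cell annotations such as clusterings) attach to the
#' experiment with [attach_category()].
#'
#' @param matrix sparse (or coercible) numeric matrix, genes in rows, cells in
#'   columns, all entries non-negative
#' @param gene_ids character vector of gene identifiers, one per row
#' @param cell_ids character vector of cell barcodes, one per column
#' @param species organism name, e.g. `"Homo sapiens"`
#' @param accession experiment identifier string
#' @param source one of `"GXA"`, `"HCA"`, `"file"`
#' @param gene_symbols optional character vector of display symbols per gene
#' @return an object of class `scnv_experiment`
#' @export
scnv_experiment <- function(matrix, gene_ids, cell_ids,
                            species = "unknown", accession = "unnamed",
                            source = c("file", "GXA", "HCA"),
                            gene_symbols = NULL) {
  source <- match.arg(source)
  m <- as(as(as(matrix, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
    scnv_error("scnv_consistency_error", sprintf(
      "matrix is %d x %d but %d gene ids and %d cell ids were given",
      nrow(m), ncol(m), length(gene_ids), length(cell_ids)))
  }
  if (length(gene_ids) == 0L || length(cell_ids) == 0L) {
    scnv_error("scnv_format_error", "gene_ids and cell_ids must be non-empty")
  }
  if (length(m@x) && min(m@x) < 0) {
    scnv_error("scnv_domain_error", "expression matrix has negative entries")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    scnv_warn(sprintf("duplicate gene ids kept as separate rows: %s",
                      paste(utils::head(dup, 10L), collapse = ", ")))
  }
  rownames(m) <- NULL; colnames(m) <- NULL
  structure(list(
    matrix = m,
    gene_ids = as.character(gene_ids),
    gene_symbols = if (!is.null(gene_symbols)) as.character(gene_symbols),
    cell_ids = as.character(cell_ids),
    species = species,
    accession = accession,
    source = source,
    categories = list()
  ), class = "scnv_experiment")
}

#' @export
print.scnv_experiment <- function(x, ...) {
  cat(sprintf("<scnv_experiment> %s (%s, %s)\n", x$accession, x$species, x$source))
  cat(sprintf("  %d genes x %d cells, %d nonzero entries (%.2f%% dense)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$matrix@x),
              100 * length(x$matrix@x) / prod(dim(x$matrix))))
  if (length(x$categories)) {
    cat("  categories:", paste(vapply(x$categories, `[[`, "", "name"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.scnv_experiment <- function(x) dim(x$matrix)

#' Construct a cell-annotation category
#'
#' A category is a named set of rows, each row assigning every cell to a group
#' label (e.g. one clustering resolution per row). One row is "selected" and
#' drives differential expression.
#'
#' @param name category name, e.g. `"Cluster"`
#' @param rows list of rows created by [scnv_category_row()]
#' @param selected_row 1-based index of the selected row; defaults to the
#'   first row flagged as default (see [select_default_row()])
#' @return an object of class `scnv_category`
#' @export
scnv_category <- function(name, rows, selected_row = NULL) {
  stopifnot(length(rows) >= 1L)
  cat <- structure(list(name = name, rows = rows, selected_row = 1L),
                   class = "scnv_category")
  cat$selected_row <- if (is.null(selected_row)) select_default_row(cat)
                      else as.integer(selected_row)
  if (cat$selected_row < 1L || cat$selected_row > length(rows)) {
    scnv_error("scnv_consistency_error", "selected_row out of range")
  }
  cat
}

#' One row of a category
#'
#' @param row_label label of the row (for a clustering, the K value as a string)
#' @param assignments named character vector mapping cell id to group label
#' @param is_default whether this row is flagged as the default (the
#'   `sel.K` flag of cluster tables)
#' @return an object of class `scnv_category_row`
#' @export
scnv_category_row <- function(row_label, assignments, is_default = FALSE) {
  if (length(assignments) == 0L) {
    scnv_error("scnv_format_error", "category row assigns no cells")
  }
  structure(list(row_label = as.character(row_label),
                 is_default = isTRUE(is_default),
                 assignments = assignments),
            class = "scnv_category_row")
}

#' @export
print.scnv_category <- function(x, ...) {
  cat(sprintf("<scnv_category> %s: %d row(s), selected row %d\n",
              x$name, length(x$rows), x$selected_row))
  for (i in seq_along(x$rows)) {
    r <- x$rows[[i]]
    cat(sprintf("  [%d]%s %s: %d cells, %d groups\n", i,
                if (r$is_default) "*" else " ", r$row_label,
                length(r$assignments), length(unique(r$assignments))))
  }
  invisible(x)
}

#' Index of the default row of a category
#'
#' Returns the first row flagged as default (for cluster tables, the row whose
#' `sel.K` column is TRUE, i.e. the resolution the atlas itself recommends).
#' When no row is flagged, falls back to the first row with a warning.
#'
#' @param category an [scnv_category()]
#' @return 1-based row index
#' @export
select_default_row <- function(category) {
  stopifnot(inherits(category, "scnv_category"))
  flags <- vapply(category$rows, `[[`, logical(1), "is_default")
  if (any(flags)) return(which(flags)[1L])
  scnv_warn(sprintf("category '%s' has no default row flagged; using row 1",
                    category$name))
  1L
}

#' Attach a category to an experiment
#'
#' Reconciles the category's cells against the experiment: cells present in
#' the category but absent from the matrix are dropped with a warning; matrix
#' cells missing from a category row receive the label `"NA"`, which excludes
#' them from differential expression.
#'
#' @param exp an [scnv_experiment()]
#' @param category an [scnv_category()]
#' @return the experiment with the category appended to `$categories`
#' @export
attach_category <- function(exp, category) {
  stopifnot(inherits(exp, "scnv_experiment"), inherits(category, "scnv_category"))
  for (i in seq_along(category$rows)) {
    a <- category$rows[[i]]$assignments
    extra <- setdiff(names(a), exp$cell_ids)
    if (length(extra)) {
      scnv_warn(sprintf(
        "category '%s' row %d: dropping %d cell(s) absent from the matrix",
        category$name, i, length(extra)))
      a <- a[setdiff(names(a), extra)]
    }
    full <- setNames(rep("NA", length(exp$cell_ids)), exp$cell_ids)
    full[names(a)] <- a
    category$rows[[i]]$assignments <- full
  }
  exp$categories[[category$name]] <- category
  exp
}

# Group labels of the selected (or given) row, aligned to exp$cell_ids.
category_labels <- function(exp, category, row = NULL) {
  if (is.character(category)) {
    if (!category %in% names(exp$categories)) {
      scnv_error("scnv_lookup_error", sprintf("no category named '%s'", category))
    }
    category <- exp$categories[[category]]
  }
  row <- row %||% category$selected_row
  if (row < 1L || row > length(category$rows)) {
    scnv_error("scnv_lookup_error", sprintf("category row %d out of range", row))
  }
  a <- category$rows[[row]]$assignments
  out <- setNames(rep("NA", length(exp$cell_ids)), exp$cell_ids)
  common <- intersect(names(a), exp$cell_ids)
  out[common] <- a[common]
  out
}
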