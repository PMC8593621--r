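#' Cell-plot table: embedding coordinates joined with group labels
#'
#' One record per cell with its 2D coordinates and group label, for rendering
#' an embedding colored by category. Cells present in only one of the two
#' inputs are dropped with a warning (count recorded in the `dropped`
#' attribute).
#'
#' @param embedding an [embed_cells()] result
#' @param row an [scnv_category_row()]
#' @return data.frame of class `scnv_plot_table` with `cell_id`, `x`, `y`,
#'   `group`
#' @export
cell_plot_table <- function(embedding, row) {
  stopifnot(inherits(embedding, "scnv_embedding"),
            inherits(row, "scnv_category_row"))
  common <- intersect(embedding$cell_id, names(row$assignments))
  if (length(common) == 0L) {
    scnv_error("scnv_lookup_error", "embedding and category row share no cells")
  }
  dropped <- (nrow(embedding) - length(common)) +
    (length(row$assignments) - length(common))
  if (dropped > 0L) {
    scnv_warn(sprintf("cell plot: %d cell(s) present in only one input dropped",
                      dropped))
  }
  i <- match(common, embedding$cell_id)
  out <- data.frame(cell_id = common,
                    x = embedding$x[i], y = embedding$y[i],
                    group = unname(row$assignments[common]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("scnv_plot_table", "data.frame"),
            plot = "cell", dropped = dropped,
            x_label = paste0(attr(embedding, "method"), " 1"),
            y_label = paste0(attr(embedding, "method"), " 2"),
            title = sprintf("%s cell plot", attr(embedding, "method")))
}

#' Violin-plot table: one gene's expression across groups
#'
#' One record per labeled cell: the gene's expression value and the cell's
#' group. Jitter is recorded as metadata for the renderer, never applied to
#' the values.
#'
#' @param exp an [scnv_experiment()]
#' @param gene gene identifier (exact match; near misses are suggested)
#' @param row an [scnv_category_row()]
#' @param jitter jitter amount in [0, 1], metadata only
#' @return data.frame of class `scnv_plot_table` with `cell_id`, `value`,
#'   `group`
#' @export
violin_table <- function(exp, gene, row, jitter = 0) {
  stopifnot(inherits(exp, "scnv_experiment"),
            inherits(row, "scnv_category_row"),
            jitter >= 0, jitter <= 1)
  i <- match(gene, exp$gene_ids)
  if (is.na(i)) {
    near <- exp$gene_ids[tolower(exp$gene_ids) == tolower(gene)]
    if (length(near) == 0L) near <- utils::head(agrep(gene, exp$gene_ids, value = TRUE), 3L)
    scnv_error("scnv_lookup_error", sprintf(
      "gene '%s' not found%s", gene,
      if (length(near)) paste0("; did you mean: ", paste(near, collapse = ", "))
      else ""))
  }
  labels <- setNames(rep("NA", length(exp$cell_ids)), exp$cell_ids)
  common <- intersect(names(row$assignments), exp$cell_ids)
  labels[common] <- row$assignments[common]
  keep <- labels != "NA"
  vals <- as.numeric(exp$matrix[i, keep])
  out <- data.frame(cell_id = exp$cell_ids[keep], value = vals,
                    group = unname(labels[keep]), stringsAsFactors = FALSE)
  structure(out, class = c("scnv_plot_table", "data.frame"),
            plot = "violin", gene = gene, jitter = jitter,
            x_label = "group", y_label = "expression",
            title = sprintf("%s across groups", gene),
            accession = exp$accession)
}

#' Heatmap matrix of mean expression for the selected markers
#'
#' Rows are the union of the groups' marker genes in group-blocked order
#' (each group's markers in rank order, a gene appearing once at its first
#' occurrence); columns are the groups; values are the group mean expression
#' (`mean_in`) from the differential-expression table.
#'
#' @param de an [compute_diffexp()] result
#' @param markers a [select_markers()] result
#' @return numeric matrix, selected genes x groups
#' @export
heatmap_matrix <- function(de, markers) {
  stopifnot(inherits(de, "scnv_de"), inherits(markers, "scnv_markers"))
  genes <- unlist(lapply(markers, `[[`, "gene"), use.names = FALSE)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L) {
    scnv_error("scnv_lookup_error", "no marker genes selected for any group")
  }
  groups <- names(markers)
  m <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  for (g in groups) {
    d <- de[de$group == g, , drop = FALSE]
    m[, g] <- d$mean_in[match(genes, d$gene)]
  }
  m
}

#' Volcano-plot table for one group
#'
#' A view over the differential-expression table: x = log2 fold change,
#' y = -log10 FDR, plus the filter flag.
#'
#' @param de an [compute_diffexp()] result
#' @param group group label
#' @return data.frame of class `scnv_plot_table` with `gene`, `log2fc`,
#'   `neg_log10_fdr`, `passed_filters`
#' @export
volcano_table <- function(de, group) {
  stopifnot(inherits(de, "scnv_de"))
  d <- de[de$group == group, , drop = FALSE]
  if (nrow(d) == 0L) {
    scnv_error("scnv_lookup_error", sprintf("no group '%s' in the table", group))
  }
  out <- data.frame(gene = d$gene, log2fc = d$log2fc,
                    neg_log10_fdr = -log10(d$fdr),
                    passed_filters = d$passed_filters,
                    stringsAsFactors = FALSE)
  structure(out, class = c("scnv_plot_table", "data.frame"),
            plot = "volcano", group = group,
            x_label = "log2 fold change", y_label = "-log10 FDR",
            title = sprintf("group %s vs rest", group))
}

#' @export
print.scnv_plot_table <- function(x, ...) {
  cat(sprintf("<scnv_plot_table> %s: %d record(s)\n", attr(x, "plot"), nrow(x)))
  invisible(x)
}

#' Render a plot table or heatmap matrix to PNG
#'
#' Minimal static rendering with base graphics: cell plots as scatter points
#' colored by group, violin tables as stripcharts per group, heatmap matrices
#' via [graphics::image()]. The tables themselves are the tested surface;
#' rendering exists so pipelines can drop a figure next to their CSVs.
#'
#' @param x an `scnv_plot_table` or a [heatmap_matrix()] result
#' @param path output PNG path
#' @param width,height device size in pixels
#' @return `path`, invisibly
#' @export
render_png <- function(x, path, width = 800, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  if (is.matrix(x)) {
    graphics::image(t(x[rev(seq_len(nrow(x))), , drop = FALSE]),
                    axes = FALSE, main = "mean expression")
  } else if (identical(attr(x, "plot"), "cell")) {
    grp <- factor(x$group)
    graphics::plot(x$x, x$y, col = as.integer(grp), pch = 19,
                   xlab = attr(x, "x_label"), ylab = attr(x, "y_label"),
                   main = attr(x, "title"))
    graphics::legend("topright", legend = levels(grp),
                     col = seq_along(levels(grp)), pch = 19, cex = 0.8)
  } else if (identical(attr(x, "plot"), "violin")) {
    graphics::stripchart(value ~ factor(group), data = x, vertical = TRUE,
                         method = "jitter", pch = 19,
                         main = attr(x, "title"),
                         xlab = attr(x, "x_label"), ylab = attr(x, "y_label"))
  } else {
    graphics::plot(x[[2L]], x[[3L]], pch = 19,
                   xlab = attr(x, "x_label"), ylab = attr(x, "y_label"),
                   main = attr(x, "title"))
  }
  invisible(path)
}
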