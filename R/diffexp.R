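#' Differential-expression configuration
#'
#' Cutoffs applied when flagging records for network analysis. The defaults
#' mirror the tool's scripted workflow: a minimum absolute log2 fold change of
#' 0.5 and a minimum of 10% expressing cells in the group or in the rest set.
#'
#' @param log_fc_cutoff minimum |log2 fold change| for `passed_filters`
#' @param min_pct_cutoff minimum percentage (0-100) of expressing cells
#'   required in the group or in the comparison set
#' @param pseudocount value added to both means before taking the ratio, so
#'   genes absent from one side keep a finite fold change
#' @return a list of class `scnv_de_config`
#' @export
de_config <- function(log_fc_cutoff = 0.5, min_pct_cutoff = 10,
                      pseudocount = 0.01) {
  stopifnot(log_fc_cutoff >= 0, min_pct_cutoff >= 0, min_pct_cutoff <= 100,
            pseudocount > 0)
  structure(list(log_fc_cutoff = log_fc_cutoff,
                 min_pct_cutoff = min_pct_cutoff,
                 pseudocount = pseudocount),
            class = "scnv_de_config")
}

#' Log2 fold change of two group means
#'
#' `log2((mean_in + pseudocount) / (mean_out + pseudocount))`: the log base 2
#' of the ratio of a gene's mean expression in one group to its mean
#' expression over all other groups. The pseudocount keeps the ratio finite
#' when the gene is absent from one side.
#'
#' @param mean_in mean expression in the group (vectorized)
#' @param mean_out mean expression in the comparison set
#' @param pseudocount positive stabilizer added to both means
#' @return numeric vector of log2 fold changes
#' @export
log2_fold_change <- function(mean_in, mean_out, pseudocount = 0.01) {
  if (any(mean_in < 0, na.rm = TRUE) || any(mean_out < 0, na.rm = TRUE)) {
    scnv_error("scnv_domain_error", "means must be non-negative")
  }
  stopifnot(pseudocount > 0)
  log2((mean_in + pseudocount) / (mean_out + pseudocount))
}

#' Mann-Whitney U test of one group against the rest
#'
#' Computes the U statistic of `values_in` (midrank tie handling) and a
#' two-sided p-value. For small samples (combined n at most
#' `exact_threshold`) the p-value is exact, by enumeration of all group
#' assignments of the observed values, so ties are handled without
#' approximation; for larger samples the tie-corrected normal approximation
#' with continuity correction is used, which is accurate at single-cell
#' sample sizes.
#'
#' @param values_in expression values of the cells in the group
#' @param values_out expression values of all other labeled cells
#' @param exact_threshold largest combined sample size for which the exact
#'   permutation distribution is enumerated
#' @return list with `u` (the U statistic of the "in" sample) and `p`
#'   (two-sided p-value, clipped into (0, 1])
#' @export
mann_whitney_u <- function(values_in, values_out, exact_threshold = 12L) {
  n1 <- length(values_in); n2 <- length(values_out)
  if (n1 < 1L || n2 < 1L) {
    scnv_error("scnv_insufficient_cells_error",
               "both groups need at least one value")
  }
  x <- c(values_in, values_out)
  r <- rank(x)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (n1 + n2 <= exact_threshold) mwu_exact_p(x, n1, u)
       else mwu_p(u, n1, n2, tie_term(x))
  list(u = u, p = p)
}

# Exact two-sided permutation p-value: over all C(n, n1) assignments of the
# observed values to the "in" group, the probability of a U at least as far
# from its mean n1*n2/2 as the observed one. Handles ties exactly.
mwu_exact_p <- function(x, n1, u_obs) {
  n <- length(x); n2 <- n - n1
  r <- rank(x)
  mu <- n1 * n2 / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# sum over tie groups of t^3 - t, the quantity entering the tie-corrected
# variance of the rank sum
tie_term <- function(x) {
  t <- tabulate(match(x, unique(x)))
  sum(t^3 - t)
}

# Two-sided normal-approximation p for U with tie correction and continuity
# correction. Vectorized over u (and tie_sum). All values tied -> p = 1.
mwu_p <- function(u, n1, n2, tie_sum) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  z <- ifelse(sigma > 0, (abs(u - mu) - 0.5) / sigma, 0)
  z <- pmax(z, 0)
  p <- 2 * pnorm(-z)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validated front over
#' `stats::p.adjust(method = "BH")`. Within the tool the adjustment is
#' applied per group across that group's tested genes.
#'
#' @param p_values numeric vector of p-values in (0, 1]
#' @return adjusted p-values, same length and order as the input
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    scnv_error("scnv_domain_error", "p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' One-vs-rest differential expression over a category row
#'
#' For every group G of the selected category row and every gene, compares
#' the gene's expression in the cells of G against all other labeled cells of
#' the same row: group means, percentages of expressing cells (expression
#' strictly greater than zero), log2 fold change of the means, Mann-Whitney U
#' and its two-sided p-value, and a Benjamini-Hochberg FDR computed within
#' each group across all genes. Cells labeled `"NA"` take part in no
#' comparison. All genes are tested and reported; `passed_filters` flags the
#' records that satisfy the network-analysis cutoffs (at least
#' `min_pct_cutoff`% expressing cells in the group or in the rest set, and
#' |log2FC| at or above `log_fc_cutoff`).
#'
#' @param exp an [scnv_experiment()]
#' @param category an [scnv_category()] or the name of an attached category
#' @param row 1-based category row; defaults to the category's selected row
#' @param config a [de_config()]
#' @return a data.frame of class `scnv_de` with one record per (gene, group):
#'   columns `gene`, `group`, `mean_in`, `mean_out`, `pct_in`, `pct_out`,
#'   `log2fc`, `u_stat`, `p_value`, `fdr`, `passed_filters`
#' @export
compute_diffexp <- function(exp, category, row = NULL, config = de_config()) {
  stopifnot(inherits(exp, "scnv_experiment"), inherits(config, "scnv_de_config"))
  labels <- category_labels(exp, category, row)
  keep <- !is.na(labels) & labels != "NA"
  if (!any(keep)) scnv_error("scnv_domain_error", "no labeled cells")
  labels <- labels[keep]
  groups <- sort(unique(labels))
  if (length(groups) < 2L) {
    scnv_error("scnv_single_group_error", sprintf(
      "selected row has a single group ('%s'); one-vs-rest needs at least two",
      groups[1L]))
  }

  mat <- exp$matrix[, keep, drop = FALSE]
  n_genes <- nrow(mat)
  n_cells <- ncol(mat)
  g_idx <- match(labels, groups)
  n_per <- tabulate(g_idx, nbins = length(groups))

  # Group-wise sums and expressing-cell counts in one sparse product each.
  ind <- Matrix::sparseMatrix(i = seq_len(n_cells), j = g_idx,
                              x = 1, dims = c(n_cells, length(groups)))
  sums <- as.matrix(mat %*% ind)                       # genes x groups
  pos  <- mat; pos@x <- as.numeric(pos@x > 0)
  cnts <- as.matrix(pos %*% ind)                       # expressing cells

  tot_sum <- rowSums(sums)
  tot_cnt <- rowSums(cnts)
  mean_in  <- sweep(sums, 2L, n_per, "/")
  mean_out <- sweep(tot_sum - sums, 2L, n_cells - n_per, "/")
  pct_in   <- sweep(cnts, 2L, n_per, "/") * 100
  pct_out  <- sweep(tot_cnt - cnts, 2L, n_cells - n_per, "/") * 100

  # Rank pass: one dense gene vector at a time (memory stays O(n_cells)),
  # producing the rank sum of every group in a single rowsum.
  u_stat <- matrix(NA_real_, n_genes, length(groups))
  p_val  <- matrix(NA_real_, n_genes, length(groups))
  matT <- Matrix::t(mat)                               # cells x genes: fast column access
  for (j in seq_len(n_genes)) {
    x <- as.numeric(matT[, j])
    r <- rank(x)
    rs <- vapply(split(r, g_idx), sum, numeric(1))     # ranksum per group
    ties <- tie_term(x)
    u <- rs - n_per * (n_per + 1) / 2
    u_stat[j, ] <- u
    p_val[j, ] <- if (n_cells <= 12L) {
      vapply(seq_along(u), function(k) mwu_exact_p(x, n_per[k], u[k]), numeric(1))
    } else {
      mwu_p(u, n_per, n_cells - n_per, ties)
    }
  }

  log2fc <- log2_fold_change(mean_in, mean_out, config$pseudocount)
  fdr <- apply(p_val, 2L, benjamini_hochberg)
  passed <- (pct_in >= config$min_pct_cutoff | pct_out >= config$min_pct_cutoff) &
    abs(log2fc) >= config$log_fc_cutoff

  out <- data.frame(
    gene = rep(exp$gene_ids, times = length(groups)),
    group = rep(groups, each = n_genes),
    mean_in = as.vector(mean_in), mean_out = as.vector(mean_out),
    pct_in = as.vector(pct_in), pct_out = as.vector(pct_out),
    log2fc = as.vector(log2fc), u_stat = as.vector(u_stat),
    p_value = as.vector(p_val), fdr = as.vector(fdr),
    passed_filters = as.vector(passed),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("scnv_de", "data.frame"),
            groups = groups, cells_per_group = setNames(n_per, groups),
            config = config, accession = exp$accession,
            species = exp$species)
}

#' @export
print.scnv_de <- function(x, ...) {
  if (!all(c("gene", "group", "passed_filters") %in% names(x))) {
    return(NextMethod())
  }
  g <- attr(x, "groups") %||% sort(unique(x$group))
  cat(sprintf("<scnv_de> %s: %d genes x %d groups (%s)\n",
              attr(x, "accession") %||% "experiment",
              length(unique(x$gene)), length(g),
              paste(g, collapse = ", ")))
  cat(sprintf("  %d records pass the network-analysis filters\n",
              sum(x$passed_filters)))
  invisible(x)
}

#' @export
summary.scnv_de <- function(object, ...) {
  by_group <- split(object, object$group)
  data.frame(
    group = names(by_group),
    n_cells = as.integer(attr(object, "cells_per_group")[names(by_group)]),
    n_passed = vapply(by_group, function(d) sum(d$passed_filters), integer(1)),
    n_fdr_05 = vapply(by_group, function(d) sum(d$fdr <= 0.05), integer(1)),
    row.names = NULL
  )
}

#' Export a differential-expression table to CSV
#'
#' Column naming follows the tool's table export: `gene, group, mean_in,
#' mean_out, pct_in, pct_out, log2FC, U, p_value, FDR, passed_filters`. The U
#' statistic is the U of the "in" sample.
#'
#' @param de an [compute_diffexp()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
export_diffexp <- function(de, path) {
  out <- data.frame(gene = de$gene, group = de$group,
                    mean_in = de$mean_in, mean_out = de$mean_out,
                    pct_in = de$pct_in, pct_out = de$pct_out,
                    log2FC = de$log2fc, U = de$u_stat,
                    p_value = de$p_value, FDR = de$fdr,
                    passed_filters = de$passed_filters)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back an exported differential-expression table
#'
#' @param path CSV written by [export_diffexp()]
#' @return an `scnv_de` data.frame (group attributes reconstructed)
#' @export
read_diffexp <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(gene = as.character(raw$gene), group = as.character(raw$group),
                    mean_in = raw$mean_in, mean_out = raw$mean_out,
                    pct_in = raw$pct_in, pct_out = raw$pct_out,
                    log2fc = raw$log2FC, u_stat = raw$U,
                    p_value = raw$p_value, fdr = raw$FDR,
                    passed_filters = raw$passed_filters,
                    stringsAsFactors = FALSE)
  structure(out, class = c("scnv_de", "data.frame"),
            groups = sort(unique(out$group)),
            accession = tools::file_path_sans_ext(basename(path)))
}
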