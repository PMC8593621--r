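#' Pre-processing configuration
#'
#' Defaults follow the analysis service the desktop tool delegates to: the
#' matrix is normalized, log-transformed, restricted to the most variable
#' genes and scaled, after dropping cells with fewer than 100 detected genes
#' and genes detected in fewer than 1 cell.
#'
#' @param normalize total-count normalize each cell to the median cell total
#' @param log_transform apply log(1 + x)
#' @param restrict_hvg keep only the `n_hvg` most variable genes
#' @param scale center and scale each gene to unit variance
#' @param min_genes_per_cell minimum number of detected genes per cell
#' @param min_cells_per_gene minimum number of expressing cells per gene
#' @param n_hvg how many highly-variable genes to keep
#' @return a list of class `scnv_preprocess_config`
#' @export
preprocess_config <- function(normalize = TRUE, log_transform = TRUE,
                              restrict_hvg = TRUE, scale = TRUE,
                              min_genes_per_cell = 100L,
                              min_cells_per_gene = 1L,
                              n_hvg = 2000L) {
  structure(list(normalize = normalize, log_transform = log_transform,
                 restrict_hvg = restrict_hvg, scale = scale,
                 min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 n_hvg = as.integer(n_hvg)),
            class = "scnv_preprocess_config")
}

#' Embedding and clustering parameters
#'
#' The exposed knobs: UMAP's number of neighbors and minimum distance;
#' t-SNE's perplexity, initial dimensions (`-1` requests a PCA reduction
#' first), early exaggeration and learning rate; the neighborhood size of the
#' kNN graph behind Leiden/Louvain; and the random seed.
#'
#' @param umap_n_neighbors,umap_min_dist UMAP parameters
#' @param tsne_perplexity,tsne_init_dims,tsne_early_exaggeration,tsne_learning_rate
#'   t-SNE parameters; `tsne_init_dims = -1` triggers a PCA to at most 50
#'   components before t-SNE
#' @param cluster_n_neighbors neighborhood size for the clustering kNN graph
#' @param seed integer seed driving every stochastic step
#' @return a list of class `scnv_embed_params`
#' @export
embed_params <- function(umap_n_neighbors = 15L, umap_min_dist = 0.1,
                         tsne_perplexity = 30, tsne_init_dims = -1L,
                         tsne_early_exaggeration = 12, tsne_learning_rate = 200,
                         cluster_n_neighbors = 15L, seed = 42L) {
  structure(list(umap_n_neighbors = as.integer(umap_n_neighbors),
                 umap_min_dist = umap_min_dist,
                 tsne_perplexity = tsne_perplexity,
                 tsne_init_dims = as.integer(tsne_init_dims),
                 tsne_early_exaggeration = tsne_early_exaggeration,
                 tsne_learning_rate = tsne_learning_rate,
                 cluster_n_neighbors = as.integer(cluster_n_neighbors),
                 seed = as.integer(seed)),
            class = "scnv_embed_params")
}

#' Pre-process an expression matrix
#'
#' Filtering comes first and in a fixed order: cells with fewer than
#' `min_genes_per_cell` detected genes are removed, then genes detected in
#' fewer than `min_cells_per_gene` of the remaining cells. The transforms
#' then apply in order, each gated by its flag: per-cell total-count
#' normalization (target = median cell total), log(1+x), restriction to the
#' most variable genes (by dispersion, variance over mean of the normalized
#' values), and per-gene unit-variance scaling (centered, so the scaled
#' matrix may contain negative values and is no longer sparse).
#'
#' @param exp an [scnv_experiment()]
#' @param config a [preprocess_config()]
#' @return the filtered/transformed experiment; its `report` attribute lists
#'   `removed_cells`, `removed_genes` and the `stages` applied
#' @export
preprocess_experiment <- function(exp, config = preprocess_config()) {
  stopifnot(inherits(exp, "scnv_experiment"),
            inherits(config, "scnv_preprocess_config"))
  m <- exp$matrix
  stages <- character(0)

  detected_per_cell <- Matrix::colSums(m > 0)
  keep_cells <- detected_per_cell >= config$min_genes_per_cell
  if (!any(keep_cells)) {
    scnv_error("scnv_empty_after_filter_error",
               "no cell has enough detected genes after filtering")
  }
  removed_cells <- exp$cell_ids[!keep_cells]
  m <- m[, keep_cells, drop = FALSE]
  cell_ids <- exp$cell_ids[keep_cells]

  cells_per_gene <- Matrix::rowSums(m > 0)
  keep_genes <- cells_per_gene >= config$min_cells_per_gene
  removed_genes <- exp$gene_ids[!keep_genes]
  m <- m[keep_genes, , drop = FALSE]
  gene_ids <- exp$gene_ids[keep_genes]
  gene_symbols <- exp$gene_symbols[keep_genes]
  if (nrow(m) == 0L) {
    scnv_error("scnv_empty_after_filter_error", "no gene survives filtering")
  }
  stages <- c(stages, "filter_cells", "filter_genes")

  if (config$normalize) {
    totals <- Matrix::colSums(m)
    target <- stats::median(totals[totals > 0])
    f <- ifelse(totals > 0, target / totals, 0)
    m <- m %*% Matrix::Diagonal(x = f)
    stages <- c(stages, "normalize")
  }
  if (config$log_transform) {
    m@x <- log1p(m@x)
    stages <- c(stages, "log1p")
  }
  if (config$restrict_hvg && nrow(m) > config$n_hvg) {
    mu <- Matrix::rowMeans(m)
    ex2 <- Matrix::rowMeans(m^2)
    v <- ex2 - mu^2
    dispersion <- ifelse(mu > 0, v / mu, 0)
    top <- order(dispersion, decreasing = TRUE)[seq_len(config$n_hvg)]
    top <- sort(top)
    m <- m[top, , drop = FALSE]
    gene_ids <- gene_ids[top]
    gene_symbols <- gene_symbols[top]
    stages <- c(stages, "hvg")
  } else if (config$restrict_hvg) {
    stages <- c(stages, "hvg")
  }
  if (config$scale) {
    dm <- as.matrix(m)
    mu <- rowMeans(dm)
    sdv <- apply(dm, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    dm <- (dm - mu) / sdv
    m <- dm
    stages <- c(stages, "scale")
  }

  out <- exp
  out$matrix <- if (inherits(m, "Matrix") || !config$scale)
    as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix") else m
  out$gene_ids <- gene_ids
  out$gene_symbols <- gene_symbols
  out$cell_ids <- cell_ids
  # re-reconcile categories against the surviving cells
  for (nm in names(out$categories)) {
    for (i in seq_along(out$categories[[nm]]$rows)) {
      a <- out$categories[[nm]]$rows[[i]]$assignments
      out$categories[[nm]]$rows[[i]]$assignments <- a[intersect(names(a), cell_ids)]
    }
  }
  attr(out, "report") <- list(removed_cells = removed_cells,
                              removed_genes = removed_genes,
                              stages = stages)
  out
}

# cells x features numeric matrix for embedding/clustering
cells_matrix <- function(exp) {
  m <- exp$matrix
  t(as.matrix(m))
}

# PCA reduce a cells x genes matrix to at most k components
pca_reduce <- function(x, k = 50L) {
  k <- min(k, ncol(x), nrow(x) - 1L)
  p <- stats::prcomp(x, rank. = k, center = TRUE, scale. = FALSE)
  p$x
}

#' Two-dimensional embedding of cells
#'
#' UMAP (via uwot) or t-SNE (via Rtsne) on the pre-processed matrix,
#' deterministic under `params$seed`. For t-SNE, `tsne_init_dims = -1`
#' requests a PCA to at most 50 components first; a positive value reduces to
#' that many components instead.
#'
#' @param exp a pre-processed [scnv_experiment()]
#' @param method `"umap"` or `"tsne"`
#' @param params an [embed_params()]
#' @return an object of class `scnv_embedding`: data.frame with `cell_id`,
#'   `x`, `y`; attributes `method`, `params`, `stages`
#' @export
embed_cells <- function(exp, method = c("umap", "tsne"),
                        params = embed_params()) {
  method <- match.arg(method)
  stopifnot(inherits(params, "scnv_embed_params"))
  x <- cells_matrix(exp)
  if (nrow(x) < 3L) {
    scnv_error("scnv_parameter_error", "embedding needs at least 3 cells")
  }
  stages <- character(0)
  set.seed(params$seed)
  if (method == "umap") {
    if (params$umap_n_neighbors >= nrow(x)) {
      scnv_error("scnv_parameter_error", sprintf(
        "umap_n_neighbors = %d but only %d cells are present",
        params$umap_n_neighbors, nrow(x)))
    }
    stages <- c(stages, "umap")
    coords <- uwot::umap(x, n_neighbors = params$umap_n_neighbors,
                         min_dist = params$umap_min_dist,
                         n_threads = 1, n_sgd_threads = 1,
                         seed = params$seed)
  } else {
    if (3 * params$tsne_perplexity >= nrow(x)) {
      scnv_error("scnv_parameter_error", sprintf(
        "tsne_perplexity = %g too large for %d cells (need > 3*perplexity)",
        params$tsne_perplexity, nrow(x)))
    }
    if (params$tsne_init_dims == -1L) {
      x <- pca_reduce(x, 50L); stages <- c(stages, "pca")
    } else if (params$tsne_init_dims > 0L && params$tsne_init_dims < ncol(x)) {
      x <- pca_reduce(x, params$tsne_init_dims); stages <- c(stages, "pca")
    }
    stages <- c(stages, "tsne")
    coords <- Rtsne::Rtsne(x, dims = 2, perplexity = params$tsne_perplexity,
                           exaggeration_factor = params$tsne_early_exaggeration,
                           eta = params$tsne_learning_rate,
                           pca = FALSE, num_threads = 1,
                           check_duplicates = FALSE)$Y
  }
  out <- data.frame(cell_id = exp$cell_ids, x = coords[, 1L], y = coords[, 2L],
                    stringsAsFactors = FALSE)
  structure(out, class = c("scnv_embedding", "data.frame"),
            method = toupper(method), params = params, stages = stages)
}

#' @export
print.scnv_embedding <- function(x, ...) {
  cat(sprintf("<scnv_embedding> %s of %d cells (stages: %s)\n",
              attr(x, "method"), nrow(x),
              paste(attr(x, "stages"), collapse = " -> ")))
  invisible(x)
}

#' Graph-based clustering of cells
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance on a PCA of the
#' pre-processed matrix, `cluster_n_neighbors` neighbors per cell) and runs
#' Louvain or Leiden community detection (igraph implementations, modularity
#' objective). Deterministic under `params$seed`.
#'
#' @param exp a pre-processed [scnv_experiment()]
#' @param algorithm `"leiden"` or `"louvain"`
#' @param params an [embed_params()]
#' @return an [scnv_category_row()] labeling every cell with its cluster
#'   (labels `"0"`, `"1"`, ...; `row_label` is the number of clusters found)
#' @export
cluster_cells <- function(exp, algorithm = c("leiden", "louvain"),
                          params = embed_params()) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(params, "scnv_embed_params"))
  x <- cells_matrix(exp)
  n <- nrow(x)
  if (n < params$cluster_n_neighbors + 1L) {
    scnv_error("scnv_parameter_error", sprintf(
      "clustering needs at least cluster_n_neighbors + 1 = %d cells, have %d",
      params$cluster_n_neighbors + 1L, n))
  }
  if (all(x == 0)) {
    scnv_error("scnv_parameter_error", "matrix is all zero; nothing to cluster")
  }
  x <- pca_reduce(x, 50L)
  d <- as.matrix(stats::dist(x))
  k <- params$cluster_n_neighbors
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  # undirected union of directed kNN edges
  a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
  keep <- !duplicated(cbind(a, b)) & a != b
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  set.seed(params$seed)
  comm <- if (algorithm == "louvain") igraph::cluster_louvain(g)
          else igraph::cluster_leiden(g, objective_function = "modularity",
                                      n_iterations = 5)
  member <- igraph::membership(comm)
  labels <- as.character(as.integer(factor(member)) - 1L)
  scnv_category_row(row_label = as.character(length(unique(labels))),
                    assignments = setNames(labels, exp$cell_ids),
                    is_default = TRUE)
}

#' Export an embedding as CSV
#'
#' @param embedding an [embed_cells()] result
#' @param path output CSV
#' @param row optional [scnv_category_row()] supplying a `group` column
#' @return `path`, invisibly
#' @export
export_embedding <- function(embedding, path, row = NULL) {
  out <- as.data.frame(embedding)
  if (!is.null(row)) {
    out$group <- unname(row$assignments[out$cell_id])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
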