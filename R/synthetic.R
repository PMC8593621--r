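#' Specification of a synthetic experiment with planted markers
#'
#' The generator plants `markers_per_group` genes per group whose mean is
#' shifted by a factor of `2^marker_log2fc` in that group; all other
#' expression is drawn from a shared negative-binomial background, zeroed
#' with probability `dropout_rate` (dropout is group-independent, so fold
#' changes are preserved in expectation), then total-count normalized per
#' cell. The defaults describe the validation conditions used throughout the
#' package: 3 groups of 50 cells, 5 planted markers per group at log2FC = 2,
#' 30% dropout.
#'
#' @param n_groups number of groups (>= 2)
#' @param cells_per_group cells per group (>= 5)
#' @param n_genes total number of genes
#' @param markers_per_group planted marker genes per group
#' @param marker_log2fc planted log2 fold change of marker means
#' @param baseline_mean negative-binomial mean of background expression
#' @param nb_dispersion negative-binomial size parameter
#' @param dropout_rate probability an entry is zeroed
#' @param seed integer seed
#' @return a list of class `scnv_synthetic_spec`
#' @export
synthetic_spec <- function(n_groups = 3L, cells_per_group = 50L,
                           n_genes = 150L, markers_per_group = 5L,
                           marker_log2fc = 2, baseline_mean = 10,
                           nb_dispersion = 50, dropout_rate = 0.3,
                           seed = 42L) {
  if (n_groups < 2L || cells_per_group < 5L) {
    scnv_error("scnv_validation_error",
               "need at least 2 groups of at least 5 cells")
  }
  if (markers_per_group * n_groups > n_genes) {
    scnv_error("scnv_validation_error",
               "markers_per_group * n_groups exceeds n_genes")
  }
  if (dropout_rate < 0 || dropout_rate >= 1 || marker_log2fc < 0 ||
      baseline_mean <= 0) {
    scnv_error("scnv_validation_error", "invalid synthetic parameters")
  }
  structure(list(n_groups = as.integer(n_groups),
                 cells_per_group = as.integer(cells_per_group),
                 n_genes = as.integer(n_genes),
                 markers_per_group = as.integer(markers_per_group),
                 marker_log2fc = marker_log2fc,
                 baseline_mean = baseline_mean,
                 nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "scnv_synthetic_spec")
}

#' Generate a synthetic experiment with known ground truth
#'
#' @param spec a [synthetic_spec()]
#' @return list with `experiment` (an [scnv_experiment()] with the
#'   ground-truth clustering attached as category `"Cluster"`), `category`
#'   (the same [scnv_category()]), and `markers` (data.frame `gene`, `group`
#'   of the planted (gene, group) pairs)
#' @export
generate_experiment <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "scnv_synthetic_spec"))
  set.seed(spec$seed)
  n_cells <- spec$n_groups * spec$cells_per_group
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  cell_ids <- sprintf("C%04d", seq_len(n_cells))
  groups <- as.character(rep(seq_len(spec$n_groups) - 1L,
                             each = spec$cells_per_group))

  # planted markers: the first markers_per_group * n_groups genes, one block
  # per group
  truth <- data.frame(
    gene = gene_ids[seq_len(spec$markers_per_group * spec$n_groups)],
    group = as.character(rep(seq_len(spec$n_groups) - 1L,
                             each = spec$markers_per_group)),
    stringsAsFactors = FALSE)

  mu <- matrix(spec$baseline_mean, spec$n_genes, n_cells)
  for (g in unique(truth$group)) {
    genes_g <- match(truth$gene[truth$group == g], gene_ids)
    mu[genes_g, groups == g] <- spec$baseline_mean * 2^spec$marker_log2fc
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = spec$nb_dispersion),
                   spec$n_genes, n_cells)
  if (spec$dropout_rate > 0) {
    keep <- matrix(rbinom(length(counts), 1L, 1 - spec$dropout_rate),
                   spec$n_genes, n_cells)
    counts <- counts * keep
  }
  # per-cell total-count normalization to the median cell total
  totals <- colSums(counts)
  target <- stats::median(totals[totals > 0])
  norm <- sweep(counts, 2L, ifelse(totals > 0, totals / target, 1), "/")

  exp <- scnv_experiment(Matrix::Matrix(norm, sparse = TRUE),
                         gene_ids, cell_ids,
                         species = "Homo sapiens",
                         accession = sprintf("SYN-%d", spec$seed),
                         source = "file")
  category <- scnv_category("Cluster", list(
    scnv_category_row(row_label = as.character(spec$n_groups),
                      assignments = setNames(groups, cell_ids),
                      is_default = TRUE)))
  exp <- attach_category(exp, category)
  list(experiment = exp, category = category, markers = truth, spec = spec)
}

#' Generate a STRING-style interaction table with planted modules
#'
#' Edges among same-group planted markers appear with probability
#' `within_module_prob` and carry combined scores uniform on [0.7, 1.0];
#' background edges between any other marker pair appear with probability
#' `background_prob` and score uniform on [0.15, 0.45]. Planted module edges
#' therefore survive the default 0.4 score cutoff while background edges
#' mostly do not. An alias table mapping each gene to a protein id
#' (`P_<gene>`) accompanies the edges.
#'
#' @param markers data.frame `gene`, `group` (the generator's ground truth)
#' @param within_module_prob edge probability within a group's marker set
#' @param background_prob edge probability between other marker pairs
#' @param seed integer seed
#' @return an [scnv_interactions()] with planted-edge bookkeeping in the
#'   `planted` attribute (data.frame `protein1`, `protein2`)
#' @export
generate_interactions <- function(markers, within_module_prob = 0.9,
                                  background_prob = 0.05, seed = 42L) {
  stopifnot(within_module_prob >= 0, within_module_prob <= 1,
            background_prob >= 0, background_prob <= 1)
  set.seed(seed)
  genes <- unique(markers$gene)
  aliases <- data.frame(gene = genes,
                        protein = if (length(genes)) paste0("P_", genes)
                                  else character(0),
                        stringsAsFactors = FALSE)
  if (length(genes) < 2L) {
    return(structure(scnv_interactions(
      data.frame(protein1 = character(0), protein2 = character(0),
                 score = numeric(0)), aliases = aliases),
      planted = data.frame(protein1 = character(0), protein2 = character(0))))
  }
  pairs <- t(utils::combn(genes, 2L))
  grp <- function(g) markers$group[match(g, markers$gene)]
  same <- grp(pairs[, 1L]) == grp(pairs[, 2L])
  prob <- ifelse(same, within_module_prob, background_prob)
  present <- runif(nrow(pairs)) < prob
  score <- ifelse(same, runif(nrow(pairs), 0.7, 1.0),
                  runif(nrow(pairs), 0.15, 0.45))
  edges <- data.frame(protein1 = paste0("P_", pairs[present, 1L]),
                      protein2 = paste0("P_", pairs[present, 2L]),
                      score = score[present], stringsAsFactors = FALSE)
  structure(scnv_interactions(edges, aliases = aliases),
            planted = edges[same[present], c("protein1", "protein2")])
}

#' Write an interaction source to STRING-format files
#'
#' @param interactions an [scnv_interactions()]
#' @param edges_path output TSV (`protein1`, `protein2`, `combined_score`)
#' @param aliases_path optional output TSV for the gene-to-protein aliases
#' @return invisibly, the edge path
#' @export
write_string_edges <- function(interactions, edges_path, aliases_path = NULL) {
  utils::write.table(
    data.frame(protein1 = interactions$edges$protein1,
               protein2 = interactions$edges$protein2,
               combined_score = interactions$edges$score),
    edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(aliases_path) && !is.null(interactions$aliases)) {
    utils::write.table(interactions$aliases, aliases_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(edges_path)
}
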