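#' Network-analysis configuration
#'
#' Cutoffs used to pick the top marker genes per group and to filter
#' interaction edges. Defaults mirror the tool's scripted workflow: FDR at
#' most 0.5, |log2FC| at least 1.0, at most 200 genes per group, both signs
#' kept; the interaction-score cutoff of 0.4 is STRING's "medium confidence".
#'
#' @param fdr_cutoff maximum FDR for a marker gene, in (0, 1]
#' @param log2fc_cutoff minimum |log2 fold change|
#' @param max_genes maximum number of genes kept per group
#' @param positive_only keep only up-regulated markers (log2FC > 0)
#' @param string_score_cutoff minimum combined interaction score in [0, 1]
#' @param species organism name used for live interaction queries
#' @return a list of class `scnv_network_config`
#' @export
network_config <- function(fdr_cutoff = 0.5, log2fc_cutoff = 1.0,
                           max_genes = 200L, positive_only = FALSE,
                           string_score_cutoff = 0.4, species = "unknown") {
  stopifnot(fdr_cutoff > 0, fdr_cutoff <= 1, log2fc_cutoff >= 0,
            max_genes >= 1, string_score_cutoff >= 0, string_score_cutoff <= 1)
  structure(list(fdr_cutoff = fdr_cutoff, log2fc_cutoff = log2fc_cutoff,
                 max_genes = as.integer(max_genes),
                 positive_only = isTRUE(positive_only),
                 string_score_cutoff = string_score_cutoff,
                 species = species),
            class = "scnv_network_config")
}

#' Select the top marker genes of every group
#'
#' Per group, keeps the records that passed the differential-expression
#' filters and satisfy `fdr <= fdr_cutoff` and `|log2fc| >= log2fc_cutoff`
#' (with `log2fc > 0` when `positive_only`), ranks them by FDR ascending,
#' breaking ties by |log2FC| descending and then gene id, and truncates to
#' `max_genes`.
#'
#' @param de an [compute_diffexp()] result
#' @param config a [network_config()]
#' @return an object of class `scnv_markers`: a named list with one
#'   data.frame (`gene`, `log2fc`, `fdr`, in rank order) per group
#' @export
select_markers <- function(de, config = network_config()) {
  stopifnot(inherits(de, "scnv_de"), inherits(config, "scnv_network_config"))
  groups <- attr(de, "groups") %||% sort(unique(de$group))
  sel <- lapply(groups, function(g) {
    d <- de[de$group == g & de$passed_filters &
              de$fdr <= config$fdr_cutoff &
              abs(de$log2fc) >= config$log2fc_cutoff, , drop = FALSE]
    if (config$positive_only) d <- d[d$log2fc > 0, , drop = FALSE]
    d <- d[order(d$fdr, -abs(d$log2fc), d$gene), , drop = FALSE]
    d <- utils::head(d, config$max_genes)
    if (nrow(d) == 0L) {
      scnv_warn(sprintf("group '%s' has no genes passing the network cutoffs", g))
    }
    data.frame(gene = d$gene, log2fc = d$log2fc, fdr = d$fdr,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(setNames(sel, groups), class = "scnv_markers",
            config = config, accession = attr(de, "accession"),
            species = attr(de, "species"))
}

#' @export
print.scnv_markers <- function(x, ...) {
  cat(sprintf("<scnv_markers> %d group(s)\n", length(x)))
  for (g in names(x)) cat(sprintf("  %s: %d gene(s)\n", g, nrow(x[[g]])))
  invisible(x)
}

#' Read a STRING-style interaction table
#'
#' Expects columns `protein1`, `protein2`, `combined_score` (header required;
#' whitespace- or tab-separated). Scores given as 0-1000 integers, STRING's
#' native scale, are detected and divided by 1000; 0-1 reals pass through.
#'
#' @param path path to the edge table
#' @param aliases optional path to a two-column table mapping gene id to
#'   protein id (header `gene`, `protein` or none)
#' @return a list of class `scnv_interactions` with `edges` (data.frame
#'   `protein1`, `protein2`, `score`) and `aliases` (data.frame or NULL)
#' @export
read_string_edges <- function(path, aliases = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df))) {
    scnv_error("scnv_format_error", sprintf(
      "interaction table %s must have columns %s", path, paste(need, collapse = ", ")))
  }
  score <- as.numeric(df$combined_score)
  if (length(score) && max(score) > 1) score <- score / 1000
  al <- NULL
  if (!is.null(aliases)) {
    al <- utils::read.table(aliases, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(unlist(al[1, ])), c("gene", "protein"))) al <- al[-1, ]
    names(al) <- c("gene", "protein")
    al$gene <- as.character(al$gene); al$protein <- as.character(al$protein)
  }
  scnv_interactions(data.frame(protein1 = as.character(df$protein1),
                               protein2 = as.character(df$protein2),
                               score = score, stringsAsFactors = FALSE),
                    aliases = al)
}

#' Construct an interaction source from in-memory tables
#'
#' @param edges data.frame with columns `protein1`, `protein2`, `score`
#'   (scores in [0, 1])
#' @param aliases optional data.frame mapping `gene` to `protein`; when NULL,
#'   gene ids are used as protein ids directly
#' @return a list of class `scnv_interactions`
#' @export
scnv_interactions <- function(edges, aliases = NULL) {
  stopifnot(all(c("protein1", "protein2", "score") %in% names(edges)))
  structure(list(edges = edges, aliases = aliases), class = "scnv_interactions")
}

# gene -> protein mapping; identity when no alias table is supplied
map_genes <- function(genes, interactions) {
  if (is.null(interactions$aliases)) {
    data.frame(gene = genes, protein = genes, stringsAsFactors = FALSE)
  } else {
    i <- match(genes, interactions$aliases$gene)
    data.frame(gene = genes, protein = interactions$aliases$protein[i],
               stringsAsFactors = FALSE)
  }
}

#' Build the category union network over all groups' markers
#'
#' Nodes are the proteins encoded by the union of every group's selected
#' marker genes (one interaction query over the concatenated list, so edges
#' between markers of different groups are kept). Edges are the interactions
#' among those proteins whose combined score reaches
#' `config$string_score_cutoff`; self-loops are dropped and undirected
#' duplicates collapsed to the highest-scoring record. Genes with no protein
#' mapping are reported in the `unmapped` attribute, never silently dropped;
#' mapped genes with no surviving edge stay as isolated nodes. Each node
#' carries the log2FC and FDR of its gene in every group that selected it.
#'
#' @param markers a [select_markers()] result
#' @param interactions an [scnv_interactions()] source (offline edge table)
#'   or a function `(genes, species) -> scnv_interactions` for live queries
#' @param config a [network_config()]
#' @return an object of class `scnv_network` with `nodes` and `edges`
#'   data.frames, `kind = "category_union"`
#' @export
build_union_network <- function(markers, interactions,
                                config = network_config()) {
  stopifnot(inherits(markers, "scnv_markers"))
  union_genes <- sort(unique(unlist(lapply(markers, `[[`, "gene"), use.names = FALSE)))
  if (is.function(interactions)) {
    interactions <- interactions(union_genes, config$species)
  }
  stopifnot(inherits(interactions, "scnv_interactions"))

  mapping <- map_genes(union_genes, interactions)
  unmapped <- mapping$gene[is.na(mapping$protein)]
  mapping <- mapping[!is.na(mapping$protein), , drop = FALSE]
  if (nrow(mapping) == 0L) {
    scnv_error("scnv_empty_network_error", "no marker gene maps to a protein")
  }

  nodes <- data.frame(protein = mapping$protein, gene = mapping$gene,
                      stringsAsFactors = FALSE)
  for (g in names(markers)) {
    i <- match(nodes$gene, markers[[g]]$gene)
    nodes[[paste0("log2fc_", g)]] <- markers[[g]]$log2fc[i]
    nodes[[paste0("fdr_", g)]] <- markers[[g]]$fdr[i]
    nodes[[paste0("selected_", g)]] <- !is.na(i)
  }

  e <- interactions$edges
  e <- e[e$protein1 %in% nodes$protein & e$protein2 %in% nodes$protein &
           e$score >= config$string_score_cutoff &
           e$protein1 != e$protein2, , drop = FALSE]
  if (nrow(e)) {
    a <- pmin(e$protein1, e$protein2); b <- pmax(e$protein1, e$protein2)
    e <- data.frame(from = a, to = b, score = e$score, stringsAsFactors = FALSE)
    e <- e[order(e$from, e$to, -e$score), , drop = FALSE]
    e <- e[!duplicated(e[c("from", "to")]), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(from = character(0), to = character(0), score = numeric(0))
  }

  structure(list(nodes = nodes, edges = e,
                 name = sprintf("%s: all groups", attr(markers, "accession") %||% "experiment"),
                 kind = "category_union", group = NA_character_),
            class = "scnv_network", unmapped = unmapped,
            config = config)
}

#' Extract one induced subnetwork per group
#'
#' A group's subnetwork keeps the union-network nodes whose gene is in that
#' group's marker list, together with the edges of the union network whose
#' two endpoints both survive (induced subgraph). A group with an empty
#' marker list yields an empty subnetwork. With the union network this makes
#' number-of-groups + 1 networks in total.
#'
#' @param union a [build_union_network()] result
#' @param markers the [select_markers()] result the union was built from
#' @return list of `scnv_network` objects, one per group, in group order
#' @export
extract_group_subnetworks <- function(union, markers) {
  stopifnot(inherits(union, "scnv_network"), inherits(markers, "scnv_markers"))
  lapply(setNames(names(markers), names(markers)), function(g) {
    nodes <- union$nodes[union$nodes$gene %in% markers[[g]]$gene, , drop = FALSE]
    rownames(nodes) <- NULL
    e <- union$edges[union$edges$from %in% nodes$protein &
                       union$edges$to %in% nodes$protein, , drop = FALSE]
    rownames(e) <- NULL
    structure(list(nodes = nodes, edges = e,
                   name = sprintf("%s: group %s",
                                  sub(":.*$", "", union$name), g),
                   kind = "group_subnetwork", group = g),
              class = "scnv_network", config = attr(union, "config"))
  })
}

#' @export
print.scnv_network <- function(x, ...) {
  cat(sprintf("<scnv_network> %s [%s]: %d nodes, %d edges\n",
              x$name, x$kind, nrow(x$nodes), nrow(x$edges)))
  un <- attr(x, "unmapped")
  if (length(un)) cat(sprintf("  %d unmapped gene(s): %s\n", length(un),
                              paste(utils::head(un, 5L), collapse = ", ")))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param network an `scnv_network`
#' @return an undirected igraph graph with node/edge attributes
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "scnv_network"))
  vertices <- network$nodes
  names(vertices)[1] <- "name"
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = vertices)
}

#' Write a network to GraphML
#'
#' @param network an `scnv_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  # GraphML cannot carry NA numeric attributes portably; blank them to NaN
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a network in SIF (simple interaction format)
#'
#' One `source interacts target` line per edge; isolated nodes are written as
#' bare node lines so no marker disappears from the file.
#'
#' @param network an `scnv_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network_sif <- function(network, path) {
  lines <- character(0)
  if (nrow(network$edges)) {
    lines <- paste(network$edges$from, "interacts", network$edges$to, sep = "\t")
  }
  isolated <- setdiff(network$nodes$protein,
                      c(network$edges$from, network$edges$to))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Write node and edge attribute tables for a network
#'
#' Nodes: one row per (node, group) with that group's log2FC and FDR; edges:
#' `source`, `target`, `score`.
#'
#' @param network an `scnv_network`
#' @param nodes_path,edges_path output CSV paths
#' @return invisibly, a list of the two paths
#' @export
export_network_tables <- function(network, nodes_path, edges_path) {
  gcols <- grep("^log2fc_", names(network$nodes), value = TRUE)
  groups <- sub("^log2fc_", "", gcols)
  rows <- lapply(groups, function(g) {
    sel <- network$nodes[[paste0("selected_", g)]]
    data.frame(gene = network$nodes$gene[sel], group = g,
               log2FC = network$nodes[[paste0("log2fc_", g)]][sel],
               FDR = network$nodes[[paste0("fdr_", g)]][sel],
               stringsAsFactors = FALSE)
  })
  node_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = network$nodes$gene, group = NA, log2FC = NA, FDR = NA)
  utils::write.csv(node_tab, nodes_path, row.names = FALSE)
  utils::write.csv(data.frame(source = network$edges$from,
                              target = network$edges$to,
                              score = network$edges$score),
                   edges_path, row.names = FALSE)
  invisible(list(nodes = nodes_path, edges = edges_path))
}

#' Live STRING interaction source
#'
#' Returns a function suitable as the `interactions` argument of
#' [build_union_network()]: it queries the STRING network endpoint for the
#' gene list (no added interactors, viruses excluded, mirroring the protein
#' query the desktop tool issues) and parses the TSV response. Requires
#' network access; offline analyses should use [read_string_edges()].
#'
#' @param transport a function `url -> local file path`; defaults to a
#'   downloader. Injectable so recorded responses can stand in for the API.
#' @param base_url STRING API root
#' @return a function `(genes, species) -> scnv_interactions`
#' @export
string_api_source <- function(transport = NULL,
                              base_url = "https://string-db.org/api/tsv/network") {
  transport <- transport %||% function(url) {
    dest <- tempfile("string_")
    ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE), error = function(e) 1L)
    if (!identical(ok, 0L)) {
      scnv_error("scnv_transport_error", sprintf("STRING request failed: %s", url))
    }
    dest
  }
  function(genes, species) {
    url <- paste0(base_url, "?identifiers=",
                  utils::URLencode(paste(genes, collapse = "\r"), reserved = TRUE),
                  "&species=", utils::URLencode(species, reserved = TRUE),
                  "&add_nodes=0&includesViruses=false")
    path <- transport(url)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    # response columns: preferredName_A/B carry the query identifiers; score
    # is the combined score on [0, 1]
    a <- df$preferredName_A %||% df$protein1
    b <- df$preferredName_B %||% df$protein2
    s <- df$score %||% df$combined_score
    scnv_interactions(data.frame(protein1 = a, protein2 = b,
                                 score = as.numeric(s), stringsAsFactors = FALSE))
  }
}
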