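# Marker selection and functional-interaction network construction

# A hand-set DE table: 6 genes x 2 groups with chosen (fdr, log2fc).
toy_de_table <- function() {
  recs <- expand.grid(gene = paste0("g", 1:6), group = c("G1", "G2"),
                      stringsAsFactors = FALSE)
  recs$log2fc <- c( 2.0, -1.5, 1.2, 0.8, 3.0, 1.1,
                   -2.0,  1.5, 0.4, 1.9, 1.0, 2.5)
  recs$fdr    <- c(0.01, 0.01, 0.20, 0.03, 0.40, 0.60,
                   0.02, 0.05, 0.01, 0.30, 0.49, 0.55)
  recs$p_value <- recs$fdr / 2
  recs$mean_in <- 2^recs$log2fc; recs$mean_out <- 1
  recs$pct_in <- 50; recs$pct_out <- 50
  recs$u_stat <- 10
  recs$passed_filters <- TRUE
  structure(recs, class = c("scnv_de", "data.frame"),
            groups = c("G1", "G2"), accession = "TOY")
}

# Brute-force filter/sort/truncate over every record.
oracle_select <- function(de, fdr_cutoff, log2fc_cutoff, max_genes,
                          positive_only) {
  out <- list()
  for (g in unique(de$group)) {
    keep <- de$group == g & de$passed_filters & de$fdr <= fdr_cutoff &
      abs(de$log2fc) >= log2fc_cutoff
    if (positive_only) keep <- keep & de$log2fc > 0
    d <- de[keep, ]
    d <- d[order(d$fdr, -abs(d$log2fc), d$gene), ]
    out[[g]] <- head(d$gene, max_genes)
  }
  out
}

test_that("marker selection matches a brute-force oracle on the toy table", {
  de <- toy_de_table()
  for (cfg in list(network_config(),
                   network_config(fdr_cutoff = 0.05),
                   network_config(log2fc_cutoff = 1.5),
                   network_config(max_genes = 2),
                   network_config(positive_only = TRUE))) {
    got <- suppressWarnings(select_markers(de, cfg))
    want <- oracle_select(de, cfg$fdr_cutoff, cfg$log2fc_cutoff,
                          cfg$max_genes, cfg$positive_only)
    for (g in names(want)) expect_identical(got[[g]]$gene, want[[g]])
  }
})

test_that("negative markers are excluded when positive_only is set", {
  mk <- select_markers(toy_de_table(), network_config(positive_only = TRUE))
  expect_false("g2" %in% mk$G1$gene)   # log2fc = -1.5 in G1
  expect_true("g2" %in% mk$G2$gene)    # +1.5 in G2
})

test_that("max_genes truncates to the smallest-FDR genes", {
  set.seed(8)
  n <- 300
  de <- structure(data.frame(
    gene = sprintf("g%03d", 1:n), group = "G1",
    mean_in = 2, mean_out = 1, pct_in = 50, pct_out = 50,
    log2fc = runif(n, 1.2, 3), u_stat = 1,
    p_value = runif(n, 1e-6, 0.2), fdr = runif(n, 1e-6, 0.4),
    passed_filters = TRUE, stringsAsFactors = FALSE),
    class = c("scnv_de", "data.frame"), groups = "G1")
  mk <- select_markers(de, network_config(max_genes = 200))
  expect_identical(nrow(mk$G1), 200L)
  expect_lte(max(mk$G1$fdr), sort(de$fdr)[200])
  expect_false(is.unsorted(mk$G1$fdr))
})

test_that("raising the FDR cutoff never removes marker genes", {
  de <- toy_de_table()
  lo <- suppressWarnings(select_markers(de, network_config(fdr_cutoff = 0.05)))
  hi <- suppressWarnings(select_markers(de, network_config(fdr_cutoff = 0.5)))
  for (g in names(lo)) expect_true(all(lo[[g]]$gene %in% hi[[g]]$gene))
})

toy_markers <- function(sel) {
  # sel: named list group -> character vector of genes
  structure(lapply(sel, function(gs) {
    data.frame(gene = gs, log2fc = rep(2, length(gs)),
               fdr = rep(0.01, length(gs)), stringsAsFactors = FALSE)
  }), class = "scnv_markers", accession = "TOY")
}

test_that("the union network applies the score cutoff on a toy graph", {
  mk <- toy_markers(list(g1 = c("A", "B"), g2 = c("C", "D")))
  ia <- scnv_interactions(data.frame(
    protein1 = c("A", "B", "C"), protein2 = c("B", "C", "D"),
    score = c(0.9, 0.3, 0.8), stringsAsFactors = FALSE))
  net <- build_union_network(mk, ia, network_config(string_score_cutoff = 0.4))
  expect_setequal(net$nodes$protein, c("A", "B", "C", "D"))
  expect_identical(nrow(net$edges), 2L)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "C D"))
})

test_that("markers missing from the alias table are reported, not dropped silently", {
  mk <- toy_markers(list(g1 = c("A", "B", "Z")))
  ia <- scnv_interactions(
    data.frame(protein1 = "pA", protein2 = "pB", score = 0.9),
    aliases = data.frame(gene = c("A", "B"), protein = c("pA", "pB")))
  net <- build_union_network(mk, ia)
  expect_identical(attr(net, "unmapped"), "Z")
  expect_setequal(net$nodes$protein, c("pA", "pB"))
})

test_that("a marker absent from the edge table stays as an isolated node", {
  mk <- toy_markers(list(g1 = c("A", "B", "C")))
  ia <- scnv_interactions(data.frame(protein1 = "A", protein2 = "B",
                                     score = 0.9))
  net <- build_union_network(mk, ia)
  expect_true("C" %in% net$nodes$protein)
  expect_false("C" %in% c(net$edges$from, net$edges$to))
})

test_that("node attributes carry each group's DE statistics", {
  mk <- structure(list(
    g1 = data.frame(gene = c("A", "B"), log2fc = c(2, 3), fdr = c(0.01, 0.02)),
    g2 = data.frame(gene = "B", log2fc = -1.2, fdr = 0.3)),
    class = "scnv_markers")
  ia <- scnv_interactions(data.frame(protein1 = "A", protein2 = "B", score = 1))
  net <- build_union_network(mk, ia)
  b <- net$nodes[net$nodes$gene == "B", ]
  expect_equal(b$log2fc_g1, 3); expect_equal(b$fdr_g1, 0.02)
  expect_equal(b$log2fc_g2, -1.2); expect_true(b$selected_g2)
  a <- net$nodes[net$nodes$gene == "A", ]
  expect_true(is.na(a$log2fc_g2)); expect_false(a$selected_g2)
})

test_that("an all-unmapped marker set raises an empty-network error", {
  mk <- toy_markers(list(g1 = "Z"))
  ia <- scnv_interactions(
    data.frame(protein1 = "pA", protein2 = "pB", score = 0.9),
    aliases = data.frame(gene = "A", protein = "pA"))
  expect_error(build_union_network(mk, ia), class = "scnv_empty_network_error")
})

test_that("subnetworks are induced subgraphs, verified against a brute-force scan", {
  set.seed(21)
  for (trial in 1:10) {
    genes <- sprintf("G%02d", 1:12)
    groups <- list(a = sample(genes, 5), b = sample(genes, 4),
                   c = sample(genes, 6))
    mk <- toy_markers(groups)
    pairs <- t(combn(genes, 2))
    present <- runif(nrow(pairs)) < 0.4
    ia <- scnv_interactions(data.frame(
      protein1 = pairs[present, 1], protein2 = pairs[present, 2],
      score = runif(sum(present)), stringsAsFactors = FALSE))
    cfg <- network_config(string_score_cutoff = 0.3)
    un <- build_union_network(mk, ia, cfg)
    subs <- extract_group_subnetworks(un, mk)
    expect_identical(length(subs), length(groups))
    for (g in names(groups)) {
      sub <- subs[[g]]
      expect_setequal(sub$nodes$gene, intersect(un$nodes$gene, groups[[g]]))
      # brute-force edge scan over the union's edges
      want <- un$edges[un$edges$from %in% sub$nodes$protein &
                         un$edges$to %in% sub$nodes$protein, ]
      expect_identical(nrow(sub$edges), nrow(want))
      expect_setequal(paste(sub$edges$from, sub$edges$to),
                      paste(want$from, want$to))
      # independent check via igraph's induced_subgraph
      gi <- igraph::induced_subgraph(as_igraph(un),
                                     intersect(un$nodes$protein, sub$nodes$protein))
      expect_equal(igraph::ecount(gi), nrow(sub$edges), ignore_attr = TRUE)
      # subnetwork edges are a subset of union edges
      expect_true(all(paste(sub$edges$from, sub$edges$to) %in%
                        paste(un$edges$from, un$edges$to)))
    }
  }
})

test_that("group count plus union always gives n_groups + 1 networks", {
  for (k in c(2L, 5L)) {
    sel <- setNames(lapply(1:k, function(i) paste0("A", i)), paste0("grp", 1:k))
    mk <- toy_markers(sel)
    ia <- scnv_interactions(data.frame(protein1 = "A1", protein2 = "A2",
                                       score = 0.9))
    un <- build_union_network(mk, ia)
    subs <- extract_group_subnetworks(un, mk)
    expect_identical(length(subs) + 1L, k + 1L)
  }
})

test_that("raising the score cutoff never adds edges", {
  mk <- toy_markers(list(g1 = paste0("N", 1:8)))
  set.seed(5)
  pairs <- t(combn(paste0("N", 1:8), 2))
  ia <- scnv_interactions(data.frame(protein1 = pairs[, 1], protein2 = pairs[, 2],
                                     score = runif(nrow(pairs))))
  prev <- Inf
  for (cut in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    net <- build_union_network(mk, ia, network_config(string_score_cutoff = cut))
    expect_lte(nrow(net$edges), prev)
    expect_true(all(net$edges$score >= cut))
    prev <- nrow(net$edges)
  }
})

test_that("STRING 0-1000 integer scores are detected and rescaled", {
  d <- local_tempdir()
  f <- file.path(d, "links.tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "pA\tpB\t900", "pB\tpC\t150"), f)
  ia <- read_string_edges(f)
  expect_equal(ia$edges$score, c(0.9, 0.15))
  f2 <- file.path(d, "links_real.tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "pA\tpB\t0.9"), f2)
  expect_equal(read_string_edges(f2)$edges$score, 0.9)
})

test_that("networks export to GraphML/SIF and read back with igraph", {
  d <- local_tempdir()
  mk <- toy_markers(list(g1 = c("A", "B"), g2 = "C"))
  ia <- scnv_interactions(data.frame(protein1 = c("A", "B"),
                                     protein2 = c("B", "C"),
                                     score = c(0.9, 0.8)))
  net <- build_union_network(mk, ia)
  gml <- file.path(d, "net.graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3, ignore_attr = TRUE)
  expect_equal(igraph::ecount(g), 2, ignore_attr = TRUE)
  sif <- file.path(d, "net.sif")
  write_network_sif(net, sif)
  expect_identical(length(readLines(sif)), 2L)
  paths <- export_network_tables(net, file.path(d, "n.csv"), file.path(d, "e.csv"))
  nt <- read.csv(paths$nodes); et <- read.csv(paths$edges)
  expect_setequal(nt$gene[nt$group == "g1"], c("A", "B"))
  expect_identical(names(et), c("source", "target", "score"))
})
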