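# Independent oracles and small fixture builders shared across tests. The
# oracles deliberately use brute force (enumeration, dense scans) so they
# share no code path with the implementation they check.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mwu_p <- function(values_in, values_out) {
  x <- c(values_in, values_out)
  n1 <- length(values_in); n <- length(x)
  mu <- n1 * (n - n1) / 2
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hand-rolled BH step-up, independent of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Dense one-vs-rest summary for a single (gene, group) pair.
oracle_de_record <- function(values, labels, group, pseudocount = 0.01) {
  vin <- values[labels == group]
  vout <- values[labels != group & labels != "NA"]
  list(mean_in = mean(vin), mean_out = mean(vout),
       pct_in = 100 * mean(vin > 0), pct_out = 100 * mean(vout > 0),
       log2fc = log2((mean(vin) + pseudocount) / (mean(vout) + pseudocount)))
}

# A tiny hand-built experiment: 4 genes x 6 cells, two groups of 3.
toy_experiment <- function() {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 2, 2, 2, 3, 4, 4),
    j = c(1, 2, 3, 4, 5, 6, 1, 2, 5),
    x = c(5, 4, 6, 5, 4, 6, 2, 1, 1),
    dims = c(4, 6))
  exp <- scnv_experiment(m, gene_ids = paste0("g", 1:4),
                         cell_ids = paste0("c", 1:6),
                         species = "Homo sapiens", accession = "TOY")
  cat <- scnv_category("Cluster", list(
    scnv_category_row("2", setNames(rep(c("A", "B"), each = 3),
                                    paste0("c", 1:6)), is_default = TRUE)))
  attach_category(exp, cat)
}

local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("scnvtest_")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
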