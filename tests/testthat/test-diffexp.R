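# One-vs-rest differential expression: fold change, Mann-Whitney U, BH FDR

test_that("log2 fold change follows the mean-ratio formula", {
  expect_equal(log2_fold_change(3.7, 3.7), 0)
  expect_equal(log2_fold_change(4, 1, pseudocount = 1e-12), 2, tolerance = 1e-9)
  expect_equal(log2_fold_change(1, 0, pseudocount = 0.01),
               log2(1.01 / 0.01), tolerance = 1e-12)
  expect_equal(log2_fold_change(1, 0), 6.658, tolerance = 1e-3)
  expect_error(log2_fold_change(-1, 2), class = "scnv_domain_error")
})

test_that("exchanging in and out negates log2fc", {
  set.seed(3)
  a <- runif(20, 0, 5); b <- runif(20, 0, 5)
  expect_equal(log2_fold_change(mean(a), mean(b)),
               -log2_fold_change(mean(b), mean(a)))
})

test_that("the printed U and exact p are reproduced for [5,5] vs [1,1]", {
  w <- mann_whitney_u(c(5, 5), c(1, 1))
  expect_equal(w$u, 4)
  expect_equal(w$p, 1 / 3, tolerance = 1e-12)
})

test_that("identical multisets give the null U and p near 1", {
  w <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$u, 9 / 2)
  expect_gte(w$p, 0.99)
})

test_that("p agrees with the exhaustive-permutation oracle within 0.05 at small n", {
  set.seed(11)
  worst <- 0
  for (trial in 1:60) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    # mix of continuous and heavily tied data
    pool <- if (trial %% 2 == 0) rnorm(n1 + n2) else sample(0:2, n1 + n2, TRUE)
    vin <- pool[seq_len(n1)]; vout <- pool[-seq_len(n1)]
    got <- mann_whitney_u(vin, vout)$p
    want <- oracle_mwu_p(vin, vout)
    worst <- max(worst, abs(got - want))
  }
  expect_lte(worst, 0.05)
})

test_that("the large-sample approximation tracks wilcox.test", {
  set.seed(4)
  for (trial in 1:10) {
    vin <- rnorm(30); vout <- rnorm(45, mean = runif(1, -1, 1))
    got <- mann_whitney_u(vin, vout)
    ref <- wilcox.test(vin, vout, exact = FALSE, correct = TRUE)
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the null rejection rate is calibrated at n 8 vs 12", {
  set.seed(20240915)
  hits <- replicate(500, {
    mann_whitney_u(rnorm(8), rnorm(12))$p < 0.05
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("empty groups raise an insufficient-cells error", {
  expect_error(mann_whitney_u(numeric(0), c(1, 2)),
               class = "scnv_insufficient_cells_error")
})

test_that("BH adjustment matches the hand-computed step-up and its properties", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_identical(benjamini_hochberg(numeric(0)), numeric(0))
  set.seed(99)
  for (trial in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  }
  expect_error(benjamini_hochberg(c(0.5, 0)), class = "scnv_domain_error")
})

test_that("the full table matches a dense per-record oracle on a toy matrix", {
  exp <- toy_experiment()
  de <- compute_diffexp(exp, "Cluster")
  labels <- setNames(rep(c("A", "B"), each = 3), paste0("c", 1:6))
  for (k in seq_len(nrow(de))) {
    vals <- as.numeric(exp$matrix[match(de$gene[k], exp$gene_ids), ])
    want <- oracle_de_record(vals, labels, de$group[k])
    expect_equal(de$mean_in[k], want$mean_in)
    expect_equal(de$mean_out[k], want$mean_out)
    expect_equal(de$pct_in[k], want$pct_in)
    expect_equal(de$pct_out[k], want$pct_out)
    expect_equal(de$log2fc[k], want$log2fc)
    vin <- vals[labels == de$group[k]]; vout <- vals[labels != de$group[k]]
    w <- mann_whitney_u(vin, vout)
    expect_equal(de$u_stat[k], w$u)
    expect_equal(de$p_value[k], w$p)
  }
  # FDR is BH within each group
  for (g in c("A", "B")) {
    expect_equal(de$fdr[de$group == g],
                 oracle_bh(de$p_value[de$group == g]))
  }
})

test_that("in/out symmetry holds across the two groups of a 2-group table", {
  de <- compute_diffexp(toy_experiment(), "Cluster")
  a <- de[de$group == "A", ]; b <- de[de$group == "B", ]
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_in, b$mean_out)
})

test_that("group cell counts partition the labeled cells", {
  gen <- generate_experiment(synthetic_spec(n_genes = 30, cells_per_group = 8,
                                            seed = 5))
  de <- compute_diffexp(gen$experiment, "Cluster")
  expect_identical(sum(attr(de, "cells_per_group")), 24L)
})

test_that("low-percentage and low-fold-change records fail the filters", {
  # gene expressed in 1/20 (5%) of each side, large values so log2fc is big
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 21, 1), x = c(9, 1, 1),
                            dims = c(2, 40))
  exp <- scnv_experiment(m, c("gA", "gB"), sprintf("c%d", 1:40))
  cat <- scnv_category("Cluster", list(scnv_category_row(
    "2", setNames(rep(c("G1", "G2"), each = 20), sprintf("c%d", 1:40)),
    is_default = TRUE)))
  exp <- attach_category(exp, cat)
  de <- compute_diffexp(exp, "Cluster")
  rec <- de[de$gene == "gA" & de$group == "G1", ]
  expect_equal(rec$pct_in, 5); expect_equal(rec$pct_out, 5)
  expect_false(rec$passed_filters)

  # |log2fc| below the 0.5 default fails regardless of significance
  de2 <- compute_diffexp(toy_experiment(), "Cluster",
                         config = de_config(log_fc_cutoff = 0.5))
  weak <- abs(de2$log2fc) < 0.5
  expect_false(any(de2$passed_filters[weak]))
  # and every passing record satisfies the stated conjunction
  ok <- (de2$pct_in >= 10 | de2$pct_out >= 10) & abs(de2$log2fc) >= 0.5
  expect_identical(de2$passed_filters, ok)
})

test_that("cells labeled NA are excluded from both sides", {
  exp <- toy_experiment()
  cat <- scnv_category("Partial", list(scnv_category_row(
    "2", c(c1 = "A", c2 = "A", c3 = "NA", c4 = "B", c5 = "B", c6 = "NA"),
    is_default = TRUE)))
  exp <- attach_category(exp, cat)
  de <- compute_diffexp(exp, "Partial")
  rec <- de[de$gene == "g1" & de$group == "A", ]
  expect_equal(rec$mean_in, mean(c(5, 4)))
  expect_equal(rec$mean_out, 0)
})

test_that("a single-group row is rejected", {
  exp <- toy_experiment()
  cat <- scnv_category("One", list(scnv_category_row(
    "1", setNames(rep("X", 6), paste0("c", 1:6)), is_default = TRUE)))
  exp <- attach_category(exp, cat)
  expect_error(compute_diffexp(exp, "One"), class = "scnv_single_group_error")
})

test_that("planted markers are recovered with calibrated effect sizes", {
  gen <- generate_experiment(synthetic_spec(seed = 42))
  de <- compute_diffexp(gen$experiment, "Cluster")
  rec <- merge(gen$markers, de, by = c("gene", "group"))
  expect_identical(nrow(rec), 15L)
  expect_true(all(rec$passed_filters))
  expect_gte(mean(rec$fdr <= 0.05), 0.9)
  expect_gte(median(rec$log2fc), 1.5)
  expect_lte(median(rec$log2fc), 2.5)
  # planted records carry the smallest FDRs of their groups
  for (g in unique(rec$group)) {
    dg <- de[de$group == g, ]
    top <- dg$gene[order(dg$fdr)][1:5]
    expect_gte(length(intersect(top, rec$gene[rec$group == g])), 4L)
  }
})

test_that("the DE table export round-trips through CSV", {
  d <- local_tempdir()
  de <- compute_diffexp(toy_experiment(), "Cluster")
  path <- export_diffexp(de, file.path(d, "de.csv"))
  header <- readLines(path, n = 1)
  expect_match(header, "gene.*group.*log2FC.*U.*p_value.*FDR.*passed_filters")
  back <- read_diffexp(path)
  expect_equal(back$log2fc, de$log2fc)
  expect_equal(back$fdr, de$fdr)
  expect_identical(back$passed_filters, de$passed_filters)
})
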