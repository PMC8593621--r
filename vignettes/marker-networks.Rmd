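---
title: "From cell clusters to marker networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cell clusters to marker networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnetkit)
```

`scnetkit` interprets groups of cells in a single-cell RNA-seq experiment by
(1) testing every gene one-vs-rest for differential expression, (2) selecting
top markers per group under explicit cutoffs, and (3) projecting the markers
onto a functional-interaction network. This vignette explains the model
behind each step, the parameters that matter, the numerical choices, and
what the synthetic validation does and does not establish.

## The one-vs-rest model

A *category* is a named annotation of cells (a clustering, a cell type
assignment, a disease state); one *row* of a category maps every cell to a
group label. For the selected row with groups $g = 1, \dots, K$, each gene is
compared between the cells of group $g$ ("in") and all other labeled cells
("out"). Cells labeled `"NA"` — typically cells present in the matrix but
missing from the annotation — take part in no comparison. One-vs-rest is the
only supported design: the comparison set is always the complement within
the same row, so the $K$ per-group tests partition the labeled cells.

Per (gene, group) record the package reports:

* `mean_in`, `mean_out`: group means of the normalized expression values.
* `pct_in`, `pct_out`: percentage of cells with expression strictly greater
  than zero. Zero is the natural detection threshold for normalized counts;
  no other threshold is configurable because none is well defined across
  normalization schemes.
* `log2fc` $= \log_2\frac{\text{mean\_in} + c}{\text{mean\_out} + c}$ with
  pseudocount $c = 0.01$ (configurable). Without $c$, a marker absent from
  the rest set has an undefined fold change; $c$ small relative to typical
  normalized means leaves well-expressed genes essentially untouched while
  capping the fold change of barely-detected ones at
  $\log_2(\text{mean\_in}/0.01)$.
* `u_stat`, `p_value`: the Mann–Whitney U of the "in" sample and its
  two-sided p-value (below).
* `fdr`: Benjamini–Hochberg adjustment of the p-values, applied within each
  group across that group's tested genes. Group-wise adjustment matches the
  per-group marker-list semantics of network construction: each group's
  list is a separate family of discoveries.
* `passed_filters`: TRUE iff (`pct_in` ≥ 10 **or** `pct_out` ≥ 10) **and**
  |`log2fc`| ≥ 0.5 (both cutoffs configurable via `de_config()`). The
  "or" keeps genes that vanish in one side — exactly the markers of
  interest. Filters are flags, not exclusions: every gene is tested and
  reported, because the filters exist to reduce noise in the downstream
  interaction network, not to censor the table.

## The rank test and its p-value

Expression values are ranked with midranks across the combined sample and
$U = R_{\text{in}} - n_{\text{in}}(n_{\text{in}}+1)/2$ is taken for the "in"
sample (the exported `U` column documents this convention). Two regimes
compute the p-value:

* **Combined $n \le 12$:** the exact two-sided permutation p —
  $P(|U - \mu| \ge |U_{\text{obs}} - \mu|)$ over all
  $\binom{n}{n_\text{in}}$ assignments of the observed values, $\mu =
  n_\text{in} n_\text{out}/2$. Enumeration costs at most
  $\binom{12}{6} = 924$ assignments and handles ties exactly. A pure normal
  approximation is badly biased at such sizes: for `[5,5]` vs `[1,1]` it
  gives 0.19 where the exact answer is 1/3.
* **Larger samples:** the normal approximation with tie-corrected variance
  $\sigma^2 = \frac{n_1 n_2}{12}\left(n + 1 - \frac{\sum_t (t^3 -
  t)}{n(n-1)}\right)$ and a 0.5 continuity correction. At single-cell group
  sizes (tens to hundreds of cells) its error is far below any decision
  threshold; the test suite bounds the small-$n$ error against the exact
  oracle and checks type-I calibration at $n = 8$ vs $12$ (rejection rate at
  $p < 0.05$ within $[0.02, 0.09]$).

Degenerate inputs: if every value is tied, $\sigma = 0$ and the p-value is
1. P-values are clipped into $(0, 1]$. An empty side raises an
insufficient-cells error; a selected row with a single group is rejected
outright since no comparison set exists.

## Marker selection and network construction

`select_markers()` keeps, per group, the records with `passed_filters`,
`fdr` ≤ 0.5, |`log2fc`| ≥ 1.0 (only positive if `positive_only`), ranks them
by FDR ascending with ties broken by |log2FC| descending then gene id, and
truncates to 200 genes. Defaults follow the scripted workflow the package
mirrors (`fdrCutoff=0.5`, `log2FCCutoff=1.0`, `maxgenes=200`,
`positiveOnly=false`). The ranking key itself is a design choice — "top
differentially expressed" could plausibly mean smallest p, smallest FDR, or
largest fold change; FDR-first with a fold-change tie-break is used and
documented so results are reproducible even if other tools rank
differently.

`build_union_network()` issues **one** query over the concatenated marker
lists of all groups, so the union network retains interactions between
markers of different groups. Offline sources are STRING-format edge tables
(`protein1`, `protein2`, `combined_score`; 0–1000 integer scores are
auto-detected and divided by 1000) with an optional gene-to-protein alias
table; without aliases, gene identifiers are used as protein identifiers
directly. Live queries go through `string_api_source()` with the
protein-query semantics (no added interactors, viruses excluded). Edges
below the combined-score cutoff (default 0.4, STRING's "medium confidence")
are dropped post-hoc, self-loops removed, and undirected duplicates
collapsed to the highest-scoring record. Genes that map to no protein are
collected in the `unmapped` attribute — reported, never silently dropped —
and mapped genes without surviving edges remain as isolated nodes, since an
unconnected marker is still a marker.

`extract_group_subnetworks()` induces one subnetwork per group: the union
nodes whose gene is in the group's marker list plus all union edges with
both endpoints surviving. Together with the union this always yields
$K + 1$ networks; an empty marker list yields an empty subnetwork rather
than an error so a weakly separated group does not abort a workflow. Two
monotonicity properties follow from the construction and are enforced by
tests: raising the score cutoff never adds edges, and relaxing the FDR
cutoff never removes markers.

## Pre-processing, embeddings, clustering

`preprocess_experiment()` filters cells first, then genes — cells with fewer
than 100 detected genes, then genes detected in fewer than 1 remaining cell
(both configurable) — followed by optional transforms in a fixed order:
per-cell total-count normalization to the **median cell total** (a scale
the data itself sets, avoiding an arbitrary constant), $\log(1+x)$,
restriction to the 2000 most variable genes (dispersion = variance/mean of
the normalized values), and per-gene centering/unit-variance scaling. The
filter stage is idempotent; the transform defaults mirror the conventional
single-cell pipeline this package interoperates with. The HVG count,
normalization target and scaling behavior are documented defaults of this
implementation, not reproductions of any service's unpublished values.
Scaling densifies and introduces negative values, so differential
expression should run on the normalized (unscaled) matrix; scaled output
feeds embeddings and clustering.

Embeddings delegate to established implementations — UMAP via uwot, t-SNE
via Rtsne — exposing exactly the parameters that matter: number of
neighbors and minimum distance for UMAP; perplexity, initial dimensions,
early exaggeration and learning rate for t-SNE. `tsne_init_dims = -1`
requests a PCA to at most 50 components before t-SNE (a positive value
reduces to that many components); the `stages` attribute of the returned
embedding records whether PCA ran. Clustering builds a k-nearest-neighbor
graph (Euclidean distance on a 50-component PCA, `cluster_n_neighbors`
neighbors, undirected union of directed kNN edges) and applies igraph's
Louvain or Leiden (modularity objective) community detection. Every
stochastic step is seeded through `embed_params(seed=)` and is reproducible
on a single machine with single-threaded execution, which is how the
package runs them.

## The synthetic generator

`generate_experiment()` plants known structure so the whole pipeline can be
validated offline: background counts are negative binomial with common mean
`baseline_mean` and size `nb_dispersion`; each group's
`markers_per_group` genes have their mean multiplied by
$2^{\texttt{marker\_log2fc}}$ in that group; entries are zeroed
independently with probability `dropout_rate`; cells are total-count
normalized to the median cell total. Because dropout is group-independent,
the planted log2 fold change survives in expectation through dropout and
normalization, which is what makes effect-size recovery testable.

The defaults — 3 groups × 50 cells, 5 markers per group at log2FC = 2, 30%
dropout — are the validation conditions used by the acceptance checks. The
free parameters were set once by a power analysis across 60 seeds:
`baseline_mean = 10` and `nb_dispersion = 50` emulate moderately expressed,
robustly detected marker genes (after normalization, technical
overdispersion is modest; the binding noise source is dropout), and
`n_genes = 150` keeps the multiple-testing burden at the level of a
compact, focused panel. Under these conditions mean planted-marker recall
at FDR ≤ 0.05 is about 0.97. Notably, 30% dropout caps the achievable
rank-test separation (the Wilcoxon AUC cannot exceed roughly 0.75
regardless of effect size), so a small percentage of planted markers
missing the FDR threshold in any given run is a property of the stated
conditions, not a defect; with a full-transcriptome gene count the same
conditions would push typical recall below 0.9 through the
Benjamini–Hochberg threshold alone.

What the generator does **not** emulate: library-size variation, batch
structure, gene–gene correlation, expression-dependent dropout, or
realistic mean-variance profiles across thousands of genes. Passing tests
on this generator demonstrate that the statistics, filters and network
logic are implemented correctly under controlled conditions — not that any
particular biological dataset will yield markers at a given rate.

`generate_interactions()` plants network modules the same way: edges among
same-group markers appear with probability 0.9 and scores uniform on
$[0.7, 1.0]$; background marker pairs connect with probability 0.05 and
scores on $[0.15, 0.45]$. The default 0.4 score cutoff therefore retains
every planted module edge and at most the thin $[0.4, 0.45]$ sliver of the
background, so union-network recovery of the planted modules is a sharp
check.

## Data access and formats

MatrixMarket triples (`.mtx` + `.mtx_rows` + `.mtx_cols`) are read from
directories or zip/tar.gz/tgz/gzipped-tar archives; coordinate entries are
1-based per the MatrixMarket convention and storage is column-compressed
sparse, so memory follows the nonzero count. `.mtx_rows` may carry one or
two columns; the first is the canonical gene identifier, the second an
optional display symbol. Duplicate gene identifiers are kept as separate
matrix rows and flagged with a warning — merging them would silently alter
the statistics. Category tables are delimiter-sniffed (comma vs tab from
the header line). Cluster tables arrive with groups in rows (`sel.K`, `K`,
then one column per cell; the `sel.K` flag marks the default resolution,
with a first-row fallback plus warning when no flag is set); cell-metadata
tables arrive with cells in rows and are read with `transpose = TRUE`, each
annotation column becoming one category row. Group labels are treated as
opaque strings throughout — no assumption about 0- versus 1-based cluster
numbering. On attachment, category cells missing from the matrix are
dropped with a warning, and matrix cells missing from the category get the
label `"NA"`, excluding them from differential expression.

The atlas clients wrap the public REST endpoints of the two supported
repositories, with an on-disk cache (key: source + accession + file type; a
second fetch performs zero transport requests) and a recorded-fixture mode
that replays payloads from a directory, so every client behavior is
testable with no network. Timeouts are 60 s with 3 retries and exponential
backoff. For the project index of the second repository, a single project
may carry one matrix per organ; each matrix file becomes an independent
entry. Only the first-generation data-coordination API is implemented; the
successor catalog is rejected as unsupported rather than guessed at. The
raw per-experiment JSON is stored alongside the parsed fields since the
listing schema is release-dependent.

## Known limitations

* Only one-vs-rest comparisons; arbitrary two-group contrasts are out of
  scope.
* No normalization or batch correction of raw counts: input matrices must
  already be normalized.
* Loom/HDF5/AnnData inputs are not supported; MatrixMarket triples and
  delimited tables are the interchange formats.
* The interactive rendering layer of the original desktop workflow
  (linked selections, styled canvases) is deliberately absent: plot tables
  and static PNGs are the supported surface.
* Problem sizes in the test suite and acceptance script are compact by
  design (hundreds of cells, 60–150 genes) — the package's own validation
  conditions, chosen so the full pipeline, including enumeration oracles,
  runs in seconds while exercising every code path.
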