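#' Read an expression matrix from a MatrixMarket triple
#'
#' Reads the three-file MatrixMarket layout used by the Single Cell Expression
#' Atlas: a coordinate `.mtx` file plus `.mtx_rows` (gene identifiers, with an
#' optional second column of gene symbols) and `.mtx_cols` (cell barcodes).
#' The triple may live in a directory or inside a zip, tar.gz, tgz or gzipped
#' tar archive. Coordinate entries are 1-based per the MatrixMarket standard;
#' storage is a column-compressed sparse matrix, so memory scales with the
#' number of nonzero entries.
#'
#' @param path path to a directory or archive holding exactly one `.mtx`, one
#'   `.mtx_rows` and one `.mtx_cols` file
#' @param species organism name recorded on the experiment
#' @param accession experiment identifier; defaults to the file/dir name
#' @param source provenance tag, one of `"file"`, `"GXA"`, `"HCA"`
#' @return an [scnv_experiment()]
#' @export
read_mtx_triple <- function(path, species = "unknown",
                            accession = NULL, source = "file") {
  if (!file.exists(path)) {
    scnv_error("scnv_io_error", sprintf("path does not exist: %s", path))
  }
  accession <- accession %||% sub("\\.(zip|tar\\.gz|tgz|gz|tar)$", "",
                                  basename(path), ignore.case = TRUE)
  dir <- if (dir.exists(path)) path else extract_archive(path)

  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  member <- function(suffix) {
    hit <- files[grepl(paste0("\\", suffix, "(\\.gz)?$"), files)]
    if (suffix == ".mtx") hit <- hit[!grepl("\\.mtx_(rows|cols)(\\.gz)?$", hit)]
    if (length(hit) == 0L) {
      scnv_error("scnv_format_error",
                 sprintf("no file with suffix '%s' found in %s", suffix, path))
    }
    if (length(hit) > 1L) {
      scnv_error("scnv_format_error",
                 sprintf("multiple files with suffix '%s' found in %s", suffix, path))
    }
    hit
  }
  mtx_file  <- member(".mtx")
  rows_file <- member(".mtx_rows")
  cols_file <- member(".mtx_cols")

  m <- Matrix::readMM(mtx_file)
  rows <- read_delim_matrix(rows_file)
  cols <- read_delim_matrix(cols_file)
  gene_ids <- rows[, 1L]
  gene_symbols <- if (ncol(rows) >= 2L) rows[, 2L] else NULL
  cell_ids <- cols[, 1L]

  if (nrow(m) != length(gene_ids)) {
    scnv_error("scnv_consistency_error", sprintf(
      "matrix header declares %d rows but .mtx_rows lists %d genes",
      nrow(m), length(gene_ids)))
  }
  if (ncol(m) != length(cell_ids)) {
    scnv_error("scnv_consistency_error", sprintf(
      "matrix header declares %d columns but .mtx_cols lists %d cells",
      ncol(m), length(cell_ids)))
  }
  scnv_experiment(m, gene_ids, cell_ids, species = species,
                  accession = accession, source = source,
                  gene_symbols = gene_symbols)
}

# Unpack a zip/tar.gz/tgz/gz archive into a fresh temp dir and return it.
extract_archive <- function(path) {
  dir <- tempfile("scnv_extract_")
  dir.create(dir)
  lower <- tolower(path)
  if (grepl("\\.zip$", lower)) {
    utils::unzip(path, exdir = dir)
  } else if (grepl("\\.(tar\\.gz|tgz|tar|gz)$", lower)) {
    # plain .gz is accepted as a gzipped tar; untar autodetects compression
    utils::untar(path, exdir = dir)
  } else {
    scnv_error("scnv_format_error", sprintf(
      "unrecognized archive type: %s (expected zip, tar.gz, tgz or gz)", path))
  }
  dir
}

#' Write an experiment (and optional category) in the atlas archive layout
#'
#' Emits `<accession>.mtx`, `.mtx_rows` and `.mtx_cols` plus, when a category
#' is given, a `<accession>.clusters.tsv` in the cluster-table dialect
#' (columns `sel.K`, `K`, then one column per cell). With
#' `archive = "tar.gz"` the files are bundled into a single archive that
#' [read_mtx_triple()] reads back unchanged.
#'
#' @param exp an [scnv_experiment()]
#' @param dir output directory (created if missing)
#' @param category optional [scnv_category()] written alongside the matrix
#' @param archive `"none"` to leave loose files, `"tar.gz"` to bundle the
#'   matrix triple
#' @return path to the archive, or to `dir` for loose files
#' @export
write_experiment <- function(exp, dir, category = NULL,
                             archive = c("none", "tar.gz")) {
  archive <- match.arg(archive)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) scnv_error("scnv_io_error", sprintf("cannot create directory %s", dir))
  }
  base <- file.path(dir, exp$accession)
  Matrix::writeMM(exp$matrix, paste0(base, ".mtx"))
  rows <- if (is.null(exp$gene_symbols)) exp$gene_ids
          else paste(exp$gene_ids, exp$gene_symbols, sep = "\t")
  writeLines(rows, paste0(base, ".mtx_rows"))
  writeLines(exp$cell_ids, paste0(base, ".mtx_cols"))

  if (!is.null(category)) {
    write_category_csv(category, paste0(base, ".clusters.tsv"),
                       cell_ids = exp$cell_ids)
  }

  if (archive == "tar.gz") {
    tarball <- paste0(base, ".tar.gz")
    members <- paste0(exp$accession, c(".mtx", ".mtx_rows", ".mtx_cols"))
    old <- setwd(dir); on.exit(setwd(old))
    utils::tar(basename(tarball), files = members, compression = "gzip",
               tar = "internal")
    unlink(members)
    return(tarball)
  }
  invisible(dir)
}

#' Read a category table from CSV/TSV
#'
#' Two orientations exist in the wild. Cluster tables ship groups in rows and
#' cells in columns, with leading `sel.K` and `K` columns (`transpose =
#' FALSE`). Cell-metadata tables ship cells in rows and annotations in
#' columns; read those with `transpose = TRUE`, which transposes the table
#' first so that every metadata column becomes one category row. The
#' delimiter (comma or tab) is sniffed from the header line.
#'
#' @param path path to the table
#' @param transpose transpose the table before interpreting it (cell-metadata
#'   orientation)
#' @param name category name; defaults to `"Cluster"` for cluster tables and
#'   the file name otherwise
#' @return an [scnv_category()]
#' @export
read_category_csv <- function(path, transpose = FALSE, name = NULL) {
  m <- read_delim_matrix(path)
  if (transpose) m <- t(m)
  if (nrow(m) < 2L) {
    scnv_error("scnv_empty_category_error",
               sprintf("category table %s has no data rows", path))
  }
  header <- m[1L, ]
  body <- m[-1L, , drop = FALSE]
  clusters_dialect <- length(header) >= 3L &&
    tolower(header[1L]) == "sel.k" && tolower(header[2L]) == "k"

  if (clusters_dialect) {
    cells <- header[-(1:2)]
    rows <- lapply(seq_len(nrow(body)), function(i) {
      scnv_category_row(
        row_label = body[i, 2L],
        assignments = setNames(body[i, -(1:2)], cells),
        is_default = toupper(body[i, 1L]) == "TRUE")
    })
    name <- name %||% "Cluster"
  } else {
    cells <- header[-1L]
    if (length(cells) == 0L) {
      scnv_error("scnv_format_error", sprintf("category table %s has no cell columns", path))
    }
    rows <- lapply(seq_len(nrow(body)), function(i) {
      scnv_category_row(row_label = body[i, 1L],
                        assignments = setNames(body[i, -1L], cells))
    })
    name <- name %||% tools::file_path_sans_ext(basename(path))
  }
  suppressWarnings(scnv_category(name, rows))
}

#' Write a category in the cluster-table dialect
#'
#' @param category an [scnv_category()]
#' @param path output path (TSV)
#' @param cell_ids cell order to write; defaults to the first row's cells
#' @return `path`, invisibly
#' @export
write_category_csv <- function(category, path, cell_ids = NULL) {
  cell_ids <- cell_ids %||% names(category$rows[[1L]]$assignments)
  lines <- paste(c("sel.K", "K", cell_ids), collapse = "\t")
  for (r in category$rows) {
    a <- setNames(rep("NA", length(cell_ids)), cell_ids)
    common <- intersect(names(r$assignments), cell_ids)
    a[common] <- r$assignments[common]
    lines <- c(lines, paste(c(if (r$is_default) "TRUE" else "FALSE",
                              r$row_label, unname(a)), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
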