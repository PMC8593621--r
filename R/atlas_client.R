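# REST clients for the two public atlases. Every payload fetch goes through
# client_get(), which consults an on-disk cache first and otherwise asks the
# client's transport: either a live HTTP download or a recorded-fixture store,
# so the whole client surface is testable offline. The transport-call counter
# makes cache behavior assertable.

GXA_EXPERIMENTS_URL <- "https://www.ebi.ac.uk/gxa/sc/json/experiments"
GXA_MATRIX_URL <- "https://www.ebi.ac.uk/gxa/sc/experiment/%s/download/zip?fileType=normalised"
GXA_CLUSTERS_URL <- "https://www.ebi.ac.uk/gxa/sc/experiment/%s/download?fileType=cluster"
GXA_DESIGN_URL <- "https://www.ebi.ac.uk/gxa/sc/experiment/%s/download?fileType=experiment-design"
HCA_PROJECTS_URL <- "https://service.azul.data.humancellatlas.org/index/projects"

#' The Human Cell Atlas project filter restricting results to matrix files
#'
#' The projects index lists raw sequencing artifacts alongside computed
#' matrices; this JSON filter, URL-encoded into the `filters` query option,
#' keeps only projects with matrix files.
#'
#' @return the filter as a JSON string
#' @export
hca_filter_json <- function() '{"fileFormat":{"is":["matrix"]}}'

#' Create an atlas client
#'
#' A client bundles a transport (live HTTP, or a directory of recorded
#' responses for offline use), an on-disk cache, and a request counter. With
#' `fixture_dir` set, payloads are looked up by key in that directory and no
#' network access ever happens.
#'
#' @param fixture_dir directory of recorded payloads (offline mode), or NULL
#'   for live HTTP
#' @param cache_dir cache directory; payloads are re-read from here without
#'   touching the transport. Defaults to a per-session temp directory.
#' @param timeout HTTP timeout in seconds (live mode)
#' @param retries number of HTTP retry attempts (live mode)
#' @return an object of class `scnv_client`
#' @export
atlas_client <- function(fixture_dir = NULL,
                         cache_dir = file.path(tempdir(), "scnv_cache"),
                         timeout = 60, retries = 3L) {
  if (!is.null(fixture_dir) && !dir.exists(fixture_dir)) {
    scnv_error("scnv_io_error", sprintf("fixture dir does not exist: %s", fixture_dir))
  }
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(fixture_dir = fixture_dir, cache_dir = cache_dir,
                 timeout = timeout, retries = as.integer(retries),
                 counter = new.env(parent = emptyenv())),
            class = "scnv_client")
}

#' Number of transport requests a client has performed
#'
#' Counts fixture reads and live downloads alike; cache hits do not count.
#'
#' @param client an [atlas_client()]
#' @return integer request count
#' @export
request_count <- function(client) {
  get0("n", envir = client$counter, ifnotfound = 0L)
}

# Fetch a payload: cache, then transport. `key` names the payload in both the
# cache and the fixture store; fixture files may carry any archive extension.
client_get <- function(client, url, key) {
  hit <- list.files(client$cache_dir, pattern = paste0("^", gsub("([.\\\\])", "\\\\\\1", key)),
                    full.names = TRUE)
  if (length(hit)) return(hit[[1L]])

  n <- request_count(client)
  assign("n", n + 1L, envir = client$counter)

  if (!is.null(client$fixture_dir)) {
    src <- list.files(client$fixture_dir,
                      pattern = paste0("^", gsub("([.\\\\])", "\\\\\\1", key)),
                      full.names = TRUE)
    if (length(src) == 0L) {
      scnv_error("scnv_unknown_accession_error", sprintf(
        "no recorded payload '%s' in fixture store (url: %s)", key, url))
    }
    dest <- file.path(client$cache_dir, basename(src[[1L]]))
    file.copy(src[[1L]], dest, overwrite = TRUE)
    return(dest)
  }

  dest <- file.path(client$cache_dir, key)
  old <- getOption("timeout"); options(timeout = client$timeout)
  on.exit(options(timeout = old))
  for (attempt in seq_len(client$retries)) {
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                       error = function(e) -1L)
    if (identical(status, 0L)) return(dest)
    Sys.sleep(2^(attempt - 1L))
  }
  unlink(dest)
  scnv_error("scnv_transport_error", sprintf("request failed after %d attempts: %s",
                                             client$retries, url))
}

parse_json_payload <- function(path, url) {
  tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
           error = function(e) {
             scnv_error("scnv_transport_error", sprintf(
               "malformed JSON from %s: %s", url, conditionMessage(e)))
           })
}

#' List the experiments of the Single Cell Expression Atlas
#'
#' One entry per experiment in the atlas's JSON listing, with accession,
#' species, cell count and description populated; the raw per-experiment JSON
#' is kept in `$raw` rather than guessing a full metadata schema.
#'
#' @param client an [atlas_client()]
#' @return list of entries of class `scnv_atlas_entry`
#' @export
list_gxa_entries <- function(client) {
  path <- client_get(client, GXA_EXPERIMENTS_URL, "gxa_experiments.json")
  payload <- parse_json_payload(path, GXA_EXPERIMENTS_URL)
  exps <- payload$experiments %||% payload
  if (length(exps) == 0L) {
    scnv_warn("atlas listing is empty")
    return(list())
  }
  lapply(exps, function(e) {
    structure(list(
      accession = e$experimentAccession %||% e$accession,
      description = e$experimentDescription %||% e$description %||% "",
      species = e$species %||% "unknown",
      n_cells = as.integer(e$numberOfAssays %||% e$numberOfCells %||% 0L),
      source = "GXA", download_url = NA_character_, raw = e),
      class = "scnv_atlas_entry")
  })
}

#' @export
print.scnv_atlas_entry <- function(x, ...) {
  cat(sprintf("<%s> %s (%s, %d cells): %s\n", x$source, x$accession,
              x$species, x$n_cells, substr(x$description, 1, 60)))
  invisible(x)
}

#' Fetch one Single Cell Expression Atlas experiment
#'
#' Downloads (or replays) the three payloads of an accession — the normalized
#' matrix archive, the cluster table, the experiment design — and assembles
#' them: the matrix as an [scnv_experiment()], the clusters as a category read
#' in cluster orientation, the design transposed (cells arrive in rows) with
#' every design column becoming one category row.
#'
#' @param client an [atlas_client()]
#' @param accession experiment accession, e.g. `"E-GEOD-81383"`
#' @param species organism recorded on the experiment
#' @return an [scnv_experiment()] with categories `"Cluster"` and `"Design"`
#'   attached (design omitted when the atlas provides none)
#' @export
fetch_gxa_experiment <- function(client, accession, species = "unknown") {
  archive <- client_get(client, sprintf(GXA_MATRIX_URL, accession),
                        paste0("gxa_", accession, "_normalised"))
  clusters_file <- client_get(client, sprintf(GXA_CLUSTERS_URL, accession),
                              paste0("gxa_", accession, "_cluster"))
  exp <- read_mtx_triple(archive, species = species, accession = accession,
                         source = "GXA")
  clusters <- read_category_csv(clusters_file, transpose = FALSE, name = "Cluster")
  exp <- attach_category(exp, clusters)
  design <- tryCatch({
    design_file <- client_get(client, sprintf(GXA_DESIGN_URL, accession),
                              paste0("gxa_", accession, "_experiment-design"))
    read_category_csv(design_file, transpose = TRUE, name = "Design")
  }, scnv_unknown_accession_error = function(e) NULL,
     scnv_transport_error = function(e) NULL)
  if (!is.null(design)) exp <- attach_category(exp, design)
  exp
}

#' List Human Cell Atlas matrix experiments (DCP1)
#'
#' Queries the DCP1 projects index restricted to matrix files (see
#' [hca_filter_json()]). A project may ship one matrix per tissue or organ;
#' each matrix file becomes its own entry so downstream analysis treats them
#' as independent experiments.
#'
#' @param client an [atlas_client()]
#' @param catalog DCP catalog generation; only `"dcp1"` is supported
#' @return list of entries of class `scnv_atlas_entry`, each carrying the
#'   matrix `download_url`
#' @export
list_hca_entries <- function(client, catalog = "dcp1") {
  if (!identical(catalog, "dcp1")) {
    scnv_error("scnv_unsupported_error",
               sprintf("catalog '%s' is unsupported; only dcp1 is implemented", catalog))
  }
  url <- paste0(HCA_PROJECTS_URL, "?catalog=dcp1&filters=",
                utils::URLencode(hca_filter_json(), reserved = TRUE))
  path <- client_get(client, url, "hca_projects.json")
  payload <- parse_json_payload(path, url)
  hits <- payload$hits %||% list()
  entries <- list()
  for (h in hits) {
    title <- if (length(h$projects)) h$projects[[1L]]$projectTitle %||% "" else ""
    short <- if (length(h$projects)) h$projects[[1L]]$projectShortname %||% h$entryId else h$entryId
    species <- "unknown"
    if (length(h$donorOrganisms) && length(h$donorOrganisms[[1L]]$genusSpecies)) {
      species <- h$donorOrganisms[[1L]]$genusSpecies[[1L]]
    }
    n_cells <- 0L
    if (length(h$cellSuspensions)) {
      n_cells <- as.integer(h$cellSuspensions[[1L]]$totalCells %||% 0L)
    }
    for (m in h$matrices %||% list()) {
      entries[[length(entries) + 1L]] <- structure(list(
        accession = paste0(short %||% "project", "/", m$name),
        description = title, species = species, n_cells = n_cells,
        source = "HCA", download_url = m$url, raw = h),
        class = "scnv_atlas_entry")
    }
  }
  if (length(entries) == 0L) scnv_warn("no HCA matrix entries found")
  entries
}

#' Fetch one Human Cell Atlas matrix experiment
#'
#' Follows an entry's matrix `download_url`. The archive holds the matrix in
#' MatrixMarket format, the gene identifiers, and one combined file carrying
#' the cell barcodes plus categorical annotations; every annotation column of
#' that file becomes a category row (column names are release-dependent, so
#' parsing is header-driven).
#'
#' @param client an [atlas_client()]
#' @param entry an entry from [list_hca_entries()]
#' @return an [scnv_experiment()] with a `"Metadata"` category when the
#'   barcode file carries annotation columns
#' @export
fetch_hca_experiment <- function(client, entry) {
  stopifnot(inherits(entry, "scnv_atlas_entry"))
  key <- paste0("hca_", gsub("[^A-Za-z0-9._-]", "_", entry$accession))
  archive <- client_get(client, entry$download_url, key)
  dir <- extract_archive(archive)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  mtx <- files[grepl("\\.mtx(\\.gz)?$", files)]
  if (length(mtx) != 1L) {
    scnv_error("scnv_format_error", "HCA archive must hold exactly one .mtx file")
  }
  others <- setdiff(files, mtx)
  genes_file <- others[grepl("genes|rows", basename(others), ignore.case = TRUE)]
  barcode_file <- others[grepl("barcode|cells|cols|meta", basename(others),
                               ignore.case = TRUE)]
  if (length(genes_file) < 1L || length(barcode_file) < 1L) {
    scnv_error("scnv_format_error",
               "HCA archive must hold a gene list and a barcode/annotation file")
  }
  m <- Matrix::readMM(mtx)
  genes <- read_delim_matrix(genes_file[[1L]])
  bc <- read_delim_matrix(barcode_file[[1L]])
  header <- bc[1L, ]; body <- bc[-1L, , drop = FALSE]
  cell_ids <- body[, 1L]
  exp <- scnv_experiment(m, gene_ids = genes[, 1L], cell_ids = cell_ids,
                         species = entry$species, accession = entry$accession,
                         source = "HCA",
                         gene_symbols = if (ncol(genes) >= 2L) genes[, 2L])
  if (ncol(bc) >= 2L) {
    rows <- lapply(2:ncol(bc), function(j) {
      scnv_category_row(row_label = header[j],
                        assignments = setNames(body[, j], cell_ids))
    })
    exp <- attach_category(exp, suppressWarnings(scnv_category("Metadata", rows)))
  }
  exp
}
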