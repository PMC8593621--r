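#' @importFrom methods as is new
#' @importFrom stats median p.adjust pnorm prcomp rank rnbinom runif rbinom
#'   setNames var sd quantile
#' @importFrom utils read.table write.table untar unzip tar head modifyList
NULL

# Condition helpers: every user-facing error carries a subclass so callers
# (and the CLI) can branch on the failure kind rather than on message text.
scnv_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "scnv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

scnv_warn <- function(msg) warning(msg, call. = FALSE)

#' Detect the field delimiter of a delimited text file
#'
#' Looks at the first non-empty line and picks tab if it contains at least one
#' tab, otherwise comma. Cluster and metadata tables in the wild come as both
#' CSV and TSV under a ".csv"-ish name, so the delimiter is sniffed, never
#' assumed from the extension.
#'
#' @param path path to a delimited text file
#' @return a single character, `"\t"` or `","`
#' @keywords internal
sniff_delim <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  line <- ""
  while (!nzchar(line)) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) scnv_error("scnv_format_error", sprintf("empty file: %s", path))
  }
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

# Split delimited lines into a character matrix, erroring on ragged rows.
read_delim_matrix <- function(path) {
  delim <- sniff_delim(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) scnv_error("scnv_format_error", sprintf("empty file: %s", path))
  fields <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    scnv_error("scnv_format_error", sprintf(
      "ragged rows in %s: widths %s", path, paste(unique(widths), collapse = "/")))
  }
  m <- do.call(rbind, fields)
  # strip surrounding quotes if the writer quoted fields
  m[] <- gsub('^"|"$', "", m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
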