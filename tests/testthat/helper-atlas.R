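# Builders for synthetic recorded-response fixture stores emulating the
# atlas payload layouts. All payloads are generated in code at test time;
# nothing here is a real atlas response.

# A GXA-style store: experiments listing JSON plus, per accession, the
# normalised-matrix archive, the cluster table and the experiment design.
build_gxa_store <- function(dir, accessions = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  listing <- lapply(names(accessions), function(acc) {
    gen <- accessions[[acc]]
    list(experimentAccession = acc,
         experimentDescription = paste("synthetic fixture for", acc),
         species = gen$experiment$species,
         numberOfAssays = ncol(gen$experiment$matrix))
  })
  jsonlite::write_json(list(experiments = listing),
                       file.path(dir, "gxa_experiments.json"),
                       auto_unbox = TRUE)
  for (acc in names(accessions)) {
    gen <- accessions[[acc]]
    gen$experiment$accession <- acc
    stage <- tempfile("gxa_stage_"); dir.create(stage)
    tarball <- write_experiment(gen$experiment, stage, archive = "tar.gz")
    file.copy(tarball, file.path(dir, paste0("gxa_", acc, "_normalised.tar.gz")))
    write_category_csv(gen$category,
                       file.path(dir, paste0("gxa_", acc, "_cluster.tsv")),
                       cell_ids = gen$experiment$cell_ids)
    # a minimal experiment design: cells in rows, one annotation column
    n <- length(gen$experiment$cell_ids)
    writeLines(c("Assay\tindividual",
                 paste(gen$experiment$cell_ids,
                       rep(c("donor1", "donor2"), length.out = n), sep = "\t")),
               file.path(dir, paste0("gxa_", acc, "_experiment-design.tsv")))
    unlink(stage, recursive = TRUE)
  }
  dir
}

# An HCA-style store: DCP1 projects listing plus per-matrix archives holding
# the matrix, gene ids, and the combined barcode+annotation file.
build_hca_store <- function(dir, projects = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hits <- list()
  for (p in projects) {
    matrices <- list()
    for (m in p$matrices) {
      key <- paste0("hca_", gsub("[^A-Za-z0-9._-]", "_",
                                 paste0(p$shortname, "/", m$name)))
      if (!is.null(m$gen)) {
        gen <- m$gen
        stage <- tempfile("hca_stage_"); dir.create(stage)
        Matrix::writeMM(gen$experiment$matrix, file.path(stage, "matrix.mtx"))
        writeLines(gen$experiment$gene_ids, file.path(stage, "genes.tsv"))
        labels <- gen$category$rows[[1]]$assignments
        writeLines(c("barcode\tcluster\torgan",
                     paste(gen$experiment$cell_ids,
                           labels[gen$experiment$cell_ids],
                           m$organ %||% "tissue", sep = "\t")),
                   file.path(stage, "cells.tsv"))
        old <- setwd(stage)
        utils::tar("bundle.tar.gz",
                   files = c("matrix.mtx", "genes.tsv", "cells.tsv"),
                   compression = "gzip", tar = "internal")
        setwd(old)
        file.copy(file.path(stage, "bundle.tar.gz"),
                  file.path(dir, paste0(key, ".tar.gz")))
        unlink(stage, recursive = TRUE)
      }
      matrices[[length(matrices) + 1L]] <-
        list(name = m$name, url = paste0("https://example.org/", key),
             organ = m$organ %||% "tissue")
    }
    hits[[length(hits) + 1L]] <- list(
      entryId = p$shortname,
      projects = list(list(projectTitle = p$title,
                           projectShortname = p$shortname)),
      donorOrganisms = list(list(genusSpecies = list("Homo sapiens"))),
      cellSuspensions = list(list(totalCells = p$n_cells %||% 0L)),
      matrices = matrices)
  }
  jsonlite::write_json(list(hits = hits), file.path(dir, "hca_projects.json"),
                       auto_unbox = TRUE)
  dir
}
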