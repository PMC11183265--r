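#' Write a CountMatrix as matrix-market plus TSV sidecars
#'
#' Writes `matrix.mtx` (sparse triplet), `genes.tsv` (gene metadata) and
#' `cells.tsv` (cell metadata) into `dir`.
#'
#' @param x a `CountMatrix`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(x$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CountMatrix written by [write_count_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A `CountMatrix`.
#' @export
read_count_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"))
  count_matrix(counts, genes, cells)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "scAgeStates") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TF-target database from a 3-column TSV
#'
#' @param path TSV with columns tf, target, source.
#' @param universe gene universe (e.g. expression-matrix gene names).
#' @return A `TFTargetDatabase`.
#' @export
read_tf_database <- function(path, universe) {
  records <- utils::read.delim(path)
  stopifnot(all(c("tf", "target", "source") %in% names(records)))
  records <- unique(records[, c("tf", "target", "source")])
  structure(list(records = records, universe = universe),
            class = "TFTargetDatabase")
}

#' Write a TF-target database to TSV
#'
#' @param db a `TFTargetDatabase`.
#' @param path output path.
#' @export
write_tf_database <- function(db, path) {
  utils::write.table(db$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a limiting-dilution assay table from TSV
#'
#' @param path TSV with columns group, dose, tested, positive.
#' @return An `LDAssayTable` data.frame.
#' @export
read_ld_table <- function(path) {
  x <- utils::read.delim(path)
  stopifnot(all(c("group", "dose", "tested", "positive") %in% names(x)),
            all(x$positive <= x$tested), all(x$dose > 0))
  class(x) <- c("LDAssayTable", "data.frame")
  x
}
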