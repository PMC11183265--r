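#' Construct a CountMatrix
#'
#' The universal input container of the pipeline: a genes x cells matrix of
#' UMI counts together with gene-level and cell-level metadata. Counts are
#' stored sparse (`Matrix::dgCMatrix`).
#'
#' @param counts non-negative integer matrix or sparse Matrix, genes x cells.
#' @param gene_meta data.frame with one row per gene; must contain `name`
#'   plus logical flags `is_ercc`, `is_mito`, `is_stromal_marker`.
#' @param cell_meta data.frame with one row per cell; must contain `barcode`
#'   and typically `age_months`, `batch`, `genotype`, `treatment`,
#'   `total_reads`.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_meta, cell_meta) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (nrow(counts) != nrow(gene_meta))
    stop("gene_meta rows (", nrow(gene_meta), ") != matrix rows (",
         nrow(counts), ")")
  if (ncol(counts) != nrow(cell_meta))
    stop("cell_meta rows (", nrow(cell_meta), ") != matrix cols (",
         ncol(counts), ")")
  if (!all(c("name", "is_ercc", "is_mito", "is_stromal_marker") %in%
             names(gene_meta)))
    stop("gene_meta needs columns: name, is_ercc, is_mito, is_stromal_marker")
  if (!"barcode" %in% names(cell_meta))
    stop("cell_meta needs a 'barcode' column")
  if (anyDuplicated(gene_meta$name))
    stop("duplicate gene names in gene_meta")
  if (anyDuplicated(cell_meta$barcode))
    stop("duplicate barcodes in cell_meta")
  rownames(counts) <- gene_meta$name
  colnames(counts) <- cell_meta$barcode
  structure(list(counts = counts,
                 gene_meta = as.data.frame(gene_meta),
                 cell_meta = as.data.frame(cell_meta)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  ERCC genes:", sum(x$gene_meta$is_ercc),
      " mito genes:", sum(x$gene_meta$is_mito),
      " stromal markers:", sum(x$gene_meta$is_stromal_marker), "\n")
  if ("age_months" %in% names(x$cell_meta)) {
    tab <- table(x$cell_meta$age_months)
    cat("  cells per age (months):",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by gene and/or cell index
#'
#' @param x a `CountMatrix`.
#' @param genes,cells logical, integer or character index into genes / cells;
#'   missing means keep all.
#' @return A `CountMatrix` restricted to the selected rows/columns.
#' @export
subset_cm <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  count_matrix(x$counts[genes, cells, drop = FALSE],
               x$gene_meta[genes, , drop = FALSE],
               x$cell_meta[cells, , drop = FALSE])
}

#' Construct a NormalizedMatrix
#'
#' Dense genes x cells matrix of log-normalized (optionally
#' covariate-residualized) expression values, carrying the metadata of the
#' CountMatrix it was derived from.
#'
#' @param values numeric matrix, genes x cells.
#' @param gene_meta,cell_meta metadata data.frames (as in [count_matrix()]).
#' @param scale_factor the library-size scale factor used.
#' @param covariates_removed character vector of covariate names regressed
#'   out (empty if none).
#' @return An object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, gene_meta, cell_meta,
                              scale_factor = 1e4,
                              covariates_removed = character()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(gene_meta),
            ncol(values) == nrow(cell_meta))
  rownames(values) <- gene_meta$name
  colnames(values) <- cell_meta$barcode
  structure(list(values = values,
                 gene_meta = as.data.frame(gene_meta),
                 cell_meta = as.data.frame(cell_meta),
                 scale_factor = scale_factor,
                 covariates_removed = covariates_removed),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "cells (scale factor", x$scale_factor, ")\n")
  if (length(x$covariates_removed))
    cat("  covariates regressed out:",
        paste(x$covariates_removed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)
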