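#' QC thresholds for cell and gene filtering
#'
#' Defaults follow the four cell-level criteria used throughout the
#' pipeline: per-batch barcode whitelist by read-count rank, ERCC spike-in
#' fraction at most 10%, mitochondrial fraction at most 5%, detected genes
#' between 200 and 6000, all four stromal markers (Pecam1, Ptprc, Lyve1,
#' Col1a1) at most 0.1 on the log-normalized scale; genes must be detected
#' in at least 10 cells.
#'
#' @param max_ercc_fraction,max_mito_fraction upper bounds on the count
#'   fraction from spike-ins / mitochondrial genes.
#' @param min_genes,max_genes bounds on detected genes per cell.
#' @param stromal_expression_cutoff log-normalized expression above which a
#'   stromal marker flags a contaminant cell.
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param barcode_top_n barcodes retained per sequencing batch, ranked by
#'   total read counts.
#' @return A `QCThresholds` list.
#' @export
qc_thresholds <- function(max_ercc_fraction = 0.10,
                          max_mito_fraction = 0.05,
                          min_genes = 200, max_genes = 6000,
                          stromal_expression_cutoff = 0.1,
                          min_cells_per_gene = 10,
                          barcode_top_n = 100) {
  stopifnot(max_ercc_fraction >= 0, max_mito_fraction >= 0,
            min_genes >= 0, min_genes < max_genes,
            stromal_expression_cutoff >= 0, min_cells_per_gene >= 0,
            barcode_top_n >= 1)
  structure(list(max_ercc_fraction = max_ercc_fraction,
                 max_mito_fraction = max_mito_fraction,
                 min_genes = min_genes, max_genes = max_genes,
                 stromal_expression_cutoff = stromal_expression_cutoff,
                 min_cells_per_gene = min_cells_per_gene,
                 barcode_top_n = barcode_top_n),
            class = "QCThresholds")
}

#' Filter cells and genes by the four QC criteria
#'
#' Cells are retained only if they pass all of: (1) barcode among the top-N
#' by total reads within their sequencing batch; (2) ERCC fraction <=
#' `max_ercc_fraction` and mitochondrial fraction <= `max_mito_fraction`;
#' (3) detected genes within `[min_genes, max_genes]`; (4) every stromal
#' marker at most `stromal_expression_cutoff` on the log-normalized scale.
#' Genes detected in fewer than `min_cells_per_gene` of the surviving cells
#' are then dropped (spike-ins, mitochondrial genes and stromal markers used
#' by the filters are always kept). Per-rule exclusion counts are attached
#' as the `qc_log` attribute.
#'
#' @param x a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return The filtered `CountMatrix`, with attribute `qc_log` (a list of
#'   per-rule exclusion counts and survivor totals).
#' @export
filter_cells_and_genes <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "CountMatrix"))
  th <- thresholds
  counts <- x$counts
  n_cells <- ncol(counts)
  totals <- Matrix::colSums(counts)
  total_reads <- if ("total_reads" %in% names(x$cell_meta))
    x$cell_meta$total_reads else totals

  ## rule 1: per-batch barcode whitelist by read-count rank
  batch <- if ("batch" %in% names(x$cell_meta))
    as.character(x$cell_meta$batch) else rep("all", n_cells)
  pass_barcode <- logical(n_cells)
  for (b in unique(batch)) {
    i <- which(batch == b)
    keep <- i[order(total_reads[i], decreasing = TRUE)][
      seq_len(min(th$barcode_top_n, length(i)))]
    pass_barcode[keep] <- TRUE
  }

  ## rule 2: spike-in and mitochondrial fractions
  ercc_frac <- Matrix::colSums(counts[x$gene_meta$is_ercc, , drop = FALSE]) /
    pmax(totals, 1)
  mito_frac <- Matrix::colSums(counts[x$gene_meta$is_mito, , drop = FALSE]) /
    pmax(totals, 1)
  pass_frac <- ercc_frac <= th$max_ercc_fraction &
    mito_frac <= th$max_mito_fraction

  ## rule 3: detected gene number
  n_detected <- Matrix::colSums(counts > 0)
  pass_genes <- n_detected >= th$min_genes & n_detected <= th$max_genes

  ## rule 4: stromal marker expression on the log-normalized scale
  strom <- which(x$gene_meta$is_stromal_marker)
  if (length(strom)) {
    lognorm <- log1p(t(t(as.matrix(counts[strom, , drop = FALSE])) /
                         pmax(totals, 1)) * 1e4)
    pass_strom <- colSums(lognorm > th$stromal_expression_cutoff) == 0
  } else pass_strom <- rep(TRUE, n_cells)

  keep_cells <- pass_barcode & pass_frac & pass_genes & pass_strom
  if (!any(keep_cells)) {
    excl <- c(barcode = sum(!pass_barcode),
              ercc_mito_fraction = sum(!pass_frac),
              gene_number = sum(!pass_genes), stromal = sum(!pass_strom))
    stop("no cells pass QC; dominant filter: ",
         names(which.max(excl)), " (", max(excl), " of ", n_cells,
         " cells excluded)")
  }

  ## gene filter among surviving cells
  det <- Matrix::rowSums(counts[, keep_cells, drop = FALSE] > 0)
  keep_genes <- det >= th$min_cells_per_gene |
    x$gene_meta$is_ercc | x$gene_meta$is_mito | x$gene_meta$is_stromal_marker

  out <- subset_cm(x, genes = which(keep_genes), cells = which(keep_cells))
  attr(out, "qc_log") <- list(
    n_cells_in = n_cells,
    excluded = c(barcode = sum(!pass_barcode),
                 ercc_mito_fraction = sum(!pass_frac),
                 gene_number = sum(!pass_genes),
                 stromal = sum(!pass_strom)),
    n_cells_out = sum(keep_cells),
    n_genes_in = nrow(counts),
    n_genes_out = sum(keep_genes))
  out
}

#' Log-normalize UMI counts
#'
#' `value = ln(1 + count / cell_total * scale_factor)`, the standard
#' library-size log-normalization with natural log and scale factor 10,000.
#'
#' @param x a filtered `CountMatrix`.
#' @param scale_factor library-size scale factor.
#' @return A [normalized_matrix()].
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "CountMatrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(x$cell_meta$barcode[totals == 0], 5),
               collapse = ", "),
         " (should have been removed by QC)")
  values <- log1p(t(t(as.matrix(x$counts)) / totals) * scale_factor)
  normalized_matrix(values, x$gene_meta, x$cell_meta,
                    scale_factor = scale_factor)
}

#' Regress covariates out of a normalized matrix
#'
#' Replaces each gene's values with ordinary-least-squares residuals against
#' the covariate design (intercept included; character/factor covariates are
#' one-hot encoded). Rank-deficient designs have their collinear columns
#' dropped with a warning.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param covariates data.frame of per-cell covariates, rows aligned to
#'   cells (e.g. cell-cycle scores, ERCC fraction, mitochondrial fraction,
#'   batch, detected-gene number).
#' @return A `NormalizedMatrix` of per-gene residuals (each gene centered,
#'   orthogonal to every covariate), with `covariates_removed` recorded.
#' @export
regress_covariates <- function(normalized, covariates) {
  stopifnot(inherits(normalized, "NormalizedMatrix"),
            nrow(covariates) == ncol(normalized$values))
  covariates <- as.data.frame(covariates)
  design <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    drop <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    warning("rank-deficient covariate design; dropping: ",
            paste(drop, collapse = ", "))
    design <- design[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(design)
  }
  Y <- t(normalized$values)                      # cells x genes
  resid <- qr.resid(qrX, Y)
  normalized_matrix(t(resid), normalized$gene_meta, normalized$cell_meta,
                    scale_factor = normalized$scale_factor,
                    covariates_removed = names(covariates))
}
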