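match_set_genes <- function(set, gene_names) {
  hit <- match(toupper(set), toupper(gene_names))
  list(matched = gene_names[hit[!is.na(hit)]],
       unmatched = set[is.na(hit)])
}

#' Per-cell gene-set module score with expression-matched controls
#'
#' Genes are binned by their mean expression into `n_bins` equal-frequency
#' bins; for every set gene, `n_controls` control genes are drawn (without
#' replacement) from its bin; the score is the mean expression of the set
#' genes minus the mean expression of the pooled control genes, per cell.
#' Set genes are matched to matrix genes case-insensitively.
#'
#' @param normalized a `NormalizedMatrix` (or plain genes x cells matrix).
#' @param gene_set character vector of gene names.
#' @param n_bins number of expression bins.
#' @param n_controls control genes drawn per set gene.
#' @param seed integer seed controlling the control draw.
#' @return A `ModuleScoreResult`: per-cell `score`, the matched and control
#'   genes, and the parameters used.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24,
                         n_controls = 100, seed = 1L) {
  values <- if (inherits(normalized, "NormalizedMatrix"))
    normalized$values else as.matrix(normalized)
  m <- match_set_genes(gene_set, rownames(values))
  if (!length(m$matched))
    stop("no set genes matched the matrix; unmatched: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  set.seed(as.integer(seed))
  avg <- rowMeans(values)
  bin <- as.integer(cut(rank(avg, ties.method = "first"),
                        breaks = min(n_bins, nrow(values)), labels = FALSE))
  names(bin) <- rownames(values)
  ctrl <- character()
  for (g in m$matched) {
    pool <- names(bin)[bin == bin[g]]
    ctrl <- c(ctrl, sample(pool, min(n_controls, length(pool))))
  }
  ctrl <- unique(ctrl)
  score <- colMeans(values[m$matched, , drop = FALSE]) -
    colMeans(values[ctrl, , drop = FALSE])
  structure(list(score = score, set_genes = m$matched,
                 unmatched = m$unmatched, control_genes = ctrl,
                 n_bins = n_bins, n_controls = n_controls,
                 seed = as.integer(seed)),
            class = "ModuleScoreResult")
}

#' Convert a CountMatrix to log2(TPM + 1)
#'
#' For UMI data all genes share the same effective length, so TPM reduces to
#' counts scaled to one million per cell.
#'
#' @param x a `CountMatrix`.
#' @return dense genes x cells matrix of `log2(TPM + 1)`.
#' @export
counts_to_log2_tpm <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) stop("cell(s) with zero total counts")
  log2(t(t(as.matrix(x$counts)) / totals) * 1e6 + 1)
}

#' Call cell-cycle phase per cell, including a G0 rule
#'
#' For each phase, genes are filtered by Pearson correlation (threshold
#' `rho`) with the phase's average expression profile, with two refinement
#' rounds (average over current genes, filter, recompute). Phase scores are
#' the mean of the retained genes, z-scored across cells. Cells with both
#' z(G1/S) < 0 and z(G2/M) < 0 are called G0; all other cells get the
#' argmax phase.
#'
#' @param tpm_log genes x cells matrix of `log2(TPM + 1)` (see
#'   [counts_to_log2_tpm()]).
#' @param phase_genes data.frame with columns `gene`, `phase`; phases must
#'   cover G1/S, S, G2, G2/M, M/G1.
#' @param rho correlation threshold for retaining a phase gene.
#' @param n_refine refinement rounds of the average-profile filter.
#' @return A `CellCyclePhaseCall`: per-cell `phase`, the cells x phases
#'   z-score matrix, retained gene lists, and `rho`.
#' @export
call_cell_cycle <- function(tpm_log, phase_genes, rho = 0.25,
                            n_refine = 2) {
  req <- c("G1/S", "S", "G2", "G2/M", "M/G1")
  if (!all(req %in% phase_genes$phase))
    stop("phase_genes must cover all of: ", paste(req, collapse = ", "))
  tpm_log <- as.matrix(tpm_log)
  retained <- list()
  for (ph in req) {
    genes <- intersect(phase_genes$gene[phase_genes$phase == ph],
                       rownames(tpm_log))
    cur <- genes
    for (i in seq_len(n_refine)) {
      if (length(cur) < 2) break
      avg <- colMeans(tpm_log[cur, , drop = FALSE])
      r <- apply(tpm_log[cur, , drop = FALSE], 1,
                 function(y) suppressWarnings(stats::cor(y, avg)))
      r[is.na(r)] <- 0
      cur <- cur[r >= rho]
    }
    retained[[ph]] <- cur
  }
  n_surv <- vapply(retained, length, integer(1))
  if (any(n_surv == 0))
    stop("phase(s) retained zero genes after filtering: ",
         paste(sprintf("%s=%d", names(n_surv), n_surv), collapse = ", "))
  z <- vapply(req, function(ph) {
    s <- colMeans(tpm_log[retained[[ph]], , drop = FALSE])
    as.numeric(scale(s))
  }, numeric(ncol(tpm_log)))
  rownames(z) <- colnames(tpm_log)
  phase <- req[max.col(z, ties.method = "first")]
  phase[z[, "G1/S"] < 0 & z[, "G2/M"] < 0] <- "G0"
  names(phase) <- colnames(tpm_log)
  structure(list(phase = phase, z = z, retained = retained,
                 correlation_threshold = rho),
            class = "CellCyclePhaseCall")
}

#' Classify a pathway's state-activity profile into one of six patterns
#'
#' Operates on the four state-mean activities after range normalization to
#' `[0, 1]`. The patterns: 1 gradual decline across the time course; 2 peak
#' in state 2; 3 peak in state 3 with a sharp drop in state 4; 4 rise into
#' state 3 with a plateau persisting into state 4; 5 continuous increase
#' through states 3 and 4; 6 late activation confined to state 4.
#' Precedence 6, 4, 5, 3, 2, 1; anything else is "unclassified". Flat
#' profiles (range below `flat_tol`) are unclassified.
#'
#' @param a numeric length-4 vector of state-mean activities.
#' @param epsilon tolerance on the normalized scale.
#' @param flat_tol minimum raw range for a profile to be classifiable.
#' @return integer pattern 1..6, or `NA` for unclassified.
#' @export
classify_pattern <- function(a, epsilon = 0.1, flat_tol = 1e-8) {
  stopifnot(length(a) == 4)
  rng <- max(a) - min(a)
  if (!is.finite(rng) || rng < flat_tol) return(NA_integer_)
  x <- (a - min(a)) / rng
  e <- epsilon
  if (which.max(x) == 4 && all(x[1:3] <= e)) return(6L)
  if (x[3] >= max(x[1], x[2]) + 3 * e && x[4] >= max(x[1], x[2]) + 3 * e &&
      abs(x[3] - x[4]) <= e) return(4L)
  if (x[4] > x[3] && x[3] > x[2] && x[4] - x[2] >= 3 * e) return(5L)
  if (which.max(x) == 3 && x[4] <= x[3] - 3 * e) return(3L)
  if (which.max(x) == 2) return(2L)
  if (which.max(x) == 1 && x[4] <= x[1] - 3 * e &&
      x[1] >= x[2] - e && x[2] >= x[3] - e && x[3] >= x[4] - e) return(1L)
  NA_integer_
}

#' Pathway activity dynamics over pseudotime, with pattern classification
#'
#' For each gene set: module score per cell, spline-smoothed over
#' pseudotime, averaged within each state interval, range-normalized and
#' classified into one of the six dynamic patterns.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param t a `Pseudotime` or numeric vector.
#' @param states a `StateMap`.
#' @param sets named list of gene sets (a `GeneSetCollection`).
#' @param epsilon pattern-rule tolerance.
#' @param grid_size smoothing grid size.
#' @param n_bins,n_controls,seed passed to [module_score()].
#' @return data.frame: pathway, state means a1..a4, pattern; the smoothed
#'   curves are attached as attribute `curves` (sets x grid).
#' @export
pathway_dynamics <- function(normalized, t, states, sets, epsilon = 0.1,
                             grid_size = 100, n_bins = 24,
                             n_controls = 100, seed = 1L) {
  tv <- if (inherits(t, "Pseudotime")) t$t else t
  stopifnot(inherits(states, "StateMap"))
  grid <- seq(min(tv), max(tv), length.out = grid_size)
  state_of_grid <- findInterval(grid, states$boundaries) + 1L
  basis <- splines::ns(tv, df = 3)
  X <- cbind(1, basis)
  Xg <- cbind(1, stats::predict(basis, grid))
  curves <- matrix(NA_real_, length(sets), grid_size,
                   dimnames = list(names(sets), NULL))
  res <- lapply(names(sets), function(nm) {
    sc <- module_score(normalized, sets[[nm]], n_bins = n_bins,
                       n_controls = n_controls, seed = seed)$score
    beta <- qr.coef(qr(X), sc)
    beta[is.na(beta)] <- 0
    fit <- as.numeric(Xg %*% beta)
    curves[nm, ] <<- fit
    a <- vapply(1:4, function(s) mean(fit[state_of_grid == s]), numeric(1))
    data.frame(pathway = nm, a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4],
               pattern = classify_pattern(a, epsilon))
  })
  out <- do.call(rbind, res)
  attr(out, "curves") <- curves
  attr(out, "grid") <- grid
  out
}

#' Paired two-group pathway comparison
#'
#' Per-sample pathway score = mean expression of the set genes; the two
#' groups are compared with a two-sided paired t-test on the pair
#' differences. Zero-variance non-zero differences are flagged and reported
#' with p below machine epsilon instead of an undefined t.
#'
#' @param expr_a,expr_b genes x samples matrices; column j of `expr_a` is
#'   paired with column j of `expr_b` (e.g. tumor vs matched normal).
#' @param set gene list.
#' @return list: per-sample `score_a`, `score_b`, `t`, `p`,
#'   `zero_variance` flag.
#' @export
paired_pathway_compare <- function(expr_a, expr_b, set) {
  stopifnot(ncol(expr_a) == ncol(expr_b))
  if (ncol(expr_a) < 2) stop("need at least 2 matched pairs")
  ga <- match_set_genes(set, rownames(expr_a))$matched
  gb <- match_set_genes(set, rownames(expr_b))$matched
  if (!length(ga) || !length(gb)) stop("set matched no genes")
  score_a <- colMeans(expr_a[ga, , drop = FALSE])
  score_b <- colMeans(expr_b[gb, , drop = FALSE])
  d <- score_a - score_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(score_a = score_a, score_b = score_b, t = 0, p = 1,
                  zero_variance = FALSE))
    return(list(score_a = score_a, score_b = score_b,
                t = sign(mean(d)) * Inf, p = .Machine$double.eps,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(score_a, score_b, paired = TRUE)
  list(score_a = score_a, score_b = score_b,
       t = unname(tt$statistic), p = tt$p.value, zero_variance = FALSE)
}
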