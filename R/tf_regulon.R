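#' Consensus hypergeometric TF enrichment on a gene cluster
#'
#' For every (TF, source) pair, tests the overlap between the TF's targets
#' and the cluster genes with an upper-tail hypergeometric test. By default
#' the universe is the gene list carried by the database (normally the
#' expression-matrix genes); with `universe_mode = "per_source"` it is
#' further intersected with the genes appearing as targets in that source,
#' so sources with sparse coverage are not penalized. BH adjustment is
#' applied within source across TFs; a TF is flagged reliable for the
#' cluster when supported (q < `q_cutoff`) by at least `min_sources`
#' sources.
#'
#' @param cluster_genes gene list defining the cluster.
#' @param db a `TFTargetDatabase` (list with `records` data.frame
#'   tf/target/source, and `universe` = expression-matrix genes).
#' @param q_cutoff per-source BH q cutoff counting as support.
#' @param min_sources sources required for the reliable flag.
#' @param universe_mode "given" (use `db$universe` as is) or "per_source"
#'   (intersect it with each source's target table).
#' @return data.frame: tf, source, universe size N, K (targets in
#'   universe), n (cluster size in universe), k (overlap), p, q,
#'   n_supporting_sources, reliable.
#' @export
enrich_tfs <- function(cluster_genes, db, q_cutoff = 0.05,
                       min_sources = 2,
                       universe_mode = c("given", "per_source")) {
  stopifnot(inherits(db, "TFTargetDatabase") ||
              all(c("records", "universe") %in% names(db)))
  universe_mode <- match.arg(universe_mode)
  recs <- db$records
  out <- list()
  for (s in unique(recs$source)) {
    rs <- recs[recs$source == s, ]
    uni <- if (universe_mode == "per_source")
      intersect(db$universe, unique(rs$target)) else db$universe
    N <- length(uni)
    clu <- intersect(cluster_genes, uni)
    n <- length(clu)
    rows <- lapply(unique(rs$tf), function(tf) {
      tgt <- intersect(rs$target[rs$tf == tf], uni)
      K <- length(tgt)
      if (K == 0) return(NULL)       # TF with no targets in universe
      k <- length(intersect(tgt, clu))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      data.frame(tf = tf, source = s, N = N, K = K, n = n, k = k, p = p)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) next
    rows$q <- stats::p.adjust(rows$p, method = "BH")
    out[[s]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  support <- tapply(res$q < q_cutoff, res$tf, sum)
  res$n_supporting_sources <- as.integer(support[res$tf])
  res$reliable <- res$n_supporting_sources >= min_sources
  res
}

#' TF activity profile over pseudotime
#'
#' Module score of the union of the TF's targets across all database
#' sources, spline-smoothed over pseudotime.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param t a `Pseudotime` or numeric vector.
#' @param tf TF name (must appear in at least one source).
#' @param db a `TFTargetDatabase`.
#' @param seed passed to [module_score()].
#' @param grid_size smoothing grid size.
#' @return list: per-cell `activity`, `grid`, smoothed `curve`, `targets`.
#' @export
tf_activity_profile <- function(normalized, t, tf, db, seed = 1L,
                                grid_size = 100) {
  tv <- if (inherits(t, "Pseudotime")) t$t else t
  targets <- unique(db$records$target[db$records$tf == tf])
  if (!length(targets)) stop("TF ", tf, " has no targets in any source")
  ms <- module_score(normalized, targets, seed = seed)
  basis <- splines::ns(tv, df = 3)
  beta <- qr.coef(qr(cbind(1, basis)), ms$score)
  beta[is.na(beta)] <- 0
  grid <- seq(min(tv), max(tv), length.out = grid_size)
  curve <- as.numeric(cbind(1, stats::predict(basis, grid)) %*% beta)
  list(activity = ms$score, grid = grid, curve = curve, targets = targets,
       module_score = ms)
}

#' Split a TF's binding targets by regulation direction from WT vs KO cells
#'
#' Per-gene two-sided Wilcoxon rank-sum test of WT against KO expression;
#' genes with p < `p_cutoff` are split by direction (KO < WT: positively
#' regulated; KO > WT: negatively regulated, i.e. repressed by the TF) and
#' intersected with the binding target list. Per-gene weights are the
#' absolute standardized rank-sum statistics.
#'
#' @param wt_values,ko_values genes x cells matrices (same genes).
#' @param binding_targets gene list from binding data (e.g. ChIP targets).
#' @param p_cutoff rank-sum p cutoff.
#' @return A `RegulonDirection`: `positively_regulated`,
#'   `negatively_regulated` (disjoint), and per-gene `weight`.
#' @export
derive_regulon_direction <- function(wt_values, ko_values, binding_targets,
                                     p_cutoff = 0.05) {
  stopifnot(nrow(wt_values) == nrow(ko_values))
  if (ncol(wt_values) < 20 || ncol(ko_values) < 20)
    stop("need at least 20 cells per group")
  genes <- intersect(rownames(wt_values), binding_targets)
  if (!length(genes)) stop("no binding targets present in the matrices")
  n1 <- ncol(wt_values); n2 <- ncol(ko_values)
  stat <- p <- delta <- numeric(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    wt <- wt_values[g, ]; ko <- ko_values[g, ]
    w <- suppressWarnings(stats::wilcox.test(wt, ko, exact = FALSE))
    p[i] <- w$p.value
    # standardized rank-sum statistic (normal approximation, tie-corrected)
    r <- rank(c(wt, ko))
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    stat[i] <- (w$statistic - n1 * n2 / 2) / sqrt(max(sigma2, 1e-12))
    delta[i] <- mean(ko) - mean(wt)
  }
  p[is.na(p)] <- 1
  sig <- p < p_cutoff
  pos <- genes[sig & delta < 0]
  neg <- genes[sig & delta > 0]
  if (!length(pos) && !length(neg))
    stop("no differential binding targets in either direction")
  w <- abs(stat); names(w) <- genes
  structure(list(positively_regulated = pos, negatively_regulated = neg,
                 weight = w, p = stats::setNames(p, genes)),
            class = "RegulonDirection")
}

#' Repressor activity score from negatively regulated targets
#'
#' Activity of a repressive TF read out from its repressed (negatively
#' regulated) targets: the weighted average expression of those targets,
#' sign-flipped so that strong repression (low target expression) gives a
#' high activity score.
#'
#' @param normalized a `NormalizedMatrix` (or genes x cells matrix).
#' @param direction a `RegulonDirection` with non-empty
#'   `negatively_regulated`.
#' @param weights "stat" (absolute standardized rank-sum statistic from the
#'   WT-vs-KO test) or "uniform".
#' @return named per-cell numeric activity score.
#' @export
regulon_activity <- function(normalized, direction,
                             weights = c("stat", "uniform")) {
  weights <- match.arg(weights)
  values <- if (inherits(normalized, "NormalizedMatrix"))
    normalized$values else as.matrix(normalized)
  neg <- intersect(direction$negatively_regulated, rownames(values))
  if (!length(neg)) stop("no negatively regulated genes in the matrix")
  w <- if (weights == "stat") direction$weight[neg]
       else stats::setNames(rep(1, length(neg)), neg)
  if (all(w == 0)) stop("all weights are zero")
  out <- -as.numeric(w %*% values[neg, , drop = FALSE]) / sum(w)
  stats::setNames(out, colnames(values))
}
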