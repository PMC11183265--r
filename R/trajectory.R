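#' Infer a one-dimensional aging pseudotime
#'
#' Orders cells along a single latent axis: PCA (top 10 components) on the
#' normalized matrix, a Gaussian-kernel diffusion coordinate on the PCA
#' embedding, then refinement by projection onto a principal curve fitted
#' through the embedding. The orientation is chosen so cells of the rooting
#' age group sit earlier (lower mean t) than the oldest group, and t is
#' rescaled to `[0, 1]`.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param root_age_months age group used to root the trajectory (its most
#'   abundant end becomes t = 0); must be present in `cell_meta$age_months`.
#' @param n_pcs number of principal components.
#' @param n_neighbors neighborhood size for the kernel bandwidth and the
#'   connectivity check.
#' @param n_var_genes number of highly variable genes kept for the
#'   embedding (all genes if the matrix is smaller).
#' @return A `Pseudotime` object: per-cell `t` in `[0,1]` plus the
#'   orientation anchor.
#' @export
infer_pseudotime <- function(normalized, root_age_months,
                             n_pcs = 10, n_neighbors = 15,
                             n_var_genes = 500) {
  stopifnot(inherits(normalized, "NormalizedMatrix"))
  n <- ncol(normalized$values)
  if (n < 50) stop("need at least 50 cells to infer a trajectory")
  ages <- normalized$cell_meta$age_months
  if (!root_age_months %in% ages)
    stop("root age ", root_age_months, " not present in cell metadata")

  vars <- apply(normalized$values, 1, stats::var)
  hvg <- order(vars, decreasing = TRUE)[
    seq_len(min(n_var_genes, nrow(normalized$values)))]
  pcs <- stats::prcomp(t(normalized$values[hvg, , drop = FALSE]),
                       center = TRUE, rank. = min(n_pcs, n - 1))$x

  ## diffusion coordinate on the PCA embedding
  d2 <- as.matrix(stats::dist(pcs))^2
  knn_d <- apply(d2, 1, function(r) sort(r)[n_neighbors + 1])
  # connectivity check on the kNN graph
  adj <- d2 <= outer(knn_d, rep(1, n))
  adj <- adj | t(adj); diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("disconnected embedding: ", comp$no, " components (sizes ",
         paste(utils::head(sort(comp$csize, decreasing = TRUE), 3),
               collapse = ", "),
         "); no usable 1-D ordering")
  sigma2 <- stats::median(knn_d)
  K <- exp(-d2 / (2 * sigma2))
  q <- rowSums(K)
  K1 <- K / outer(q, q)                 # density normalization
  Dv <- rowSums(K1)
  Ms <- K1 / outer(sqrt(Dv), sqrt(Dv))  # symmetrized transition operator
  ev <- eigen(Ms, symmetric = TRUE)
  # several structured axes can compete (cell cycle, contamination); take
  # the diffusion component along which the chronological age groups
  # separate most -- this is the aging axis the trajectory orders
  cand <- seq(2, min(6, ncol(ev$vectors)))
  r2 <- vapply(cand, function(j) {
    dc <- ev$vectors[, j] / sqrt(Dv)
    summary(stats::lm(dc ~ factor(ages)))$r.squared
  }, numeric(1))
  dc1 <- ev$vectors[, cand[which.max(r2)]] / sqrt(Dv)

  lambda <- principal_curve_lambda(pcs, order(dc1))

  old_age <- max(ages)
  if (mean(lambda[ages == root_age_months]) > mean(lambda[ages == old_age]))
    lambda <- -lambda
  # report t as the normalized rank along the curve: the latent scale of a
  # 1-D ordering is only identified up to a monotone map, so the quantile
  # convention makes pseudotime comparable across runs and datasets
  r <- rank(lambda, ties.method = "average")
  t <- (r - min(r)) / (max(r) - min(r))
  names(t) <- normalized$cell_meta$barcode
  structure(list(t = t, orientation_anchor = root_age_months),
            class = "Pseudotime")
}

# Principal-curve arc-length coordinate: starting from an initial ordering,
# iteratively smooth each embedding dimension against the current coordinate
# and re-project every cell onto the arc-length of the fitted curve.
principal_curve_lambda <- function(pcs, init_order, n_iter = 3,
                                   grid_size = 200) {
  n <- nrow(pcs)
  lambda <- numeric(n)
  lambda[init_order] <- seq_len(n)
  for (iter in seq_len(n_iter)) {
    lg <- seq(min(lambda), max(lambda), length.out = grid_size)
    curve <- vapply(seq_len(ncol(pcs)), function(j) {
      fit <- stats::smooth.spline(lambda, pcs[, j], df = 6)
      stats::predict(fit, lg)$y
    }, numeric(grid_size))
    seg <- sqrt(rowSums(diff(curve)^2))
    arc <- c(0, cumsum(seg))
    # nearest curve point per cell
    cross <- pcs %*% t(curve)
    d2 <- outer(rowSums(pcs^2), rowSums(curve^2), "+") - 2 * cross
    lambda <- arc[max.col(-d2, ties.method = "first")]
  }
  lambda
}

#' @export
print.Pseudotime <- function(x, ...) {
  cat("Pseudotime over", length(x$t), "cells; rooted at",
      x$orientation_anchor, "months\n")
  invisible(x)
}

#' Test genes for pseudotime dependence
#'
#' Per-gene likelihood-ratio test (Gaussian likelihood on normalized values)
#' of a natural cubic spline in t (3 df) against the intercept-only model,
#' with Benjamini-Hochberg correction. Zero-variance genes get p = 1.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param t a `Pseudotime` (or numeric vector aligned to cells).
#' @param q_cutoff BH q-value cutoff for the `selected` flag.
#' @return data.frame: gene, p, q, selected, ordered as in the matrix.
#' @export
test_pseudotime_genes <- function(normalized, t, q_cutoff = 0.05) {
  tv <- if (inherits(t, "Pseudotime")) t$t else t
  Y <- t(normalized$values)                       # cells x genes
  n <- nrow(Y)
  X <- stats::model.matrix(~ splines::ns(tv, df = 3))
  qrX <- qr(X)
  rss1 <- colSums(qr.resid(qrX, Y)^2)
  rss0 <- colSums(scale(Y, scale = FALSE)^2)
  lrt <- n * log(pmax(rss0, .Machine$double.xmin) /
                   pmax(rss1, .Machine$double.xmin))
  p <- stats::pchisq(lrt, df = 3, lower.tail = FALSE)
  p[rss0 < 1e-12] <- 1                            # constant genes
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = normalized$gene_meta$name, p = p, q = q,
             selected = q < q_cutoff)
}

#' Smooth, log-transform, standardize and truncate gene curves
#'
#' Fits each gene's expression as a spline in pseudotime, evaluates the fit
#' on an equally spaced grid, clamps negative fits to 0, applies
#' `log10(x + 1)`, standardizes each gene across the grid, and truncates all
#' values to `[-3, 3]`.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param t a `Pseudotime` or numeric vector.
#' @param genes character vector of gene names to smooth.
#' @param grid_size number of grid points over `[min(t), max(t)]`.
#' @param df spline degrees of freedom; 6 by default, flexible enough to
#'   track sigmoidal and peaked programs without biasing their crossing
#'   points (a stiffer fit shifts the state borders).
#' @return A `SmoothedCurves` object: `grid` (pseudotime points) and
#'   `values` (genes x grid, all entries in `[-3, 3]`).
#' @export
smooth_scale_truncate <- function(normalized, t, genes, grid_size = 100,
                                  df = 6) {
  tv <- if (inherits(t, "Pseudotime")) t$t else t
  miss <- setdiff(genes, normalized$gene_meta$name)
  if (length(miss)) stop("genes not in matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  Y <- t(normalized$values[genes, , drop = FALSE])  # cells x genes
  basis <- splines::ns(tv, df = df)
  X <- cbind(1, basis)
  beta <- qr.coef(qr(X), Y)
  beta[is.na(beta)] <- 0
  grid <- seq(min(tv), max(tv), length.out = grid_size)
  Xg <- cbind(1, stats::predict(basis, grid))
  fit <- Xg %*% beta                                # grid x genes
  fit[fit < 0] <- 0
  lg <- log10(fit + 1)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  z <- sweep(sweep(lg, 2, mu), 2, ifelse(sd > 1e-8, sd, 1), "/")
  z[, sd <= 1e-8] <- 0                     # flat genes carry no shape
  z[z > 3] <- 3; z[z < -3] <- -3
  structure(list(grid = grid, values = t(z),
                 truncation_bound = 3, pseudocount = 1, log_base = 10),
            class = "SmoothedCurves")
}

#' Cluster gene curves by hierarchical clustering
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of smoothed
#' gene curves, tree cut at `k`.
#'
#' @param curves a `SmoothedCurves`.
#' @param k number of clusters.
#' @return A `GeneClusterMap`: named integer vector `cluster`, plus `k` and
#'   the linkage used.
#' @export
cluster_genes <- function(curves, k = 4) {
  stopifnot(inherits(curves, "SmoothedCurves"))
  n_genes <- nrow(curves$values)
  if (k > n_genes) stop("k = ", k, " exceeds number of genes (", n_genes, ")")
  hc <- stats::hclust(stats::dist(curves$values), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, k = k, linkage = "ward.D2", hclust = hc),
            class = "GeneClusterMap")
}

#' Segment cells into four states at cluster-curve intersections
#'
#' Averages the smoothed curves within each gene cluster, labels every grid
#' point by the dominant (argmax) cluster, smooths the label sequence with a
#' majority filter, and places the three state boundaries at the label
#' transitions. Clusters are renumbered so their order of dominance along
#' pseudotime is 1 (a-Young) to 4 (l-Sen), and every cell is assigned the
#' state of its pseudotime interval.
#'
#' @param curves a `SmoothedCurves`.
#' @param clusters a `GeneClusterMap` with exactly 4 clusters.
#' @param t a `Pseudotime` or numeric vector.
#' @param majority_window odd window width for the label majority filter.
#' @return A `StateMap`: `boundaries` (3 pseudotime values), per-cell
#'   `state` in 1..4, `state_counts`, state `labels`, and the cluster ->
#'   state renumbering.
#' @export
assign_states <- function(curves, clusters, t, majority_window = 5) {
  stopifnot(inherits(curves, "SmoothedCurves"),
            inherits(clusters, "GeneClusterMap"))
  if (clusters$k != 4) stop("state assignment requires exactly 4 clusters")
  tv <- if (inherits(t, "Pseudotime")) t$t else t
  cl <- clusters$cluster[rownames(curves$values)]
  avg <- vapply(1:4, function(j)
    colMeans(curves$values[cl == j, , drop = FALSE]),
    numeric(length(curves$grid)))
  lab <- max.col(avg, ties.method = "first")

  runs <- NULL
  for (w in seq(majority_window, 21, by = 2)) {
    sm <- majority_filter(lab, w)
    sm <- merge_short_runs(sm, min_len = max(3, w %/% 2))
    r <- rle(sm)
    if (length(r$lengths) == 4 && !anyDuplicated(r$values)) {
      runs <- r; break
    }
  }
  if (is.null(runs)) {
    r <- rle(merge_short_runs(majority_filter(lab, majority_window), 3))
    if (length(unique(r$values)) < 4)
      stop("only ", length(unique(r$values)),
           " clusters ever dominate the trajectory; re-cluster the genes")
    stop("cluster dominance alternates along pseudotime (",
         length(r$lengths), " runs); re-cluster the genes")
  }

  cut_idx <- cumsum(runs$lengths)[1:3]
  boundaries <- (curves$grid[cut_idx] + curves$grid[cut_idx + 1]) / 2
  state <- findInterval(tv, boundaries) + 1L
  names(state) <- names(tv)
  labels <- c("a-Young", "q-Young", "e-Sen", "l-Sen")
  structure(list(boundaries = boundaries, state = state,
                 state_counts = tabulate(state, 4),
                 labels = labels,
                 cluster_to_state = stats::setNames(1:4, runs$values)),
            class = "StateMap")
}

majority_filter <- function(lab, w) {
  n <- length(lab)
  h <- w %/% 2
  out <- lab
  for (i in seq_len(n)) {
    win <- lab[max(1, i - h):min(n, i + h)]
    tab <- table(win)
    out[i] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}

# merge label runs shorter than min_len into their larger neighbor
merge_short_runs <- function(lab, min_len) {
  repeat {
    r <- rle(lab)
    short <- which(r$lengths < min_len)
    if (!length(short) || length(r$lengths) == 1) return(lab)
    i <- short[which.min(r$lengths[short])]
    left_len <- if (i > 1) r$lengths[i - 1] else -1
    right_len <- if (i < length(r$lengths)) r$lengths[i + 1] else -1
    r$values[i] <- if (left_len >= right_len) r$values[i - 1]
                   else r$values[i + 1]
    lab <- inverse.rle(r)
  }
}

#' @export
print.StateMap <- function(x, ...) {
  cat("StateMap: boundaries at",
      paste(signif(x$boundaries, 3), collapse = ", "), "\n")
  cat("  ", paste(sprintf("%s: %d", x$labels, x$state_counts),
                  collapse = "  "), "\n")
  invisible(x)
}
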