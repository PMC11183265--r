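#' Build a gene co-expression network
#'
#' Connects gene pairs whose Pearson correlation across cells is at least
#' `r_min`, then restricts to the largest connected component. The network
#' is unweighted, symmetric, with no self-loops.
#'
#' @param normalized a `NormalizedMatrix` (or genes x cells matrix).
#' @param r_min correlation threshold for an edge.
#' @param min_sd genes with expression standard deviation below this are
#'   excluded before correlation.
#' @return A `CoexpressionNetwork`: 0/1 adjacency `A` (genes x genes),
#'   `genes` (largest-component gene names), `r_min`, and the spectral
#'   radius `lambda_max` of `A`.
#' @export
build_network <- function(normalized, r_min = 0.3, min_sd = 1e-8) {
  values <- if (inherits(normalized, "NormalizedMatrix"))
    normalized$values else as.matrix(normalized)
  if (ncol(values) < 50) stop("need at least 50 cells to build a network")
  keep <- apply(values, 1, stats::sd) > min_sd
  values <- values[keep, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(values)))
  r[is.na(r)] <- 0
  A <- (r >= r_min) * 1
  diag(A) <- 0
  deg <- rowSums(A)
  A <- A[deg > 0, deg > 0, drop = FALSE]
  if (nrow(A) == 0)
    stop("no edges at r_min = ", r_min, "; lower the threshold")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  A <- A[main, main, drop = FALSE]
  if (nrow(A) < 2)
    stop("largest connected component has fewer than 2 genes; ",
         "lower the threshold")
  lambda_max <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(A = A, genes = rownames(A), r_min = r_min,
                 lambda_max = lambda_max),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork:", length(x$genes), "genes,",
      sum(x$A) / 2, "edges (r >=", x$r_min, "), lambda_max =",
      signif(x$lambda_max, 5), "\n")
  invisible(x)
}

#' Signaling entropy rate of one cell on a co-expression network
#'
#' Defines an expression-weighted random walk on the network: transition
#' probabilities `P_ij = A_ij x_j / sum_k A_ik x_k`, stationary distribution
#' `pi_i` proportional to `x_i (Ax)_i` (exact for this reversible chain),
#' local entropies `S_i = -sum_j P_ij ln P_ij`, and entropy rate
#' `SR = sum_i pi_i S_i`, normalized by `ln(lambda_max(A))` so the maximum
#' attainable value is 1. Exact zeros in `x` are replaced by a small epsilon
#' (the walk is undefined at zeros).
#'
#' @param x non-negative expression vector named by (or aligned to) the
#'   network genes.
#' @param net a `CoexpressionNetwork`.
#' @return list: `SR`, `normalized` (SR / ln lambda_max), and the
#'   stationary distribution `pi`.
#' @export
signaling_entropy <- function(x, net) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  if (!is.null(names(x))) x <- x[net$genes]
  if (length(x) != length(net$genes))
    stop("x must cover all ", length(net$genes), " network genes")
  if (any(is.na(x)) || any(x < 0)) stop("x must be non-negative, no NAs")
  pos <- x[x > 0]
  if (!length(pos)) stop("x is identically zero")
  x[x == 0] <- 1e-3 * min(pos)
  A <- net$A
  Ax <- as.numeric(A %*% x)
  if (any(Ax == 0)) stop("isolated node in network; invariant violated")
  P <- A * rep(x, each = nrow(A))        # P_ij ~ A_ij x_j
  P <- P / Ax
  pi <- x * Ax
  pi <- pi / sum(pi)
  lp <- ifelse(P > 0, log(P), 0)
  S <- -rowSums(P * lp)
  SR <- sum(pi * S)
  list(SR = SR, normalized = SR / log(net$lambda_max), pi = pi)
}

#' Signaling-entropy profile for every cell
#'
#' @param normalized a `NormalizedMatrix` (or genes x cells matrix) of
#'   non-negative expression values.
#' @param net a `CoexpressionNetwork` (typically fit on a reference dataset
#'   and frozen before application to perturbed cells).
#' @return An `EntropyProfile` data.frame: barcode, SR, normalized_SR.
#' @export
entropy_profile <- function(normalized, net) {
  values <- if (inherits(normalized, "NormalizedMatrix"))
    normalized$values else as.matrix(normalized)
  miss <- setdiff(net$genes, rownames(values))
  if (length(miss)) stop(length(miss), " network genes absent from matrix")
  v <- values[net$genes, , drop = FALSE]
  res <- apply(v, 2, function(x) {
    e <- signaling_entropy(pmax(x, 0), net)
    c(e$SR, e$normalized)
  })
  out <- data.frame(barcode = colnames(values),
                    SR = res[1, ], normalized_SR = res[2, ])
  class(out) <- c("EntropyProfile", "data.frame")
  out
}

#' Compare entropy between groups of cells
#'
#' All pairwise two-sided Wilcoxon rank-sum tests on the normalized entropy
#' rate, BH-adjusted across pairs. Singleton groups are excluded with a
#' warning.
#'
#' @param profiles an `EntropyProfile` (or numeric vector).
#' @param groups group labels aligned to cells.
#' @param min_cells minimum cells for a group to enter the comparison.
#' @return data.frame: group1, group2, p, q.
#' @export
compare_entropy_by_group <- function(profiles, groups, min_cells = 5) {
  x <- if (inherits(profiles, "data.frame")) profiles$normalized_SR
       else as.numeric(profiles)
  stopifnot(length(x) == length(groups))
  tab <- table(groups)
  small <- names(tab)[tab < min_cells]
  if (length(small)) {
    warning("excluding group(s) with fewer than ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    x <- x[keep]; groups <- groups[keep]
  }
  gs <- unique(as.character(groups))
  if (length(gs) < 2) stop("need at least 2 groups with enough cells")
  pairs <- utils::combn(gs, 2)
  p <- apply(pairs, 2, function(pr)
    suppressWarnings(stats::wilcox.test(x[groups == pr[1]],
                                        x[groups == pr[2]]))$p.value)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = p,
             q = stats::p.adjust(p, method = "BH"))
}
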