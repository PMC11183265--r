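# Independent oracles used across the suite. Each re-derives the quantity
# it checks by the most direct route available (enumeration, closed form,
# brute-force loops) without sharing code with the implementation.

# per-rule QC sieve: re-checks every criterion cell by cell with plain loops
sieve_oracle <- function(cm, th = qc_thresholds()) {
  counts <- as.matrix(cm$counts)
  n <- ncol(counts)
  keep <- rep(TRUE, n)
  totals <- colSums(counts)
  for (i in seq_len(n)) {
    b <- cm$cell_meta$batch[i]
    mates <- which(cm$cell_meta$batch == b)
    rk <- sum(cm$cell_meta$total_reads[mates] > cm$cell_meta$total_reads[i])
    ord <- order(cm$cell_meta$total_reads[mates], decreasing = TRUE)
    top <- mates[ord][seq_len(min(th$barcode_top_n, length(mates)))]
    if (!(i %in% top)) keep[i] <- FALSE
    if (sum(counts[cm$gene_meta$is_ercc, i]) / totals[i] >
          th$max_ercc_fraction) keep[i] <- FALSE
    if (sum(counts[cm$gene_meta$is_mito, i]) / totals[i] >
          th$max_mito_fraction) keep[i] <- FALSE
    ng <- sum(counts[, i] > 0)
    if (ng < th$min_genes || ng > th$max_genes) keep[i] <- FALSE
    for (g in which(cm$gene_meta$is_stromal_marker)) {
      if (log1p(counts[g, i] / totals[i] * 1e4) >
            th$stromal_expression_cutoff) keep[i] <- FALSE
    }
  }
  keep
}

# upper-tail hypergeometric by exhaustive enumeration of overlap counts
hyper_enum <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  sr <- rowSums(tab); sc <- colSums(tab); n <- sum(tab)
  si <- sum(choose(tab, 2))
  er <- sum(choose(sr, 2)) * sum(choose(sc, 2)) / choose(n, 2)
  mx <- (sum(choose(sr, 2)) + sum(choose(sc, 2))) / 2
  (si - er) / (mx - er)
}

# naive O(n^3) agglomeration with the Ward (ward.D2) Lance-Williams update;
# returns the list of partitions after each merge
ward_oracle_partitions <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  labels <- seq_len(n)
  partitions <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bv) { bv <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
          (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    part <- integer(n)
    for (ii in seq_along(active)) part[members[[active[ii]]]] <- ii
    partitions[[length(partitions) + 1]] <- part
  }
  partitions
}

# dense grid maximization of the single-hit log-likelihood over log f
grid_ld_mle <- function(table) {
  lf <- seq(log(1e-8), log(1), length.out = 200000)
  ll <- vapply(lf, function(l) {
    p <- 1 - exp(-exp(l) * table$dose)
    sum(table$positive * log(pmax(p, 1e-300)) -
          (table$tested - table$positive) * exp(l) * table$dose)
  }, numeric(1))
  exp(lf[which.max(ll)])
}

# exact two-sided rank-sum p by enumeration of all group assignments
ranksum_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  if (w_obs > mu) p <- 2 * mean(ws >= w_obs)
  else if (w_obs < mu) p <- 2 * mean(ws <= w_obs)
  else p <- 1
  min(p, 1)
}

# direct module-score recomputation following the documented sampling
# contract (rank-quantile bins; per set gene a draw from its bin; pooled
# unique controls), scored by plain two-mean arithmetic
module_score_oracle <- function(values, set_genes, n_bins, n_controls,
                                seed) {
  set.seed(seed)
  avg <- rowMeans(values)
  bin <- as.integer(cut(rank(avg, ties.method = "first"),
                        breaks = min(n_bins, nrow(values)),
                        labels = FALSE))
  names(bin) <- rownames(values)
  ctrl <- character()
  for (g in set_genes) {
    pool <- names(bin)[bin == bin[g]]
    ctrl <- c(ctrl, sample(pool, min(n_controls, length(pool))))
  }
  ctrl <- unique(ctrl)
  out <- numeric(ncol(values))
  for (j in seq_len(ncol(values)))
    out[j] <- mean(values[set_genes, j]) - mean(values[ctrl, j])
  out
}

# small default simulation shared by several files (kept below full size
# for speed; the acceptance suite runs the full default)
small_sim <- function(seed = 2, ...) {
  generate_aging_dataset(simulation_config(n_cells_per_age = 100,
                                           n_genes = 1000, seed = seed,
                                           ...))
}
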