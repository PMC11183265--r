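# one moderately sized simulated dataset shared across this file
traj_fixture <- local({
  d <- small_sim(seed = 21)
  f <- filter_cells_and_genes(d$counts)
  norm <- normalize_counts(f)
  # two-pass order: phases called on unregressed data, then regressed out
  cc <- call_cell_cycle(counts_to_log2_tpm(f), d$truth$phase_genes)
  reg <- regress_covariates(norm, data.frame(phase = factor(cc$phase)))
  pt <- infer_pseudotime(reg, root_age_months = 3)
  truth <- d$truth$cells[match(norm$cell_meta$barcode,
                               d$truth$cells$barcode), ]
  list(d = d, norm = norm, reg = reg, pt = pt, truth = truth)
})

test_that("pseudotime recovers the latent aging axis", {
  fx <- traj_fixture
  expect_gte(abs(cor(fx$pt$t, fx$truth$t_true, method = "spearman")), 0.9)
  # orientation: positive correlation after rooting at the youngest group
  expect_gt(cor(fx$pt$t, fx$truth$t_true, method = "spearman"), 0)
  expect_identical(range(fx$pt$t), c(0, 1))
})

test_that("young cells sit earlier than geriatric cells", {
  fx <- traj_fixture
  ages <- fx$norm$cell_meta$age_months
  expect_lt(mean(fx$pt$t[ages == min(ages)]),
            mean(fx$pt$t[ages == max(ages)]))
})

test_that("a noise-free linear gradient is recovered up to ties", {
  set.seed(30)
  n <- 80
  grad <- seq(0, 1, length.out = n)
  load <- runif(40, -1, 1)
  values <- outer(load, grad)
  gm <- data.frame(name = paste0("g", 1:40), is_ercc = FALSE,
                   is_mito = FALSE, is_stromal_marker = FALSE)
  cmeta <- data.frame(barcode = paste0("c", 1:n),
                      age_months = rep(c(2, 25), each = n / 2))
  nm <- normalized_matrix(values, gm, cmeta)
  pt <- infer_pseudotime(nm, root_age_months = 2, n_neighbors = 10)
  expect_identical(unname(rank(pt$t)), rank(grad))
})

test_that("pseudotime is invariant under cell permutation", {
  fx <- traj_fixture
  set.seed(35)
  perm <- sample(ncol(fx$reg$values))
  nm2 <- normalized_matrix(fx$reg$values[, perm],
                           fx$reg$gene_meta,
                           fx$reg$cell_meta[perm, ])
  pt2 <- infer_pseudotime(nm2, root_age_months = 3)
  # identical ordering up to numerically tied neighbors
  expect_gt(cor(pt2$t[names(fx$pt$t)], fx$pt$t, method = "spearman"),
            0.9999)
})

test_that("the spline LRT is calibrated and powered", {
  set.seed(31)
  n <- 300
  tv <- runif(n)
  # null: no pseudotime dependence
  Y <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("n%04d", 1:1000), NULL))
  gm <- data.frame(name = rownames(Y), is_ercc = FALSE, is_mito = FALSE,
                   is_stromal_marker = FALSE)
  nm <- normalized_matrix(Y, gm, data.frame(barcode = paste0("c", 1:n)))
  res <- test_pseudotime_genes(nm, tv)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
  # constant gene: never selected
  Y2 <- rbind(Y[1:5, ], const = 3)
  gm2 <- data.frame(name = rownames(Y2), is_ercc = FALSE, is_mito = FALSE,
                    is_stromal_marker = FALSE)
  nm2 <- normalized_matrix(Y2, gm2, data.frame(barcode = paste0("c", 1:n)))
  res2 <- test_pseudotime_genes(nm2, tv)
  expect_identical(res2$p[res2$gene == "const"], 1)
  expect_false(res2$selected[res2$gene == "const"])
  # power: linear signal, slope 1, noise sd 0.5, n = 500
  set.seed(32)
  t5 <- runif(500)
  sig <- matrix(t5 + rnorm(500, sd = 0.5), 1,
                dimnames = list("sig", NULL))
  nm3 <- normalized_matrix(rbind(sig, sig * 0 + 1),
                           data.frame(name = c("sig", "flat"),
                                      is_ercc = FALSE, is_mito = FALSE,
                                      is_stromal_marker = FALSE),
                           data.frame(barcode = paste0("c", 1:500)))
  res3 <- test_pseudotime_genes(nm3, t5)
  expect_lt(res3$q[res3$gene == "sig"], 1e-6)
})

test_that("smoothed curves are standardized and truncated to [-3, 3]", {
  fx <- traj_fixture
  sel <- test_pseudotime_genes(fx$reg, fx$pt)
  genes <- sel$gene[sel$selected][1:50]
  cur <- smooth_scale_truncate(fx$norm, fx$pt, genes)
  expect_true(all(cur$values >= -3 & cur$values <= 3))
  expect_identical(dim(cur$values), c(50L, 100L))
  # a constant gene flattens to all zeros
  flat <- matrix(2, 3, 200,
                 dimnames = list(paste0("f", 1:3), paste0("c", 1:200)))
  nm <- normalized_matrix(flat,
                          data.frame(name = paste0("f", 1:3),
                                     is_ercc = FALSE, is_mito = FALSE,
                                     is_stromal_marker = FALSE),
                          data.frame(barcode = paste0("c", 1:200)))
  curf <- smooth_scale_truncate(nm, seq(0, 1, length.out = 200),
                                paste0("f", 1:3))
  expect_true(all(curf$values == 0))
  # extreme z-values are clamped symmetrically
  z <- c(rnorm(97, sd = 0.1), 4.2, -5, 0)
  expect_identical(max(pmin(pmax(z, -3), 3)), 3)
})

test_that("gene clustering recovers planted curve families", {
  set.seed(33)
  grid <- seq(0, 1, length.out = 100)
  shapes <- list(function(t) 1 - t, function(t) t,
                 function(t) exp(-(t - 0.3)^2 / 0.02),
                 function(t) exp(-(t - 0.8)^2 / 0.02))
  vals <- do.call(rbind, lapply(1:4, function(k)
    t(replicate(20, shapes[[k]](grid) + rnorm(100, sd = 0.05)))))
  rownames(vals) <- sprintf("g%03d", 1:80)
  cur <- structure(list(grid = grid, values = vals), class = "SmoothedCurves")
  cl <- cluster_genes(cur, 4)
  expect_gte(ari(cl$cluster, rep(1:4, each = 20)), 0.9)
  # k = 1 puts everything together; k > genes errors
  expect_true(all(cluster_genes(cur, 1)$cluster == 1))
  expect_error(cluster_genes(cur, 81), "exceeds")
})

test_that("agglomeration matches a naive Ward oracle on a small instance", {
  set.seed(34)
  X <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), NULL))
  cur <- structure(list(grid = seq_len(10), values = X),
                   class = "SmoothedCurves")
  parts <- ward_oracle_partitions(X)
  for (k in 2:5) {
    got <- cluster_genes(cur, k)$cluster
    oracle <- parts[[6 - k]]
    expect_equal(ari(got, oracle), 1)
  }
})

test_that("state segmentation finds boundaries and is monotone in t", {
  fx <- traj_fixture
  sel <- test_pseudotime_genes(fx$reg, fx$pt)
  cur <- smooth_scale_truncate(fx$norm, fx$pt, sel$gene[sel$selected])
  cl <- cluster_genes(cur, 4)
  sm <- assign_states(cur, cl, fx$pt)
  expect_length(sm$boundaries, 3)
  expect_true(all(diff(sm$boundaries) > 0))
  # monotone step function of t
  o <- order(fx$pt$t)
  expect_true(all(diff(sm$state[o]) >= 0))
  # end points of the axis land in the terminal states
  expect_identical(unname(sm$state[which.min(fx$pt$t)]), 1L)
  expect_identical(unname(sm$state[which.max(fx$pt$t)]), 4L)
  # recovery of the generator's boundaries
  expect_lt(max(abs(sm$boundaries - fx$d$truth$boundaries)), 0.05)
  expect_gte(mean(sm$state == fx$truth$state_true), 0.9)
})

test_that("a cluster that never dominates raises a useful error", {
  grid <- seq(0, 1, length.out = 100)
  v <- rbind(a1 = 3 * (1 - grid), a2 = 3 * (1 - grid) - 0.1,
             b = 3 * grid, c = 3 * grid - 0.1)
  cur <- structure(list(grid = grid, values = v), class = "SmoothedCurves")
  cl <- structure(list(cluster = c(a1 = 1L, a2 = 2L, b = 3L, c = 4L),
                       k = 4L, linkage = "ward.D2"),
                  class = "GeneClusterMap")
  expect_error(assign_states(cur, cl, runif(50)), "re-cluster")
})
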