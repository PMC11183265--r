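# builds a small clean matrix by hand, then plants one violation per rule
make_qc_fixture <- function(n_cells = 100, seed = 1) {
  set.seed(seed)
  n_genes <- 320
  gene_meta <- data.frame(
    name = c(sprintf("G%03d", 1:300), sprintf("ERCC-%02d", 1:10),
             sprintf("mt-%02d", 1:6), "Pecam1", "Ptprc", "Lyve1", "Col1a1"),
    is_ercc = rep(c(FALSE, TRUE, FALSE), c(300, 10, 10)),
    is_mito = rep(c(FALSE, TRUE, FALSE), c(310, 6, 4)),
    is_stromal_marker = rep(c(FALSE, TRUE), c(316, 4)))
  counts <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
  counts[gene_meta$is_ercc, ] <- rpois(10 * n_cells, 2)      # ~1% ERCC
  counts[gene_meta$is_mito, ] <- rpois(6 * n_cells, 3)
  counts[gene_meta$is_stromal_marker, ] <- 0
  cell_meta <- data.frame(barcode = sprintf("c%03d", 1:n_cells),
                          age_months = 3, batch = "b1", genotype = "WT",
                          treatment = "none",
                          total_reads = colSums(counts) + 1000)
  list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta)
}

test_that("each planted QC violation removes exactly that cell", {
  fx <- make_qc_fixture()
  counts <- fx$counts
  # cell 1: ERCC fraction driven above 10%
  counts[fx$gene_meta$is_ercc, 1] <- 60
  # cell 2: mitochondrial fraction above 5%
  counts[fx$gene_meta$is_mito, 2] <- 40
  # cell 3: fewer than 200 detected genes
  counts[, 3] <- 0; counts[1:150, 3] <- 5
  # cell 4: stromal marker expressed
  counts[which(fx$gene_meta$name == "Pecam1"), 4] <- 50
  # cell 5: barcode outside the per-batch top-N (rank pushed past 100)
  fx$cell_meta$total_reads[5] <- 0
  th <- qc_thresholds(barcode_top_n = 99)
  cm <- count_matrix(counts, fx$gene_meta, fx$cell_meta)
  out <- filter_cells_and_genes(cm, th)
  keep_oracle <- sieve_oracle(cm, th)
  expect_setequal(out$cell_meta$barcode,
                  cm$cell_meta$barcode[keep_oracle])
  expect_false(any(sprintf("c%03d", 1:5) %in% out$cell_meta$barcode))
  log <- attr(out, "qc_log")
  expect_identical(log$n_cells_out, 95L)
  expect_true(sum(log$excluded) + log$n_cells_out >= log$n_cells_in)
})

test_that("a cell with ERCC fraction 0.12 is removed, a clean cell kept", {
  fx <- make_qc_fixture(seed = 2)
  counts <- fx$counts
  tot <- sum(counts[, 1])
  counts[fx$gene_meta$is_ercc, 1] <- 0
  counts[which(fx$gene_meta$is_ercc)[1], 1] <-
    round(0.12 / 0.88 * sum(counts[!fx$gene_meta$is_ercc, 1]))
  cm <- count_matrix(counts, fx$gene_meta, fx$cell_meta)
  out <- filter_cells_and_genes(cm)
  expect_false("c001" %in% out$cell_meta$barcode)
  expect_true("c002" %in% out$cell_meta$barcode)
})

test_that("filtering is idempotent and drops under-detected genes", {
  d <- small_sim(seed = 8)
  f1 <- filter_cells_and_genes(d$counts)
  f2 <- filter_cells_and_genes(f1)
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
  expect_identical(f1$cell_meta$barcode, f2$cell_meta$barcode)
})

test_that("empty QC output names the dominant filter", {
  fx <- make_qc_fixture()
  counts <- fx$counts
  counts[fx$gene_meta$is_mito, ] <- 500      # every cell fails on mito
  cm <- count_matrix(counts, fx$gene_meta, fx$cell_meta)
  expect_error(filter_cells_and_genes(cm), "ercc_mito_fraction")
})

test_that("log-normalization matches its closed form and is monotone", {
  fx <- make_qc_fixture(seed = 3)
  counts <- fx$counts
  counts[, 1] <- 0
  counts[1, 1] <- 10
  counts[2:301, 1] <- rep(c(9990 %/% 300, 0), c(300, 0))
  counts[2, 1] <- counts[2, 1] + 9990 %% 300   # cell total exactly 10000
  cm <- count_matrix(counts, fx$gene_meta, fx$cell_meta)
  norm <- normalize_counts(cm, scale_factor = 1e4)
  expect_equal(norm$values[1, 1], log(11), tolerance = 1e-12)
  zero <- which(counts[, 2] == 0)[1]
  expect_identical(norm$values[zero, 2], 0)
  # monotone within a cell
  o <- order(counts[, 3])
  expect_true(all(diff(norm$values[o, 3]) >= 0))
})

test_that("zero-total cells make normalization fail loudly", {
  fx <- make_qc_fixture(seed = 4)
  fx$counts[, 7] <- 0
  cm <- count_matrix(fx$counts, fx$gene_meta, fx$cell_meta)
  expect_error(normalize_counts(cm), "zero total")
})

test_that("covariate regression is orthogonal and matches normal equations", {
  set.seed(11)
  n <- 20
  cov <- data.frame(ercc = runif(n), batch = rep(c("a", "b"), 10))
  values <- matrix(rnorm(5 * n), 5, n)
  values[1, ] <- 2 * cov$ercc + rnorm(n, sd = 0.1)
  gm <- data.frame(name = paste0("g", 1:5), is_ercc = FALSE,
                   is_mito = FALSE, is_stromal_marker = FALSE)
  cmeta <- data.frame(barcode = paste0("c", 1:n))
  nm <- normalized_matrix(values, gm, cmeta)
  res <- regress_covariates(nm, cov)
  expect_lt(abs(cor(res$values[1, ], cov$ercc)), 1e-6)
  # normal-equations oracle: residual = y - X (X'X)^-1 X'y
  X <- cbind(1, cov$ercc, as.numeric(cov$batch == "b"))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  for (g in 1:5) {
    oracle <- values[g, ] - as.numeric(H %*% values[g, ])
    expect_equal(unname(res$values[g, ]), oracle, tolerance = 1e-10)
  }
})

test_that("a constant covariate reduces regression to centering", {
  set.seed(12)
  values <- matrix(rnorm(3 * 15), 3, 15)
  gm <- data.frame(name = paste0("g", 1:3), is_ercc = FALSE,
                   is_mito = FALSE, is_stromal_marker = FALSE)
  nm <- normalized_matrix(values, gm, data.frame(barcode = paste0("c", 1:15)))
  expect_warning(res <- regress_covariates(nm, data.frame(k = rep(1, 15))),
                 "rank-deficient")
  expect_equal(res$values, values - rowMeans(values),
               ignore_attr = TRUE, tolerance = 1e-12)
})
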