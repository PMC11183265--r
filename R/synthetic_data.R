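#' Simulation configuration for the synthetic aging dataset
#'
#' Defines the study conditions the generator emulates: four latent cell
#' states (a-Young, q-Young, e-Sen, l-Sen) ordered along one latent aging
#' axis in `[0,1]`, a state mixture that drifts with chronological age (the
#' a-Young share falls and the l-Sen share rises), gene programs following
#' six dynamic patterns over the axis, cell-cycle phase structure, ERCC
#' spike-in and mitochondrial count fractions, and a small number of stromal
#' contaminant cells.
#'
#' @param n_cells_per_age cells simulated in each age group.
#' @param ages age groups in months.
#' @param state_mixture 4 x length(ages) matrix of state proportions per age
#'   group (columns sum to 1).
#' @param n_genes total number of genes, spike-ins included.
#' @param genes_per_pattern genes assigned to each of the six dynamic
#'   patterns.
#' @param amplitude log-scale amplitude of the pattern effect on the
#'   negative-binomial mean.
#' @param nb_dispersion shared negative-binomial dispersion theta
#'   (variance = mu + mu^2 / theta).
#' @param library_size_lognormal `c(meanlog, sdlog)` of the per-cell library
#'   size factor.
#' @param ercc_fraction expected fraction of counts from ERCC spike-ins.
#' @param mito_fraction expected fraction of counts from mitochondrial genes.
#' @param n_stromal_contaminants stromal (non-epithelial) contaminant cells
#'   appended to the matrix.
#' @param phase_mixture proportions over the six cell-cycle phases
#'   G0, G1/S, S, G2, G2/M, M/G1.
#' @param phase_strength log-scale up-shift of a phase gene in cells of its
#'   phase.
#' @param n_ko_cells knockout cells appended (genotype "KO"), drawn from
#'   `ko_state_mixture` and with `ko_targets` de-repressed.
#' @param ko_state_mixture state mixture of KO cells (shifted late).
#' @param ko_shift log-scale up-shift of KO target genes in KO cells.
#' @param state_boundaries latent-axis positions of the three state borders.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A `SimulationConfig` (validated list).
#' @export
simulation_config <- function(n_cells_per_age = 200,
                              ages = c(3, 12, 17, 25),
                              state_mixture = NULL,
                              n_genes = 1500,
                              genes_per_pattern = 60,
                              amplitude = 1.5,
                              nb_dispersion = 10,
                              library_size_lognormal = c(0, 0.3),
                              ercc_fraction = 0.03,
                              mito_fraction = 0.02,
                              n_stromal_contaminants = 5,
                              phase_mixture = c(G0 = 0.30, `G1/S` = 0.15,
                                                S = 0.15, G2 = 0.10,
                                                `G2/M` = 0.20,
                                                `M/G1` = 0.10),
                              phase_strength = 2,
                              n_ko_cells = 0,
                              ko_state_mixture = c(0.05, 0.10, 0.35, 0.50),
                              ko_shift = 1.5,
                              state_boundaries = c(0.25, 0.55, 0.85),
                              seed = 1L) {
  if (is.null(state_mixture)) {
    # anchor mixtures: young / middle / old / geriatric; the a-Young share
    # declines and the l-Sen share rises with age, and the pooled state
    # abundances match the latent state-interval widths (state 3 widest)
    anchors <- cbind(c(0.55, 0.33, 0.10, 0.02),
                     c(0.28, 0.37, 0.28, 0.07),
                     c(0.12, 0.28, 0.40, 0.20),
                     c(0.05, 0.22, 0.40, 0.33))
    if (length(ages) == 4) {
      state_mixture <- anchors
    } else {
      # linear interpolation between anchors at the configured ages
      anchor_ages <- seq(min(ages), max(ages), length.out = 4)
      state_mixture <- vapply(ages, function(a) {
        w <- stats::approx(anchor_ages, seq_len(4), xout = a)$y
        lo <- floor(w); hi <- ceiling(w); fr <- w - lo
        anchors[, lo] * (1 - fr) + anchors[, hi] * fr
      }, numeric(4))
    }
  }
  state_mixture <- as.matrix(state_mixture)
  cfg <- list(n_cells_per_age = n_cells_per_age, ages = ages,
              state_mixture = state_mixture, n_genes = n_genes,
              genes_per_pattern = genes_per_pattern, amplitude = amplitude,
              nb_dispersion = nb_dispersion,
              library_size_lognormal = library_size_lognormal,
              ercc_fraction = ercc_fraction, mito_fraction = mito_fraction,
              n_stromal_contaminants = n_stromal_contaminants,
              phase_mixture = phase_mixture, phase_strength = phase_strength,
              n_ko_cells = n_ko_cells, ko_state_mixture = ko_state_mixture,
              ko_shift = ko_shift, state_boundaries = state_boundaries,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_cells_per_age > 0, cfg$n_genes > 0,
            cfg$nb_dispersion > 0,
            all(cfg$ages >= 2), all(cfg$ages <= 29),
            length(cfg$state_boundaries) == 3,
            all(diff(cfg$state_boundaries) > 0))
  if (nrow(cfg$state_mixture) != 4 ||
      ncol(cfg$state_mixture) != length(cfg$ages))
    stop("state_mixture must be 4 x length(ages)")
  if (any(abs(colSums(cfg$state_mixture) - 1) > 1e-9))
    stop("state mixtures must sum to 1")
  if (abs(sum(cfg$phase_mixture) - 1) > 1e-9)
    stop("phase_mixture must sum to 1")
  if (any(abs(sum(cfg$ko_state_mixture) - 1) > 1e-9))
    stop("ko_state_mixture must sum to 1")
  if (any(rowSums(cfg$state_mixture) == 0))
    warning("degenerate mixture: a state has zero cells at every age")
  invisible(cfg)
}

# The six pattern curve shapes over latent time t in [0,1]:
# 1 declining logistic ramp; 2/3 Gaussian bumps centered in states 2/3;
# 4 rising logistic ramp with a plateau spanning states 3-4; 5 late rising
# ramp still increasing through state 4; 6 narrow late bump in state 4.
# Centers and widths are calibrated so that, noise-free, the argmax of the
# standardized cluster-average programs (with patterns 4-6 forming the late
# cluster) switches exactly at the configured state boundaries
# 0.25 / 0.55 / 0.85 -- the generator's states are, by construction, the
# intervals where one program dominates.
pattern_curve <- function(pattern, t) {
  switch(as.character(pattern),
         "1" = stats::plogis((0.285 - t) / 0.09),
         "2" = exp(-((t - 0.375)^2) / (2 * 0.13^2)),
         "3" = exp(-((t - 0.725)^2) / (2 * 0.13^2)),
         "4" = stats::plogis((t - 0.635) / 0.075),
         "5" = stats::plogis((t - 0.83) / 0.125),
         "6" = exp(-((t - 0.975)^2) / (2 * 0.045^2)),
         rep(0, length(t)))
}

sample_state_t <- function(n, mixture, boundaries) {
  edges <- c(0, boundaries, 1)
  state <- sample.int(4, n, replace = TRUE, prob = mixture)
  t <- stats::runif(n, edges[state], edges[state + 1])
  list(state = state, t = t)
}

#' Generate a synthetic aging scRNA-seq dataset with ground truth
#'
#' Samples per-cell latent aging positions from the age-dependent state
#' mixture, then draws UMI counts gene-wise from a negative binomial whose
#' mean is `library_size * baseline * exp(amplitude * pattern(t))`. ERCC
#' spike-ins have constant means, mitochondrial genes a fixed expected count
#' share, cell-cycle phase genes are up-shifted in cells of their phase, and
#' a few stromal contaminant cells express the canonical stromal markers
#' (Pecam1, Ptprc, Lyve1, Col1a1). SASP-like and stemness gene sets are tied
#' to late-rising (patterns 4/5) and early-declining (pattern 1) programs.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a `CountMatrix`) and `truth` (a `GroundTruth`
#'   list: per-cell `t_true`, `state_true`, `phase_true`, `is_contaminant`;
#'   per-gene `pattern_true`; state boundaries; gene sets; phase-gene table;
#'   KO target genes).
#' @export
generate_aging_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  cfg <- config
  phases <- c("G0", "G1/S", "S", "G2", "G2/M", "M/G1")
  cyc_phases <- setdiff(phases, "G0")

  ## ---- gene layout -------------------------------------------------------
  n_pat <- 6 * cfg$genes_per_pattern
  # per-phase program sizes mirror what correlation-filtered Whitfield
  # phase lists typically retain in epithelial data
  phase_gene_counts <- c("G1/S" = 14, "S" = 13, "G2" = 13, "G2/M" = 21,
                         "M/G1" = 19)
  n_phase_genes <- sum(phase_gene_counts)
  n_ko_targets <- 30
  n_mito <- 30
  n_ercc <- 20
  n_stromal <- 4
  n_filler <- cfg$n_genes - n_pat - n_phase_genes - n_ko_targets -
    n_mito - n_ercc - n_stromal
  if (n_filler < 0) stop("n_genes too small for the configured gene layout")

  pattern_true <- c(rep(1:6, each = cfg$genes_per_pattern),
                    rep(NA_integer_, cfg$n_genes - n_pat))
  gene_name <- character(cfg$n_genes)
  idx_pat <- seq_len(n_pat)
  idx_phase <- n_pat + seq_len(n_phase_genes)
  idx_ko <- n_pat + n_phase_genes + seq_len(n_ko_targets)
  idx_mito <- n_pat + n_phase_genes + n_ko_targets + seq_len(n_mito)
  idx_fill <- n_pat + n_phase_genes + n_ko_targets + n_mito +
    seq_len(n_filler)
  idx_strom <- n_pat + n_phase_genes + n_ko_targets + n_mito + n_filler +
    seq_len(n_stromal)
  idx_ercc <- cfg$n_genes - n_ercc + seq_len(n_ercc)
  gene_name[idx_pat] <- sprintf("Pat%d.%03d", pattern_true[idx_pat],
                                sequence(rep(cfg$genes_per_pattern, 6)))
  phase_of_gene <- rep(names(phase_gene_counts), phase_gene_counts)
  gene_name[idx_phase] <- sprintf("Cyc%s.%02d",
                                  gsub("/", "", phase_of_gene),
                                  sequence(phase_gene_counts))
  gene_name[idx_ko] <- sprintf("KoTgt.%03d", seq_len(n_ko_targets))
  gene_name[idx_mito] <- sprintf("mt-G%03d", seq_len(n_mito))
  gene_name[idx_fill] <- sprintf("Null.%04d", seq_len(n_filler))
  gene_name[idx_strom] <- c("Pecam1", "Ptprc", "Lyve1", "Col1a1")
  gene_name[idx_ercc] <- sprintf("ERCC-%05d", seq_len(n_ercc))

  gene_meta <- data.frame(name = gene_name,
                          is_ercc = seq_len(cfg$n_genes) %in% idx_ercc,
                          is_mito = seq_len(cfg$n_genes) %in% idx_mito,
                          is_stromal_marker =
                            seq_len(cfg$n_genes) %in% idx_strom)

  ## ---- cell layout -------------------------------------------------------
  n_wt <- cfg$n_cells_per_age * length(cfg$ages)
  age <- rep(cfg$ages, each = cfg$n_cells_per_age)
  st <- lapply(seq_along(cfg$ages), function(i)
    sample_state_t(cfg$n_cells_per_age, cfg$state_mixture[, i],
                   cfg$state_boundaries))
  t_true <- unlist(lapply(st, `[[`, "t"))
  state_true <- unlist(lapply(st, `[[`, "state"))
  genotype <- rep("WT", n_wt)
  if (cfg$n_ko_cells > 0) {
    ko <- sample_state_t(cfg$n_ko_cells, cfg$ko_state_mixture,
                         cfg$state_boundaries)
    t_true <- c(t_true, ko$t)
    state_true <- c(state_true, ko$state)
    age <- c(age, rep(4, cfg$n_ko_cells))
    genotype <- c(genotype, rep("KO", cfg$n_ko_cells))
  }
  n_real <- length(t_true)
  n_cont <- cfg$n_stromal_contaminants
  if (n_cont > 0) {
    cont <- sample_state_t(n_cont, c(0.25, 0.25, 0.25, 0.25),
                           cfg$state_boundaries)
    t_true <- c(t_true, cont$t)
    state_true <- c(state_true, cont$state)
    age <- c(age, rep(age[1], n_cont))
    genotype <- c(genotype, rep("WT", n_cont))
  }
  n_cells <- n_real + n_cont
  is_contaminant <- c(rep(FALSE, n_real), rep(TRUE, n_cont))
  phase_true <- sample(phases, n_cells, replace = TRUE,
                       prob = cfg$phase_mixture)

  ## ---- mean matrix -------------------------------------------------------
  lib <- stats::rlnorm(n_cells, cfg$library_size_lognormal[1],
                       cfg$library_size_lognormal[2])
  baseline <- stats::rlnorm(cfg$n_genes, log(1.5), 0.8)
  baseline[idx_strom] <- 0.005   # stromal markers near-silent in epithelium
  mu <- matrix(baseline, cfg$n_genes, n_cells)
  for (p in 1:6) {
    g <- which(pattern_true == p)
    mu[g, ] <- mu[g, ] *
      rep(exp(cfg$amplitude * pattern_curve(p, t_true)),
          each = length(g))
  }
  # phase programs activate fully in their own phase and partially in the
  # cyclically adjacent phases (G1/S -> S -> G2 -> G2/M -> M/G1 -> G1/S),
  # emulating the gradual progression of cell-cycle expression
  # G0 (quiescent) cells actively repress the cycling programs, they do
  # not merely sit at baseline
  cyc_order <- c("G1/S", "S", "G2", "G2/M", "M/G1")
  for (ph in cyc_phases) {
    g <- idx_phase[phase_of_gene == ph]
    i <- match(ph, cyc_order)
    nb <- cyc_order[c((i - 2) %% 5 + 1, i %% 5 + 1)]
    w <- ifelse(phase_true == ph, 1,
         ifelse(phase_true %in% nb, 0.45,
         ifelse(phase_true == "G0", -0.3, 0)))
    mu[g, ] <- mu[g, ] * rep(exp(cfg$phase_strength * w),
                             each = length(g))
  }
  if (cfg$n_ko_cells > 0) {
    ko_cells <- genotype == "KO"
    mu[idx_ko, ko_cells] <- mu[idx_ko, ko_cells] * exp(cfg$ko_shift)
  }
  if (n_cont > 0) {
    cc <- which(is_contaminant)
    mu[idx_strom, cc] <- 30    # contaminants express stromal markers highly
  }
  mu <- mu * rep(lib, each = cfg$n_genes)

  # calibrate mitochondrial share, then add constant-mean spike-ins
  endo <- setdiff(seq_len(cfg$n_genes), idx_ercc)
  m_tot <- sum(mu[idx_mito, ]); t_tot <- sum(mu[endo, ])
  s <- cfg$mito_fraction * (t_tot - m_tot) /
    (m_tot * (1 - cfg$mito_fraction))
  mu[idx_mito, ] <- mu[idx_mito, ] * s
  per_cell_endo <- mean(colSums(mu[endo, ]))
  mu[idx_ercc, ] <- cfg$ercc_fraction / (1 - cfg$ercc_fraction) *
    per_cell_endo / n_ercc

  counts <- matrix(stats::rnbinom(length(mu), size = cfg$nb_dispersion,
                                  mu = mu),
                   cfg$n_genes, n_cells)

  ## ---- assemble ----------------------------------------------------------
  n_batch <- ceiling(cfg$n_cells_per_age / 100)
  batch <- character(n_cells)
  batch[seq_len(n_wt)] <- paste0("A", age[seq_len(n_wt)], ".",
    rep(rep(seq_len(n_batch), each = ceiling(cfg$n_cells_per_age / n_batch),
            length.out = cfg$n_cells_per_age), length(cfg$ages)))
  if (n_cells > n_wt)
    batch[(n_wt + 1):n_cells] <- ifelse(
      genotype[(n_wt + 1):n_cells] == "KO", "KO.1", batch[1])
  cell_meta <- data.frame(
    barcode = sprintf("cell%04d", seq_len(n_cells)),
    age_months = age, batch = batch, genotype = genotype,
    treatment = "none", total_reads = colSums(counts))
  cm <- count_matrix(counts, gene_meta, cell_meta)

  gene_sets <- list(
    SASP = gene_name[pattern_true %in% c(4, 5) &
                       seq_len(cfg$n_genes) %in%
                         c(idx_pat[pattern_true[idx_pat] == 4][1:20],
                           idx_pat[pattern_true[idx_pat] == 5][1:20])],
    stemness = gene_name[idx_pat[pattern_true[idx_pat] == 1][1:20]])
  truth <- structure(list(
    cells = data.frame(barcode = cell_meta$barcode, t_true = t_true,
                       state_true = state_true, phase_true = phase_true,
                       is_contaminant = is_contaminant),
    genes = data.frame(name = gene_name, pattern_true = pattern_true),
    boundaries = cfg$state_boundaries,
    gene_sets = gene_sets,
    phase_genes = data.frame(gene = gene_name[idx_phase],
                             phase = phase_of_gene),
    ko_targets = gene_name[idx_ko],
    config = cfg), class = "GroundTruth")
  list(counts = cm, truth = truth)
}

#' Generate a synthetic TF-target database with one planted regulator
#'
#' Builds a multi-source TF->target table in which one transcription factor
#' has planted target overlap with a designated gene cluster in at least two
#' sources, while all remaining target sets are drawn uniformly from the
#' universe.
#'
#' @param universe character vector of gene names (the enrichment universe).
#' @param cluster_genes genes of the designated cluster the planted TF
#'   regulates.
#' @param n_tfs number of transcription factors per source.
#' @param targets_per_tf target-set size for every TF.
#' @param n_sources number of database sources (labelled src1, src2, ...).
#' @param planted_tf name of the planted TF.
#' @param planted_cluster_overlap how many of the planted TF's targets fall
#'   inside `cluster_genes` (must be <= `targets_per_tf`).
#' @param seed integer seed.
#' @return A `TFTargetDatabase`: list with `records` (tf, target, source)
#'   and `universe`.
#' @export
generate_tf_database <- function(universe, cluster_genes, n_tfs = 20,
                                 targets_per_tf = 25, n_sources = 3,
                                 planted_tf = "TFplanted",
                                 planted_cluster_overlap = 20,
                                 seed = 1L) {
  stopifnot(planted_cluster_overlap <= targets_per_tf,
            length(cluster_genes) >= planted_cluster_overlap,
            all(cluster_genes %in% universe), n_sources >= 1)
  set.seed(as.integer(seed))
  sources <- paste0("src", seq_len(n_sources))
  recs <- list()
  for (s in sources) {
    for (i in seq_len(n_tfs)) {
      tf <- paste0("TF", i)
      tgt <- sample(universe, targets_per_tf)
      recs[[length(recs) + 1]] <- data.frame(tf = tf, target = tgt,
                                             source = s)
    }
  }
  # plant enrichment in (at least) the first two sources
  for (s in sources[seq_len(min(2, n_sources))]) {
    inside <- sample(cluster_genes, planted_cluster_overlap)
    outside <- sample(setdiff(universe, cluster_genes),
                      targets_per_tf - planted_cluster_overlap)
    recs[[length(recs) + 1]] <- data.frame(tf = planted_tf,
                                           target = c(inside, outside),
                                           source = s)
  }
  records <- unique(do.call(rbind, recs))
  structure(list(records = records, universe = universe),
            class = "TFTargetDatabase")
}

#' Generate limiting-dilution transplant tables from the single-hit model
#'
#' Each well receives `dose` cells and turns positive with probability
#' `1 - exp(-f * dose)`, independently across wells.
#'
#' @param true_frequency per-cell repopulating frequency f (scalar or one
#'   per group), in (0, 1].
#' @param doses cell doses transplanted (one row per dose per group).
#' @param replicates wells tested per dose.
#' @param n_groups number of groups (recycled over `true_frequency`).
#' @param seed integer seed.
#' @return An `LDAssayTable` data.frame: group, dose, tested, positive.
#' @export
generate_ld_assay <- function(true_frequency, doses, replicates = 12,
                              n_groups = 1, seed = 1L) {
  stopifnot(all(doses > 0), all(true_frequency > 0),
            all(true_frequency <= 1))
  set.seed(as.integer(seed))
  f <- rep_len(true_frequency, n_groups)
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    data.frame(group = paste0("group", g), dose = doses,
               tested = replicates,
               positive = stats::rbinom(length(doses), replicates,
                                        1 - exp(-f[g] * doses)))
  }))
  class(out) <- c("LDAssayTable", "data.frame")
  out
}
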