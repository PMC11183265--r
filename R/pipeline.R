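#' Pipeline configuration
#'
#' Bundles every stage's parameters, toggles and seeds into one
#' serializable object. Stages run in the fixed order simulate, qc,
#' normalize, trajectory, states, scores, entropy.
#'
#' @param out_dir run directory for stage outputs and the manifest.
#' @param sim a [simulation_config()] (used when the simulate stage is on).
#' @param qc a [qc_thresholds()].
#' @param stages named logical vector of stage toggles.
#' @param regress regress the cell-cycle phase (called on unregressed
#'   data, then encoded as a factor) out of the normalized matrix before
#'   trajectory inference.
#' @param regress_qc_covariates also regress ERCC fraction, mitochondrial
#'   fraction and detected-gene number; off by default because library
#'   composition couples these to the aging axis, so removing them strips
#'   genuine signal along with the technical part.
#' @param regress_batch also regress sequencing batch; off by default
#'   because batches are nested within age groups here, so the batch
#'   factor would absorb the aging signal itself.
#' @param root_age_months rooting age for pseudotime (default: youngest).
#' @param q_cutoff q cutoff for pseudotime-dependent genes.
#' @param k gene clusters for state segmentation.
#' @param grid_size smoothing grid size.
#' @param r_min co-expression edge threshold for the entropy network.
#' @param n_network_genes most variable genes used for the network.
#' @param score_seed seed for module-score control draws.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = simulation_config(),
                            qc = qc_thresholds(),
                            stages = c(simulate = TRUE, qc = TRUE,
                                       normalize = TRUE, trajectory = TRUE,
                                       states = TRUE, scores = TRUE,
                                       entropy = TRUE),
                            regress = TRUE,
                            regress_qc_covariates = FALSE,
                            regress_batch = FALSE,
                            root_age_months = NULL,
                            q_cutoff = 0.05, k = 4, grid_size = 100,
                            r_min = 0.3, n_network_genes = 300,
                            score_seed = 1L) {
  structure(list(out_dir = out_dir, sim = sim, qc = qc, stages = stages,
                 regress = regress,
                 regress_qc_covariates = regress_qc_covariates,
                 regress_batch = regress_batch,
                 root_age_months = root_age_months,
                 q_cutoff = q_cutoff, k = k, grid_size = grid_size,
                 r_min = r_min, n_network_genes = n_network_genes,
                 score_seed = as.integer(score_seed)),
            class = "PipelineConfig")
}

#' Save / load a pipeline configuration as YAML
#'
#' The round trip is lossless: `load_pipeline_config(save_pipeline_config(
#' cfg, path))` reproduces `cfg`.
#'
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @return `path` / the restored `PipelineConfig`.
#' @export
save_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$state_mixture <- apply(x$sim$state_mixture, 2, identity,
                               simplify = FALSE)
  x$sim$phase_mixture <- as.list(x$sim$phase_mixture)
  x$qc <- unclass(x$qc)
  x$stages <- as.list(x$stages)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$sim
  sim$state_mixture <- do.call(cbind, sim$state_mixture)
  sim$phase_mixture <- unlist(sim$phase_mixture)
  sim$seed <- as.integer(sim$seed)
  sim <- do.call(simulation_config, sim[setdiff(names(sim), "")])
  qc <- do.call(qc_thresholds, x$qc)
  pipeline_config(out_dir = x$out_dir, sim = sim, qc = qc,
                  stages = unlist(x$stages), regress = x$regress,
                  regress_qc_covariates = x$regress_qc_covariates,
                  regress_batch = x$regress_batch,
                  root_age_months = x$root_age_months,
                  q_cutoff = x$q_cutoff, k = x$k,
                  grid_size = x$grid_size, r_min = x$r_min,
                  n_network_genes = x$n_network_genes,
                  score_seed = x$score_seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order, writes every stage's outputs
#' under `config$out_dir`, and finishes with a `manifest.json` recording
#' the package version, seeds and an md5 hash of every output file. The
#' same configuration and seeds produce hash-identical outputs. A stage
#' failure halts the run with the failing stage named; outputs of completed
#' stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param counts a `CountMatrix` to analyze when the simulate stage is
#'   disabled.
#' @return list of in-memory stage results, invisibly; side effect: the run
#'   directory.
#' @export
run_pipeline <- function(config, counts = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(name) message("[scAgeStates] stage: ", name)
  res <- list()
  stage <- "setup"
  tryCatch({
    if (isTRUE(config$stages[["simulate"]])) {
      stage <- "simulate"; on_stage(stage)
      sim <- generate_aging_dataset(config$sim)
      counts <- sim$counts
      res$truth <- sim$truth
      write_count_matrix(counts, file.path(config$out_dir, "counts"))
      utils::write.table(sim$truth$cells,
                         file.path(config$out_dir, "truth_cells.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sim$truth$genes,
                         file.path(config$out_dir, "truth_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_gmt(sim$truth$gene_sets,
                file.path(config$out_dir, "gene_sets.gmt"))
      utils::write.table(sim$truth$phase_genes,
                         file.path(config$out_dir, "phase_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (is.null(counts)) stop("no input: simulate disabled and no counts")
    res$counts <- counts

    if (isTRUE(config$stages[["qc"]])) {
      stage <- "qc"; on_stage(stage)
      counts <- filter_cells_and_genes(counts, config$qc)
      jsonlite::write_json(attr(counts, "qc_log"),
                           file.path(config$out_dir, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA)
      res$filtered <- counts
    }

    stage <- "normalize"; on_stage(stage)
    norm <- normalize_counts(counts)
    if (isTRUE(config$regress)) {
      cov <- data.frame(row.names = counts$cell_meta$barcode)
      # two-pass order: phases are called on unregressed data, then the
      # called phase is regressed out as a factor
      if (!is.null(res$truth)) {
        cc <- call_cell_cycle(counts_to_log2_tpm(counts),
                              res$truth$phase_genes)
        cov$phase <- factor(cc$phase)
        res$cell_cycle <- cc
      }
      if (isTRUE(config$regress_qc_covariates)) {
        totals <- Matrix::colSums(counts$counts)
        cov$ercc_fraction <-
          Matrix::colSums(counts$counts[counts$gene_meta$is_ercc, ,
                                        drop = FALSE]) / totals
        cov$mito_fraction <-
          Matrix::colSums(counts$counts[counts$gene_meta$is_mito, ,
                                        drop = FALSE]) / totals
        cov$n_genes <- Matrix::colSums(counts$counts > 0)
      }
      if (isTRUE(config$regress_batch) &&
          length(unique(counts$cell_meta$batch)) > 1)
        cov$batch <- as.character(counts$cell_meta$batch)
      if (ncol(cov) > 0) {
        res$normalized_raw <- norm
        norm <- regress_covariates(norm, cov)
      }
    }
    res$normalized <- norm
    if (is.null(res$normalized_raw)) res$normalized_raw <- norm

    if (isTRUE(config$stages[["trajectory"]])) {
      stage <- "trajectory"; on_stage(stage)
      root <- if (is.null(config$root_age_months))
        min(norm$cell_meta$age_months) else config$root_age_months
      pt <- infer_pseudotime(norm, root)
      res$pseudotime <- pt
      gt <- test_pseudotime_genes(norm, pt, config$q_cutoff)
      res$gene_test <- gt
    }

    if (isTRUE(config$stages[["states"]])) {
      stage <- "states"; on_stage(stage)
      genes <- res$gene_test$gene[res$gene_test$selected]
      if (length(genes) < config$k)
        stop("only ", length(genes), " pseudotime-dependent genes")
      # curves are smoothed on the unregressed log-normalized values: the
      # log10(x+1) transform presumes non-negative expression
      curves <- smooth_scale_truncate(res$normalized_raw, res$pseudotime,
                                      genes, config$grid_size)
      cl <- cluster_genes(curves, config$k)
      sm <- assign_states(curves, cl, res$pseudotime)
      res$curves <- curves; res$clusters <- cl; res$states <- sm
      utils::write.table(
        data.frame(barcode = names(res$pseudotime$t),
                   t = res$pseudotime$t, state = sm$state),
        file.path(config$out_dir, "pseudotime_states.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(boundaries = sm$boundaries,
                                state_counts = sm$state_counts,
                                labels = sm$labels),
                           file.path(config$out_dir, "states.json"),
                           digits = NA)
      utils::write.table(
        data.frame(gene = names(cl$cluster), cluster = cl$cluster),
        file.path(config$out_dir, "gene_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages[["scores"]]) && !is.null(res$truth)) {
      stage <- "scores"; on_stage(stage)
      pd <- pathway_dynamics(res$normalized_raw, res$pseudotime,
                             res$states, res$truth$gene_sets,
                             grid_size = config$grid_size,
                             seed = config$score_seed)
      res$pathway_dynamics <- pd
      utils::write.table(pd, file.path(config$out_dir,
                                       "pathway_dynamics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sasp <- module_score(res$normalized_raw, res$truth$gene_sets$SASP,
                           seed = config$score_seed)
      res$sasp <- sasp
      utils::write.table(
        data.frame(barcode = norm$cell_meta$barcode,
                   sasp_score = sasp$score),
        file.path(config$out_dir, "sasp_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (isTRUE(config$stages[["entropy"]])) {
      stage <- "entropy"; on_stage(stage)
      raw_norm <- res$normalized_raw
      vars <- apply(raw_norm$values, 1, stats::var)
      top <- order(vars, decreasing = TRUE)[
        seq_len(min(config$n_network_genes, nrow(raw_norm$values)))]
      net <- build_network(raw_norm$values[top, , drop = FALSE],
                           r_min = config$r_min)
      res$network <- net
      ep <- entropy_profile(raw_norm, net)
      res$entropy <- ep
      utils::write.table(ep, file.path(config$out_dir, "entropy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    files <- list.files(config$out_dir, recursive = TRUE,
                        full.names = TRUE)
    files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
    manifest <- list(
      package = "scAgeStates",
      version = as.character(utils::packageVersion("scAgeStates")),
      seeds = list(simulation = config$sim$seed,
                   score = config$score_seed),
      files = lapply(stats::setNames(files,
                                     sub(paste0(config$out_dir, "/?"), "",
                                         files)),
                     function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$manifest <- manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
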