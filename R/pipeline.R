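#' End-to-end expansion-dating analysis
#'
#' Wires the full single-population pipeline: marker filtering, the
#' 10-component observed summary vector, the prior-predictive reference
#' table, rejection with local-linear adjustment, posterior
#' summarization (generations and years), and a posterior predictive
#' check. With `out_dir` set, all stage tables, the resolved
#' configuration and the seed are written next to each other so a run
#' can be reproduced exactly.
#'
#' @param obs observed [microsat_dataset()].
#' @param R reference-table replicates (the empirical-scale choice is
#'   1e5; reduce for desk-scale runs, see [ci_preset()]).
#' @param tolerance accepted fraction (default 0.003).
#' @param priors parameter priors (default [default_expansion_priors()]).
#' @param mm a [mutation_model()].
#' @param transform statistic transform (see [transform_stats()]).
#' @param n_rep_ppc predictive replicates (default 200).
#' @param gen_time generation time in years (default 25).
#' @param max_missing marker-filter threshold (default 0.5).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional output directory for all artifacts.
#' @return List with `filter_report`, `obs_stats`, `reftable`,
#'   `posterior`, `summary`, `ppc`, `config`.
#' @export
run_expansion_analysis <- function(obs, R = 5000, tolerance = 0.003,
                                   priors = default_expansion_priors(),
                                   mm = mutation_model(),
                                   transform = "none", n_rep_ppc = 200,
                                   gen_time = 25, max_missing = 0.5,
                                   seed = 1, out_dir = NULL) {
  flt <- filter_markers(obs, max_missing = max_missing)
  obs_stats <- summary_single(flt$data)
  ref <- build_reference_table("expansion", R = R,
                               n_loci = ncol(flt$data$a1),
                               n_diploid = nrow(flt$data$a1),
                               priors = priors, mm = mm, seed = seed)
  post <- abc_infer(ref, obs_stats, tolerance = tolerance,
                    transform = transform)
  summ <- summarize_posterior(post, gen_time = gen_time,
                              time_params = "t_exp")
  set.seed(seed + 1L)
  ppc <- run_ppc(post, "expansion", obs_stats, n_rep = n_rep_ppc,
                 n_loci = ncol(flt$data$a1), n_diploid = nrow(flt$data$a1),
                 mm = mm, priors = priors)
  config <- list(analysis = "expansion", R = R, tolerance = tolerance,
                 transform = transform, n_rep_ppc = n_rep_ppc,
                 gen_time = gen_time, max_missing = max_missing,
                 seed = seed, n_loci = ncol(flt$data$a1),
                 n_diploid = nrow(flt$data$a1),
                 priors = lapply(priors, unclass), mm = unclass(mm))
  res <- list(filter_report = flt$report, obs_stats = obs_stats,
              reftable = ref, posterior = post, summary = summ,
              ppc = ppc, config = config)
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

#' End-to-end divergence-topology analysis
#'
#' Builds one reference table per topology (ESW, SEW, WES, STAR) for the
#' three-population observed data, compares the models by acceptance
#' counts over a tolerance grid, fits the per-model posteriors for the
#' split times, and runs a posterior predictive check for the
#' best-supported model.
#'
#' @param obs observed [microsat_dataset()] with the three populations.
#' @param pops the three population labels in (east, south, west) order.
#' @param R_per_model reference replicates per topology.
#' @param tolerance model-choice and inference tolerance (fraction of
#'   the pooled table for model choice, of the per-model table for
#'   inference).
#' @param tolerance_grid additional tolerances for the acceptance-count
#'   curves.
#' @param models topologies to compare.
#' @param priors optional named list of per-model prior lists.
#' @param fixed fixed settings (`n0` present sizes, `M`).
#' @param mm a [mutation_model()].
#' @param transform statistic transform.
#' @param n_rep_ppc predictive replicates for the best model.
#' @param gen_time generation time in years.
#' @param max_missing marker-filter threshold.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return List with `comparison`, `best_model`, `posteriors` (per
#'   model), `summaries` (per model, split times also in years), `ppc`
#'   (best model), `obs_stats`, `config`.
#' @export
run_topology_analysis <- function(obs, pops = levels(obs$pop),
                                  R_per_model = 1250, tolerance = 0.01,
                                  tolerance_grid = NULL,
                                  models = c("ESW", "SEW", "WES", "STAR"),
                                  priors = NULL, fixed = list(),
                                  mm = mutation_model(),
                                  transform = "none", n_rep_ppc = 200,
                                  gen_time = 25, max_missing = 0.5,
                                  seed = 1, out_dir = NULL) {
  flt <- filter_markers(obs, max_missing = max_missing)
  obs_stats <- summary_threepop(flt$data, pops = pops)
  n_dip <- as.integer(table(flt$data$pop)[pops])
  n_loci <- ncol(flt$data$a1)
  refs <- vector("list", length(models))
  for (i in seq_along(models)) {
    refs[[i]] <- build_reference_table(models[i], R = R_per_model,
                                       n_loci = n_loci, n_diploid = n_dip,
                                       priors = priors[[models[i]]],
                                       mm = mm, fixed = fixed,
                                       seed = seed + i)
  }
  names(refs) <- models
  obs_vec <- setNames(as.numeric(obs_stats), colnames(refs[[1]]$stats))
  pooled <- do.call(bind_reftables, refs)
  grid <- sort(unique(c(tolerance, tolerance_grid)))
  comp <- compare_models(pooled, obs_vec, tolerances = grid,
                         transform = transform)
  at <- which(grid == tolerance)
  best <- models[which.max(comp$counts[at, models])]
  posteriors <- lapply(refs, function(r)
    abc_infer(r, obs_vec, tolerance = tolerance, transform = transform))
  summaries <- lapply(posteriors, function(p)
    summarize_posterior(p, gen_time = gen_time,
                        time_params = c("t1", "delta_t")))
  set.seed(seed + 101L)
  ppc <- run_ppc(posteriors[[best]], best, obs_vec, n_rep = n_rep_ppc,
                 n_loci = n_loci, n_diploid = n_dip, mm = mm, fixed = fixed)
  config <- list(analysis = "topology", models = models,
                 R_per_model = R_per_model, tolerance = tolerance,
                 tolerance_grid = grid, transform = transform,
                 n_rep_ppc = n_rep_ppc, gen_time = gen_time,
                 max_missing = max_missing, seed = seed,
                 n_loci = n_loci, n_diploid = n_dip, pops = pops,
                 fixed = fixed, mm = unclass(mm))
  res <- list(comparison = comp, best_model = best,
              posteriors = posteriors, summaries = summaries, ppc = ppc,
              obs_stats = obs_vec, config = config)
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# write every stage table + resolved config of a pipeline result
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = res$config)
  jsonlite::write_json(res$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_result_table(as.data.frame(t(res$obs_stats)),
                     file.path(out_dir, "observed_stats.tsv"), meta)
  if (!is.null(res$posterior)) {
    write_result_table(cbind(res$posterior$adjusted %||% res$posterior$params,
                             weight = res$posterior$weights),
                       file.path(out_dir, "posterior.tsv"), meta)
    write_result_table(res$summary, file.path(out_dir, "summary.tsv"), meta)
    write_result_table(res$ppc$envelope,
                       file.path(out_dir, "ppc_envelope.tsv"), meta)
  }
  if (!is.null(res$comparison)) {
    write_result_table(cbind(tolerance = res$comparison$tolerances,
                             res$comparison$counts),
                       file.path(out_dir, "model_counts.tsv"), meta)
    for (m in names(res$posteriors)) {
      write_result_table(res$summaries[[m]],
                         file.path(out_dir, paste0("summary_", m, ".tsv")),
                         meta)
    }
    write_result_table(res$ppc$envelope,
                       file.path(out_dir, "ppc_envelope_best.tsv"), meta)
  }
  invisible(out_dir)
}
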