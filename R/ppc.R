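#' Posterior predictive check
#'
#' Resamples parameter vectors from the (weighted, adjusted) posterior,
#' re-simulates `n_rep` datasets of the same shape as the observed one,
#' recomputes the summary vectors, and compares the observed vector to
#' the marginal 95% envelopes (2.5%/97.5% percentiles per statistic) and
#' to a two-dimensional PCA summary of the simulated statistics.
#'
#' Draws outside a parameter's physical range (a regression adjustment
#' can push e.g. a time slightly negative) are clamped to the prior
#' support before simulation.
#'
#' @param post an `abc_posterior`.
#' @param model model label (`"expansion"` or a topology), matching the
#'   posterior.
#' @param obs observed summary vector.
#' @param n_rep number of predictive replicates (>= 40).
#' @param n_loci,n_diploid shape of each replicate dataset.
#' @param mm a [mutation_model()].
#' @param fixed fixed settings for three-population models (see
#'   [build_reference_table()]).
#' @param priors priors used for support clamping (defaults per model).
#' @return An object of class `ppc_result`: `envelope` (per-statistic
#'   lower/upper/observed/inside), `sim_stats`, `pca` (loadings,
#'   simulated scores, observed score), `n_rep`.
#' @export
run_ppc <- function(post, model, obs, n_rep = 1000, n_loci, n_diploid,
                    mm = mutation_model(), fixed = list(), priors = NULL) {
  if (n_rep < 40) stop("n_rep < 40: envelope would be unreliable")
  draws <- post$adjusted %||% post$params
  if (nrow(draws) == 0) stop("empty posterior")
  if (is.null(priors)) {
    priors <- if (model == "expansion") default_expansion_priors()
              else default_threepop_priors(model)
  }
  for (nm in colnames(draws)) {
    p <- priors[[nm]]
    if (!is.null(p)) draws[, nm] <- pmin(pmax(draws[, nm], p$min), p$max)
  }
  idx <- sample.int(nrow(draws), n_rep, replace = TRUE,
                    prob = post$weights / sum(post$weights))
  expansion <- model == "expansion"
  n_dip <- as.integer(rep_len(n_diploid, if (expansion) 1L else 3L))
  group <- rep(0:(length(n_dip) - 1L), times = 2L * n_dip)
  sim <- matrix(NA_real_, n_rep, length(obs),
                dimnames = list(NULL, names(obs)))
  for (r in seq_len(n_rep)) {
    dem <- make_demography(model, draws[idx[r], ], fixed)
    hap <- sim_hap_matrix(dem, n_dip, n_loci, mm)
    sim[r, ] <- if (expansion) hap_summary_single(hap)
                else hap_summary_threepop(hap, group)
  }
  lo <- apply(sim, 2, quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(sim, 2, quantile, probs = 0.975, na.rm = TRUE)
  envelope <- data.frame(statistic = names(obs), lower = lo, upper = hi,
                         observed = as.numeric(obs),
                         inside = obs >= lo & obs <= hi,
                         row.names = NULL)
  structure(list(envelope = envelope, sim_stats = sim,
                 pca = pca_summarize(sim, obs), n_rep = n_rep),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  n_in <- sum(x$envelope$inside)
  cat(sprintf("ppc_result: %d/%d statistics inside the 95%% envelope (%d replicates)\n",
              n_in, nrow(x$envelope), x$n_rep))
  if (n_in < nrow(x$envelope))
    cat("outside:", paste(x$envelope$statistic[!x$envelope$inside],
                          collapse = ", "), "\n")
  cat(sprintf("observed PCA score: (%.3f, %.3f)\n",
              x$pca$obs_scores[1], x$pca$obs_scores[2]))
  invisible(x)
}

#' Two-dimensional PCA summary of summary statistics
#'
#' Centers and unit-scales the statistics using the simulated moments,
#' extracts the top two principal components, and projects the observed
#' vector with the same centering/scaling. Constant columns are dropped.
#' If the simulated matrix has rank 1 only one component is returned.
#'
#' @param sim matrix of simulated summary vectors (>= 3 rows).
#' @param obs observed summary vector.
#' @return List with `loadings`, `sim_scores`, `obs_scores`,
#'   `var_explained`.
#' @export
pca_summarize <- function(sim, obs) {
  if (nrow(sim) < 3) stop("need at least 3 simulated vectors")
  keep <- apply(sim, 2, function(x) sd(x, na.rm = TRUE) > 0)
  sim <- sim[, keep, drop = FALSE]; obs <- obs[keep]
  pc <- prcomp(sim, center = TRUE, scale. = TRUE)
  k <- min(2L, sum(pc$sdev > 1e-12))
  obs_sc <- (obs - pc$center) / pc$scale
  list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
       sim_scores = pc$x[, seq_len(k), drop = FALSE],
       obs_scores = as.numeric(obs_sc %*% pc$rotation[, seq_len(k)]),
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
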