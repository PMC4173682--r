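#' Prior specifications
#'
#' Per-parameter prior distributions for the prior-predictive reference
#' table: uniform or log-uniform on a finite interval.
#'
#' @param min,max finite bounds, `min < max` (both > 0 for the
#'   log-uniform).
#' @return A one-parameter prior object (class `prior`).
#' @export
prior_uniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), min < max)
  structure(list(dist = "uniform", min = min, max = max), class = "prior")
}

#' @rdname prior_uniform
#' @export
prior_loguniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), 0 < min, min < max)
  structure(list(dist = "loguniform", min = min, max = max), class = "prior")
}

#' Default priors for the single-population expansion model
#'
#' `t_exp ~ U(40, 1000)` generations, `np ~ U(500, 10000)`,
#' `n0 ~ logU(1e3, 1e5)` (present size, a nuisance parameter). These
#' defaults are this package's choices, documented in the methods
#' vignette; adjust freely via the `priors` argument of
#' [build_reference_table()].
#'
#' @return Named list of [prior_uniform()]/[prior_loguniform()] objects.
#' @export
default_expansion_priors <- function() {
  list(t_exp = prior_uniform(40, 1000),
       np = prior_uniform(500, 10000),
       n0 = prior_loguniform(1e3, 1e5))
}

#' Default priors for the three-population divergence models
#'
#' `t1 ~ U(40, 400)` generations, `delta_t ~ U(0, 400)` (dropped for
#' STAR), per-population growth rates `~ U(0, 0.05)` per generation and
#' ancestral sizes `~ U(500, 10000)` (`n_anc2` dropped for STAR).
#' Present population sizes and the migration rate `M` are fixed, not
#' inferred (see [build_reference_table()]'s `fixed` argument).
#'
#' @param topology one of `"ESW"`, `"SEW"`, `"WES"`, `"STAR"`.
#' @return Named list of priors.
#' @export
default_threepop_priors <- function(topology = "ESW") {
  pr <- list(t1 = prior_uniform(40, 400),
             delta_t = prior_uniform(0, 400),
             alpha_east = prior_uniform(0, 0.05),
             alpha_south = prior_uniform(0, 0.05),
             alpha_west = prior_uniform(0, 0.05),
             n_anc1 = prior_uniform(500, 10000),
             n_anc2 = prior_uniform(500, 10000))
  if (topology == "STAR") pr[c("delta_t", "n_anc2")] <- NULL
  pr
}

#' Draw parameter vectors from a prior specification
#'
#' @param priors named list of priors.
#' @param n number of draws.
#' @return `n` x `length(priors)` matrix with parameter names.
#' @export
sample_priors <- function(priors, n) {
  draws <- vapply(priors, function(p) {
    switch(p$dist,
           uniform = runif(n, p$min, p$max),
           loguniform = exp(runif(n, log(p$min), log(p$max))),
           stop("unknown prior family: ", p$dist))
  }, numeric(n))
  matrix(draws, nrow = n, dimnames = list(NULL, names(priors)))
}

# parameter vector -> demography for each supported model
make_demography <- function(model, par, fixed = list()) {
  if (model == "expansion") {
    expansion_demography(t_exp = par[["t_exp"]], np = par[["np"]],
                         n0 = par[["n0"]])
  } else {
    n0 <- fixed$n0 %||% c(east = 1e4, south = 1e4, west = 1e4)
    M <- fixed$M %||% 1500
    threepop_demography(topology = model,
                        t1 = par[["t1"]],
                        delta_t = if (model == "STAR") 0 else par[["delta_t"]],
                        n0 = n0,
                        alpha = c(par[["alpha_east"]], par[["alpha_south"]],
                                  par[["alpha_west"]]),
                        n_anc1 = par[["n_anc1"]],
                        n_anc2 = if (model == "STAR") 1e4 else par[["n_anc2"]],
                        M = M)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a prior-predictive reference table
#'
#' Draws `R` parameter vectors from the priors, simulates a multi-locus
#' dataset for each under the named model, and records the corresponding
#' summary vector (10 components for `"expansion"`, 18 for the
#' three-population topologies). Seeded and reproducible.
#'
#' @param model `"expansion"`, `"ESW"`, `"SEW"`, `"WES"` or `"STAR"`.
#' @param R number of replicate simulations.
#' @param n_loci loci per simulated dataset.
#' @param n_diploid diploid sample size (single number for expansion,
#'   `c(east, south, west)` otherwise).
#' @param priors named list of priors (defaults per model).
#' @param mm a [mutation_model()].
#' @param fixed fixed (non-inferred) settings for the three-population
#'   models: `n0` (present sizes, default 1e4 each) and `M` (scaled
#'   migration, default 1500).
#' @param seed optional integer seed (applied via `set.seed`).
#' @return An object of class `abc_reftable`: list with `model`
#'   (character vector, one label per row), `params` (R x p matrix),
#'   `stats` (R x S matrix), and the generating configuration.
#' @export
build_reference_table <- function(model, R, n_loci, n_diploid,
                                  priors = NULL, mm = mutation_model(),
                                  fixed = list(), seed = NULL) {
  stopifnot(R >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(priors)) {
    priors <- if (model == "expansion") default_expansion_priors()
              else default_threepop_priors(model)
  }
  params <- sample_priors(priors, R)
  expansion <- model == "expansion"
  n_dip <- as.integer(rep_len(n_diploid, if (expansion) 1L else 3L))
  group <- rep(0:(length(n_dip) - 1L), times = 2L * n_dip)
  stats <- NULL
  for (r in seq_len(R)) {
    dem <- make_demography(model, params[r, ], fixed)
    hap <- sim_hap_matrix(dem, n_dip, n_loci, mm)
    sv <- if (expansion) hap_summary_single(hap)
          else hap_summary_threepop(hap, group)
    if (is.null(stats))
      stats <- matrix(NA_real_, R, length(sv), dimnames = list(NULL, names(sv)))
    stats[r, ] <- sv
  }
  structure(list(model = rep(model, R), params = params, stats = stats,
                 config = list(n_loci = n_loci, n_diploid = n_dip,
                               priors = priors, mm = mm, fixed = fixed,
                               seed = seed)),
            class = "abc_reftable")
}

#' Combine per-model reference tables for model choice
#'
#' @param ... `abc_reftable` objects with identical summary-statistic
#'   columns.
#' @return A pooled `abc_reftable`; `params` becomes a list of per-model
#'   matrices (parameter spaces may differ between models).
#' @export
bind_reftables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 2)
  cols <- colnames(tabs[[1]]$stats)
  for (tb in tabs) {
    if (!identical(colnames(tb$stats), cols))
      stop("summary-statistic columns differ between tables")
  }
  structure(list(model = unlist(lapply(tabs, `[[`, "model")),
                 params = setNames(lapply(tabs, `[[`, "params"),
                                   vapply(tabs, function(t) t$model[1], "")),
                 stats = do.call(rbind, lapply(tabs, `[[`, "stats")),
                 config = tabs[[1]]$config),
            class = "abc_reftable")
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat("abc_reftable:", length(x$model), "rows,",
      ncol(x$stats), "summary statistics; models:",
      paste(unique(x$model), collapse = ", "), "\n")
  invisible(x)
}

#' Standardize summary statistics for the Euclidean distance
#'
#' Divides each statistic by its spread across the reference table
#' (default: median absolute deviation), computed once from the
#' simulated table and applied identically to the observed vector.
#' Zero-spread statistics are dropped with a warning. After scaling,
#' every retained column has MAD 1, so rescaling is idempotent.
#'
#' @param sim R x S matrix of simulated statistics.
#' @param obs observed statistic vector (length S).
#' @return List with `sim`, `obs` (scaled, possibly fewer columns),
#'   `scale` (the divisors) and `kept` (logical per original column).
#' @export
standardize_stats <- function(sim, obs) {
  sc <- apply(sim, 2, mad, na.rm = TRUE)
  kept <- is.finite(sc) & sc > 0
  if (!any(kept)) stop("all statistics have zero spread")
  if (!all(kept))
    warning("dropping zero-spread statistics: ",
            paste(colnames(sim)[!kept], collapse = ", "))
  list(sim = sweep(sim[, kept, drop = FALSE], 2, sc[kept], "/"),
       obs = obs[kept] / sc[kept], scale = sc[kept], kept = kept)
}

#' Transform summary statistics before regression adjustment
#'
#' Monotone per-statistic transforms applied identically to simulated
#' and observed vectors. `"log1p"` shifts a column to be non-negative
#' first if needed; `"boxcox"` estimates each column's lambda by direct
#' normal profile likelihood (on a positivity-shifted column) and falls
#' back to `"none"` with a warning if a column is degenerate.
#'
#' @param sim R x S matrix of simulated statistics.
#' @param obs observed vector.
#' @param method `"none"`, `"log1p"` or `"boxcox"`.
#' @return List with `sim`, `obs`, `method` and per-column transform
#'   parameters (`shift`, `lambda`).
#' @export
transform_stats <- function(sim, obs, method = c("none", "log1p", "boxcox")) {
  method <- match.arg(method)
  if (method == "none")
    return(list(sim = sim, obs = obs, method = method,
                shift = rep(0, ncol(sim)), lambda = NULL))
  shift <- pmax(0, -apply(sim, 2, min, na.rm = TRUE))
  if (method == "log1p") {
    sim2 <- log1p(sweep(sim, 2, shift, "+"))
    obs2 <- log1p(obs + shift)
    return(list(sim = sim2, obs = obs2, method = method, shift = shift,
                lambda = NULL))
  }
  # box-cox: shift columns strictly positive, profile lambda per column
  cmin <- apply(sim, 2, min, na.rm = TRUE)
  shift <- ifelse(cmin <= 0, -cmin + 1e-6, 0)
  bc <- function(x, lam) if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
  lambda <- numeric(ncol(sim))
  sim2 <- sim
  for (j in seq_len(ncol(sim))) {
    x <- sim[, j] + shift[j]
    if (sd(x, na.rm = TRUE) == 0) {
      warning("degenerate column, box-cox skipped: ", colnames(sim)[j])
      lambda[j] <- 1
      next
    }
    ll <- function(lam) {
      y <- bc(x, lam)
      -length(y) / 2 * log(var(y, na.rm = TRUE) + 1e-300) +
        (lam - 1) * sum(log(x), na.rm = TRUE)
    }
    lambda[j] <- optimize(ll, c(-2, 3), maximum = TRUE)$maximum
    sim2[, j] <- bc(x, lambda[j])
  }
  obs2 <- vapply(seq_along(obs),
                 function(j) bc(obs[j] + shift[j], lambda[j]), 0)
  names(obs2) <- names(obs)
  list(sim = sim2, obs = obs2, method = method, shift = shift,
       lambda = lambda)
}

#' Rejection step: indices of the accepted simulations
#'
#' Accepts exactly `floor(tolerance * R)` rows with the smallest
#' distances; ties at the boundary are broken deterministically by row
#' index.
#'
#' @param distances per-row distances to the observed vector.
#' @param tolerance accepted fraction, in (0, 1].
#' @return Integer vector of accepted row indices (in increasing
#'   distance order).
#' @export
reject_indices <- function(distances, tolerance) {
  stopifnot(tolerance > 0, tolerance <= 1)
  n_acc <- floor(tolerance * length(distances))
  if (n_acc < 1) stop("tolerance * R < 1: nothing would be accepted")
  order(distances, seq_along(distances))[seq_len(n_acc)]
}

euclidean_distances <- function(sim, obs) {
  sqrt(rowSums(sweep(sim, 2, obs, "-")^2))
}

#' Local-linear regression adjustment of accepted parameters
#'
#' Weighted least squares of each accepted parameter on the deviation of
#' its summary vector from the observed one, with Epanechnikov kernel
#' weights `1 - (d / d_max)^2`; the adjusted draws are the fitted value
#' at the observed statistics plus the residuals. Parameters with
#' strictly positive support can be regressed on the log scale and
#' back-transformed (`param_log`). A singular design falls back to the
#' unadjusted draws with a warning.
#'
#' @param params accepted-draw parameter matrix (rows = draws).
#' @param stats accepted-draw statistic matrix (same transformation and
#'   scaling as `obs`).
#' @param obs observed (scaled) statistic vector.
#' @param distances accepted-draw distances used for the kernel.
#' @param param_log logical per parameter column: regress on log scale.
#' @return List with `adjusted` (matrix like `params`), `weights`, and
#'   `coefficients` (per-parameter regression coefficients).
#' @export
loclinear_adjust <- function(params, stats, obs, distances,
                             param_log = NULL) {
  params <- as.matrix(params); stats <- as.matrix(stats)
  if (nrow(params) <= ncol(stats) + 1)
    stop("need more accepted draws than statistics + 1")
  if (is.null(param_log)) param_log <- rep(FALSE, ncol(params))
  dmax <- max(distances)
  w <- if (dmax > 0) 1 - (distances / dmax)^2 else rep(1, length(distances))
  # keep the boundary draw from being zero-weighted into oblivion
  w <- pmax(w, 1e-12)
  X <- cbind(1, sweep(stats, 2, obs, "-"))
  adjusted <- params
  coefs <- vector("list", ncol(params))
  for (j in seq_len(ncol(params))) {
    y <- params[, j]
    if (param_log[j]) {
      if (any(y <= 0)) {
        warning("non-positive values; log-scale adjustment skipped for ",
                colnames(params)[j])
        next
      }
      y <- log(y)
    }
    fit <- lm.wfit(x = X, y = y, w = w)
    if (any(is.na(fit$coefficients))) {
      warning("singular regression design; returning unadjusted draws for ",
              colnames(params)[j] %||% j)
      coefs[[j]] <- fit$coefficients
      next
    }
    adj <- fit$coefficients[1] + fit$residuals
    adjusted[, j] <- if (param_log[j]) exp(adj) else adj
    coefs[[j]] <- fit$coefficients
  }
  names(coefs) <- colnames(params)
  list(adjusted = adjusted, weights = w, coefficients = coefs)
}

#' ABC inference: rejection plus optional regression adjustment
#'
#' Computes Euclidean distances between the observed summary vector and
#' every reference-table row (after optional transformation and
#' MAD-standardization, both derived from the reference table), accepts
#' the `tolerance` fraction with the smallest distances, and applies the
#' local-linear adjustment.
#'
#' @param ref an `abc_reftable` (single model).
#' @param obs observed summary vector (same statistics as `ref$stats`).
#' @param tolerance accepted fraction (default 0.003, i.e. 0.3%).
#' @param transform statistic transform before the distance/regression
#'   (see [transform_stats()]).
#' @param standardize divide statistics by their reference-table MAD.
#' @param adjust apply [loclinear_adjust()].
#' @param param_log per-parameter log-scale flags for the adjustment;
#'   default: `TRUE` for parameters with strictly positive prior support.
#' @return An object of class `abc_posterior`: accepted indices, raw and
#'   adjusted parameter draws, Epanechnikov weights, distances, and the
#'   scaling metadata.
#' @export
abc_infer <- function(ref, obs, tolerance = 0.003,
                      transform = "none", standardize = TRUE,
                      adjust = TRUE, param_log = NULL) {
  if (length(unique(ref$model)) != 1)
    stop("abc_infer expects a single-model reference table; see compare_models")
  stats <- ref$stats
  ok <- complete.cases(stats)
  if (!all(ok)) { stats <- stats[ok, , drop = FALSE] }
  params <- ref$params[ok, , drop = FALSE]
  tr <- transform_stats(stats, obs, method = transform)
  if (standardize) {
    sc <- standardize_stats(tr$sim, tr$obs)
  } else {
    sc <- list(sim = tr$sim, obs = tr$obs, scale = rep(1, ncol(tr$sim)),
               kept = rep(TRUE, ncol(tr$sim)))
  }
  d <- euclidean_distances(sc$sim, sc$obs)
  acc <- reject_indices(d, tolerance)
  if (is.null(param_log)) {
    pr <- ref$config$priors
    param_log <- vapply(colnames(params), function(nm) {
      p <- pr[[nm]]
      !is.null(p) && p$min > 0
    }, TRUE)
  }
  post <- list(accepted = acc, params = params[acc, , drop = FALSE],
               adjusted = NULL, weights = rep(1, length(acc)),
               distances = d[acc], obs = obs, tolerance = tolerance,
               model = ref$model[1], transform = transform,
               scale = sc$scale, param_log = param_log)
  if (adjust) {
    la <- loclinear_adjust(post$params, sc$sim[acc, , drop = FALSE],
                           sc$obs, post$distances, param_log = param_log)
    post$adjusted <- la$adjusted
    post$weights <- la$weights
    post$coefficients <- la$coefficients
  }
  structure(post, class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("abc_posterior [%s]: %d accepted draws (tolerance %.4g)%s\n",
              x$model, length(x$accepted), x$tolerance,
              if (is.null(x$adjusted)) ", rejection only"
              else ", regression-adjusted"))
  invisible(x)
}

#' Weighted quantile by linear interpolation of the weighted CDF
#'
#' @param x numeric values.
#' @param w non-negative weights.
#' @param probs probabilities.
#' @return Quantiles at `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    approx(cw, x, xout = p, ties = "ordered")$y
  }, 0)
}

#' Summarize an ABC posterior
#'
#' Weighted posterior mean and 2.5%/97.5% quantiles per parameter, using
#' the regression-adjusted draws when present. Parameters named in
#' `time_params` (generations) are additionally reported in years using
#' the generation time.
#'
#' @param post an `abc_posterior`.
#' @param gen_time generation time in years (default 25).
#' @param time_params names of parameters measured in generations.
#' @return Data frame with columns `parameter`, `mean`, `q025`, `q975`,
#'   `unit`.
#' @export
summarize_posterior <- function(post, gen_time = 25,
                                time_params = intersect(
                                  c("t_exp", "t1", "delta_t", "t2"),
                                  colnames(post$params))) {
  draws <- post$adjusted %||% post$params
  if (nrow(draws) == 0) stop("empty posterior")
  w <- post$weights
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    q <- weighted_quantile(x, w, c(0.025, 0.975))
    out <- data.frame(parameter = nm, mean = weighted.mean(x, w),
                      q025 = q[1], q975 = q[2], unit = "model units")
    if (nm %in% time_params) {
      out$unit <- "generations"
      out <- rbind(out,
                   data.frame(parameter = paste0(nm, "_years"),
                              mean = out$mean * gen_time,
                              q025 = out$q025 * gen_time,
                              q975 = out$q975 * gen_time,
                              unit = "years"))
    }
    out
  })
  do.call(rbind, rows)
}

#' Model choice by acceptance counts over a tolerance grid
#'
#' Pools the per-model reference tables, computes one set of distances
#' to the observed vector (shared transformation and scaling derived
#' from the pooled table), and reports how many accepted simulations at
#' each tolerance come from each model. Ratios of per-model acceptance
#' counts approximate Bayes factors when the per-model prior
#' probabilities (here: equal `R`) are equal.
#'
#' @param ref pooled `abc_reftable` (from [bind_reftables()]).
#' @param obs observed summary vector.
#' @param tolerances tolerance grid (fractions of pooled rows).
#' @param transform,standardize as in [abc_infer()].
#' @return Class `abc_model_comparison`: `counts` (tolerance x model
#'   matrix), `ratios` (pairwise count-ratio matrix at the smallest
#'   tolerance), `tolerances`, `models`.
#' @export
compare_models <- function(ref, obs, tolerances = 0.003,
                           transform = "none", standardize = TRUE) {
  models <- unique(ref$model)
  if (length(models) < 2) stop("need at least two models")
  per_R <- table(ref$model)
  if (length(unique(per_R)) != 1)
    stop("unequal per-model replicate counts; equal R per model required")
  tr <- transform_stats(ref$stats, obs, method = transform)
  sc <- if (standardize) standardize_stats(tr$sim, tr$obs)
        else list(sim = tr$sim, obs = tr$obs)
  d <- euclidean_distances(sc$sim, sc$obs)
  counts <- matrix(0L, length(tolerances), length(models),
                   dimnames = list(NULL, models))
  for (i in seq_along(tolerances)) {
    acc <- reject_indices(d, tolerances[i])
    tab <- table(factor(ref$model[acc], levels = models))
    counts[i, ] <- as.integer(tab)
  }
  cnt <- counts[which.min(tolerances), ]
  ratios <- outer(cnt, cnt, function(a, b) ifelse(b > 0, a / b, Inf))
  structure(list(counts = counts, tolerances = tolerances,
                 models = models, ratios = ratios),
            class = "abc_model_comparison")
}

#' @export
print.abc_model_comparison <- function(x, ...) {
  i <- which.min(x$tolerances)
  cat("abc_model_comparison at tolerance", x$tolerances[i], "\n")
  print(x$counts[i, ])
  best <- x$models[which.max(x$counts[i, ])]
  others <- setdiff(x$models, best)
  bf <- x$ratios[best, others]
  cat("best model:", best, "| acceptance ratios vs",
      paste(others, collapse = "/"), "=",
      paste(sprintf("%.2f", bf), collapse = "/"), "\n")
  invisible(x)
}
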