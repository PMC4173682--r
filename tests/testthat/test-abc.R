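test_that("rejection accepts exactly floor(tolerance * R) smallest distances", {
  d <- c(5, 1, 9, 2, 3, 8, 7, 10, 4, 6)
  expect_equal(reject_indices(d, 0.3), c(2L, 4L, 5L))
  # deterministic tie-break by row index
  dt <- c(2, 1, 1, 1, 5)
  expect_equal(reject_indices(dt, 0.4), c(2L, 3L))
  # zero-distance observed row is accepted
  dd <- c(0.5, 0, 0.7, 0.9)
  expect_true(2L %in% reject_indices(dd, 0.25))
  expect_error(reject_indices(runif(10), 0.05), "nothing")
  set.seed(31)
  for (R in c(100, 1234, 5000)) {
    expect_length(reject_indices(runif(R), 0.01), floor(0.01 * R))
  }
})

test_that("standardization scales to unit MAD, drops constants, and is idempotent", {
  set.seed(32)
  sim <- cbind(a = rnorm(500, 10, 3), b = runif(500), c = rep(4, 500))
  obs <- c(a = 10, b = 0.5, c = 4)
  expect_warning(sc <- standardize_stats(sim, obs), "zero-spread")
  expect_equal(colnames(sc$sim), c("a", "b"))
  expect_equal(apply(sc$sim, 2, mad), c(a = 1, b = 1), tolerance = 1e-12)
  sc2 <- standardize_stats(sc$sim, sc$obs)
  expect_equal(sc2$sim, sc$sim, tolerance = 1e-12)
  expect_equal(sc2$scale, c(a = 1, b = 1), tolerance = 1e-12)
  expect_error(standardize_stats(cbind(rep(1, 10)), 1), "zero spread")
})

test_that("statistic transforms are monotone and reduce lognormal skewness", {
  set.seed(33)
  sim <- cbind(x = exp(rnorm(2000)), y = rnorm(2000))
  obs <- c(x = 1, y = 0)
  tr0 <- transform_stats(sim, obs, method = "none")
  expect_identical(tr0$sim, sim)
  tr1 <- transform_stats(cbind(x = c(0, 1, 2)), c(x = 0), method = "log1p")
  expect_equal(tr1$obs, c(x = 0))
  expect_equal(tr1$sim[, 1], log1p(c(0, 1, 2)))
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  tr2 <- transform_stats(sim, obs, method = "boxcox")
  expect_lt(abs(skew(tr2$sim[, "x"])), 0.2)
  expect_lt(abs(skew(tr2$sim[, "x"])), abs(skew(sim[, "x"])))
  # monotone per column
  expect_equal(order(tr2$sim[1:50, "x"]), order(sim[1:50, "x"]))
})

test_that("local-linear adjustment is exact on noiseless linear data", {
  set.seed(34)
  R <- 200
  stats <- cbind(s1 = runif(R), s2 = runif(R))
  params <- cbind(p = 2 + 3 * stats[, 1] - 1.5 * stats[, 2])
  obs <- c(s1 = 0.4, s2 = 0.6)
  d <- sqrt(rowSums(sweep(stats, 2, obs)^2))
  la <- loclinear_adjust(params, stats, obs, d)
  expect_equal(unname(la$adjusted[, 1]),
               rep(2 + 3 * 0.4 - 1.5 * 0.6, R), tolerance = 1e-10)
  # constant parameter: adjusted equals the constant
  la2 <- loclinear_adjust(cbind(p = rep(7, R)), stats, obs, d)
  expect_equal(unname(la2$adjusted[, 1]), rep(7, R), tolerance = 1e-10)
})

test_that("weighted least squares matches an lm oracle in one dimension", {
  set.seed(35)
  n <- 80
  x <- runif(n); y <- 1 + 2 * x + rnorm(n, 0, 0.1)
  obs <- 0.5
  d <- abs(x - obs)
  la <- loclinear_adjust(cbind(p = y), cbind(s = x), c(s = obs), d)
  w <- 1 - (d / max(d))^2
  fit <- lm(y ~ I(x - obs), weights = pmax(w, 1e-12))
  expect_equal(unname(la$adjusted[, 1]),
               unname(coef(fit)[1] + resid(fit)), tolerance = 1e-8)
  expect_equal(unname(la$weights), unname(pmax(w, 1e-12)), tolerance = 1e-12)
})

test_that("posterior summaries convert generations to years at 25 y/gen", {
  post <- structure(list(params = cbind(t_exp = rep(225.84, 50)),
                         adjusted = cbind(t_exp = rep(225.84, 50)),
                         weights = rep(1, 50)),
                    class = "abc_posterior")
  s <- summarize_posterior(post, gen_time = 25, time_params = "t_exp")
  expect_equal(s$mean[s$parameter == "t_exp_years"], 5646)
  expect_equal(s$unit[s$parameter == "t_exp_years"], "years")
  # equal-weight draws 1..100 -> mean 50.5
  post2 <- structure(list(params = cbind(x = 1:100), adjusted = NULL,
                          weights = rep(1, 100)),
                     class = "abc_posterior")
  s2 <- summarize_posterior(post2, time_params = character())
  expect_equal(s2$mean, 50.5)
  expect_lte(s2$q025, s2$q975)
  expect_equal(s2$q025, 3, tolerance = 0.5)
})

test_that("weighted quantiles interpolate the weighted CDF", {
  x <- c(1, 2, 3, 4)
  expect_equal(weighted_quantile(x, rep(1, 4), 0.5), 2.5)
  # weight concentrated on one value pins the quantile there
  expect_equal(weighted_quantile(x, c(0.001, 100, 0.001, 0.001), 0.5), 2,
               tolerance = 0.01)
})

test_that("abc_infer accepts the configured fraction and reduces toward the prior at tolerance 1", {
  set.seed(36)
  R <- 2000
  params <- cbind(theta = runif(R, 0, 10))
  stats <- cbind(s = params[, 1] + rnorm(R, 0, 0.5))
  ref <- structure(list(model = rep("toy", R), params = params, stats = stats,
                        config = list(priors = list(theta = prior_uniform(0, 10)))),
                   class = "abc_reftable")
  obs <- c(s = 3)
  post <- abc_infer(ref, obs, tolerance = 0.05)
  expect_length(post$accepted, 100L)
  expect_s3_class(post, "abc_posterior")
  expect_true(abs(summarize_posterior(post, time_params = character())$mean - 3) < 1)
  # rejection-only posterior at tolerance 1 reproduces the prior
  post1 <- abc_infer(ref, obs, tolerance = 1, adjust = FALSE)
  expect_equal(mean(post1$params[, 1]), mean(params[, 1]))
})

test_that("regression adjustment beats plain rejection on a linear-Gaussian toy", {
  # an off-center truth with a wide tolerance: plain rejection is pulled
  # toward the prior mean, the local-linear correction recenters it
  set.seed(37)
  better <- 0L
  for (rep in 1:50) {
    R <- 400
    theta <- runif(R, 0, 10)
    stats <- cbind(s = theta + rnorm(R, 0, 1))
    truth <- 8.5
    obs <- c(s = truth + rnorm(1, 0, 1))
    d <- abs(stats[, 1] - obs)
    acc <- reject_indices(d, 0.5)
    rej_mean <- mean(theta[acc])
    la <- loclinear_adjust(cbind(theta = theta[acc]),
                           stats[acc, , drop = FALSE], obs, d[acc])
    adj_mean <- weighted.mean(la$adjusted[, 1], la$weights)
    if (abs(adj_mean - truth) < abs(rej_mean - truth)) better <- better + 1L
  }
  expect_gte(better, 40L)
})

test_that("model comparison counts acceptances per model and forms ratios", {
  # deterministic construction: 111 near-hits for model A, 100 for model B
  R <- 1000
  statsA <- c(seq(0.001, 0.111, by = 0.001), seq(10, 19, length.out = R - 111))
  statsB <- c(seq(0.0015, by = 0.001, length.out = 100),
              seq(10, 19, length.out = R - 100))
  ref <- structure(list(model = rep(c("A", "B"), each = R),
                        params = list(A = cbind(p = rep(1, R)),
                                      B = cbind(p = rep(1, R))),
                        stats = cbind(s = c(statsA, statsB)),
                        config = list()),
                   class = "abc_reftable")
  comp <- compare_models(ref, c(s = 0), tolerances = 211 / 2000,
                         standardize = FALSE)
  expect_equal(unname(comp$counts[1, ]), c(111L, 100L))
  expect_equal(comp$ratios["A", "B"], 1.11)
  # tolerance 1: every row accepted, all ratios 1
  comp1 <- compare_models(ref, c(s = 0), tolerances = 1, standardize = FALSE)
  expect_equal(unname(comp1$counts[1, ]), c(R, R))
  # order invariance
  ref_rev <- ref
  ord <- c((R + 1):(2 * R), 1:R)
  ref_rev$model <- ref$model[ord]
  ref_rev$stats <- ref$stats[ord, , drop = FALSE]
  comp_rev <- compare_models(ref_rev, c(s = 0), tolerances = 211 / 2000,
                             standardize = FALSE)
  expect_equal(comp_rev$counts[1, c("A", "B")], comp$counts[1, c("A", "B")])
  # statistically identical models: ratio near 1
  set.seed(38)
  ref2 <- structure(list(model = rep(c("A", "B"), each = 3000),
                         params = list(), stats = cbind(s = rnorm(6000)),
                         config = list()),
                    class = "abc_reftable")
  c2 <- compare_models(ref2, c(s = 0), tolerances = 0.1, standardize = FALSE)
  expect_lt(abs(c2$ratios["A", "B"] - 1), 0.35)
  ref_uneq <- ref
  ref_uneq$model <- c(rep("A", 900), rep("B", 1100))
  expect_error(compare_models(ref_uneq, c(s = 0)), "unequal")
})
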