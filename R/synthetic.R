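#' Pseudo-observed expansion dataset with known truth
#'
#' Simulates a single-population exponential-expansion dataset whose
#' generating parameters are recorded alongside, for validating the
#' inference pipeline. The defaults mirror the scale of an inferred
#' human population expansion (onset ~226 generations, i.e. ~5650 years
#' at 25 y/generation, from a pre-expansion size of ~2200) while the
#' full empirical scale (717 loci, several hundred diploids) is
#' available by raising `n_loci`/`n_diploid`.
#'
#' @param t_exp expansion onset in generations (default 226).
#' @param np pre-expansion diploid size (default 2200).
#' @param n0 present diploid size (default 20000).
#' @param n_loci loci (default 100).
#' @param n_diploid diploid individuals (default 100).
#' @param mm a [mutation_model()].
#' @param seed integer seed; the same truth and seed reproduce the
#'   dataset exactly.
#' @return List with `data` (a [microsat_dataset()]) and `truth` (class
#'   `scenario_truth`).
#' @export
make_expansion_pseudo_obs <- function(t_exp = 226, np = 2200, n0 = 20000,
                                      n_loci = 100, n_diploid = 100,
                                      mm = mutation_model(), seed = 1) {
  set.seed(seed)
  dem <- expansion_demography(t_exp = t_exp, np = np, n0 = n0)
  d <- simulate_dataset(dem, n_diploid, n_loci, mm)
  truth <- structure(list(scenario = "expansion",
                          params = c(t_exp = t_exp, np = np, n0 = n0),
                          mm = mm, n_loci = n_loci, n_diploid = n_diploid,
                          seed = seed),
                     class = "scenario_truth")
  list(data = d, truth = truth)
}

#' Pseudo-observed three-population dataset with known truth
#'
#' Simulates an east/south/west divergence dataset under one of the four
#' topologies. Default sample sizes (east 40, south 41, west 48
#' diploids) mirror the regional pools of the empirical panel the
#' pipeline targets.
#'
#' @param topology `"ESW"`, `"SEW"`, `"WES"` or `"STAR"`.
#' @param t1,delta_t split times (generations; `t2 = t1 + delta_t`).
#' @param n0,alpha,n_anc1,n_anc2,M see [threepop_demography()].
#' @param n_loci loci (default 100).
#' @param n_diploid diploids per population `c(east, south, west)`.
#' @param mm a [mutation_model()].
#' @param seed integer seed.
#' @return List with `data` and `truth`.
#' @export
make_threepop_pseudo_obs <- function(topology = "WES", t1 = 160, delta_t = 80,
                                     n0 = c(east = 1e4, south = 1e4, west = 1e4),
                                     alpha = c(east = 0, south = 0, west = 0),
                                     n_anc1 = 2000, n_anc2 = 2000, M = 1500,
                                     n_loci = 100,
                                     n_diploid = c(east = 40, south = 41, west = 48),
                                     mm = mutation_model(), seed = 1) {
  set.seed(seed)
  dem <- threepop_demography(topology, t1 = t1, delta_t = delta_t, n0 = n0,
                             alpha = alpha, n_anc1 = n_anc1, n_anc2 = n_anc2,
                             M = M)
  d <- simulate_dataset(dem, n_diploid, n_loci, mm)
  truth <- structure(list(scenario = topology,
                          params = c(t1 = t1, delta_t = delta_t,
                                     n_anc1 = n_anc1, n_anc2 = n_anc2, M = M),
                          n0 = n0, alpha = alpha, mm = mm,
                          n_loci = n_loci, n_diploid = n_diploid,
                          seed = seed),
                     class = "scenario_truth")
  list(data = d, truth = truth)
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat("scenario_truth [", x$scenario, "] seed ", x$seed, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Degrade a dataset with missingness and indel markers
#'
#' Masks genotypes independently at the given rate and flags a fraction
#' of loci as non-microsatellite markers, producing inputs that exercise
#' the marker filters. Deterministic at a fixed seed.
#'
#' @param d a [microsat_dataset()].
#' @param missing_rate probability each genotype is masked.
#' @param indel_fraction probability each locus is flagged `"indel"`.
#' @param seed integer seed.
#' @return A degraded [microsat_dataset()].
#' @export
degrade <- function(d, missing_rate = 0, indel_fraction = 0, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  set.seed(seed)
  a1 <- d$a1; a2 <- d$a2
  if (missing_rate > 0) {
    mask <- matrix(runif(length(a1)) < missing_rate, nrow(a1))
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  mc <- d$marker_class
  if (indel_fraction > 0)
    mc[runif(length(mc)) < indel_fraction] <- "indel"
  microsat_dataset(a1, a2, pop = d$pop, loci = d$loci, ind_id = d$ind_id,
                   marker_class = mc)
}

#' Reduced-scale preset for fast end-to-end runs
#'
#' A deliberately small problem size (50 loci, 50 diploids, 5000
#' reference simulations, 1% tolerance) at which the full pipeline runs
#' in seconds-to-minutes while remaining statistically meaningful for
#' recovery checks; see the methods vignette for the reasoning.
#'
#' @return Named list `n_loci`, `n_diploid`, `R`, `tolerance`.
#' @export
ci_preset <- function() {
  list(n_loci = 50L, n_diploid = 50L, R = 5000L, tolerance = 0.01)
}
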