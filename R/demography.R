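#' Single-population exponential-expansion demography
#'
#' Backwards in time the population shrinks exponentially from its
#' present size `n0` to the pre-expansion size `np`, reached at the
#' expansion onset `t_exp`; earlier than `t_exp` the size is constant at
#' `np`. The growth rate is `alpha = log(n0/np) / t_exp` per generation,
#' so the trajectory `N(t) = n0 * exp(-alpha * t)` is continuous at
#' `t_exp`. `np > n0` (a decline, negative `alpha`) is allowed and
#' flagged in the object.
#'
#' @param t_exp expansion onset, generations before present (> 0).
#' @param np pre-expansion diploid effective size (> 0).
#' @param n0 present diploid effective size (> 0); a nuisance parameter
#'   in the inference.
#' @return An object of class `expansion_demography`.
#' @export
expansion_demography <- function(t_exp, np, n0) {
  if (any(c(t_exp, np, n0) <= 0)) stop("t_exp, np and n0 must all be > 0")
  alpha <- log(n0 / np) / t_exp
  structure(list(t_exp = t_exp, np = np, n0 = n0, alpha = alpha,
                 declining = np > n0),
            class = "expansion_demography")
}

#' @export
print.expansion_demography <- function(x, ...) {
  cat(sprintf(
    "expansion_demography: N0 = %g -> Np = %g at T_EXP = %g generations (alpha = %.6g/gen)%s\n",
    x$n0, x$np, x$t_exp, x$alpha,
    if (x$declining) " [declining]" else ""))
  invisible(x)
}

#' Three-population divergence demography
#'
#' Models the divergence of east, south and west populations under one
#' of four topologies. Backwards in time, at `t1` the topology-designated
#' pair merges into a first ancestral population of constant size
#' `n_anc1`; at `t2 = t1 + delta_t` the remaining population merges with
#' it into a second ancestral population of constant size `n_anc2`. Under
#' `"STAR"` all three populations merge at `t1` (`delta_t` must be 0).
#' Each extant population may grow exponentially (rate `alpha`, per
#' generation) since its founding split; ancestral populations are
#' constant. Symmetric migration at scaled rate `M = 4*N0*m` acts between
#' every pair of coexisting populations (per-lineage backward rate
#' `M / (4 * N_i)` with `N_i` the source population's present or constant
#' size).
#'
#' Topologies (Newick-style): `ESW` = (east, (south, west)); `SEW` =
#' (south, (east, west)); `WES` = (west, (east, south)); `STAR` =
#' (east, south, west) simultaneous.
#'
#' @param topology one of `"ESW"`, `"SEW"`, `"WES"`, `"STAR"`.
#' @param t1 first (most recent) split time, generations (> 0).
#' @param delta_t gap to the older split, `t2 - t1` (>= 0; 0 for STAR).
#' @param n0 named or positional numeric vector of present sizes
#'   `c(east, south, west)`.
#' @param alpha growth rates per generation `c(east, south, west)`.
#' @param n_anc1,n_anc2 constant ancestral sizes (first and second,
#'   backwards in time; `n_anc2` ignored for STAR).
#' @param M scaled migration rate `4*N0*m` between each coexisting pair.
#' @return An object of class `threepop_demography`.
#' @export
threepop_demography <- function(topology = c("ESW", "SEW", "WES", "STAR"),
                                t1, delta_t = 0,
                                n0 = c(east = 1e4, south = 1e4, west = 1e4),
                                alpha = c(east = 0, south = 0, west = 0),
                                n_anc1 = 1e4, n_anc2 = 1e4, M = 1500) {
  topology <- match.arg(topology)
  if (t1 <= 0) stop("t1 must be > 0")
  if (delta_t < 0) stop("delta_t must be >= 0")
  if (topology == "STAR" && delta_t > 0)
    stop("STAR topology requires delta_t = 0")
  n0 <- rep_len(as.numeric(n0), 3L); alpha <- rep_len(as.numeric(alpha), 3L)
  if (any(n0 <= 0) || n_anc1 <= 0 || n_anc2 <= 0) stop("sizes must be > 0")
  if (M < 0) stop("M must be >= 0")
  structure(list(topology = topology, t1 = t1, delta_t = delta_t,
                 t2 = t1 + delta_t,
                 n0 = setNames(n0, c("east", "south", "west")),
                 alpha = setNames(alpha, c("east", "south", "west")),
                 n_anc1 = n_anc1, n_anc2 = n_anc2, M = M),
            class = "threepop_demography")
}

#' @export
print.threepop_demography <- function(x, ...) {
  cat(sprintf("threepop_demography [%s]: T1 = %g, T2 = %g generations, M = %g\n",
              x$topology, x$t1, x$t2, x$M))
  cat(sprintf("  N0 (e/s/w) = %g/%g/%g, alpha = %g/%g/%g, N_anc = %g/%g\n",
              x$n0[1], x$n0[2], x$n0[3],
              x$alpha[1], x$alpha[2], x$alpha[3], x$n_anc1, x$n_anc2))
  invisible(x)
}

# pair of deme indices (1 = east, 2 = south, 3 = west) merging at t1
topology_pair <- function(topology) {
  switch(topology,
         ESW = c(2L, 3L),  # (east, (south, west))
         SEW = c(1L, 3L),  # (south, (east, west))
         WES = c(1L, 2L),  # (west, (east, south))
         STAR = c(1L, 2L, 3L),
         stop("unknown topology: ", topology))
}

# Flatten a demography into the event encoding consumed by the C++
# simulator: vectors size/alpha/t_growth_end/alive_start per deme, a
# merge matrix (time, from0, to0) and a per-lineage migration matrix.
dem_events <- function(dem) UseMethod("dem_events")

#' @export
dem_events.expansion_demography <- function(dem) {
  list(size = dem$n0, alpha = dem$alpha, t_growth_end = dem$t_exp,
       alive_start = 0,
       merges = matrix(numeric(0), 0, 3),
       mig = matrix(0, 1, 1),
       deme_names = "pop")
}

#' @export
dem_events.threepop_demography <- function(dem) {
  star <- dem$topology == "STAR"
  n_demes <- if (star) 4L else 5L  # east, south, west, anc1[, anc2]
  size <- c(dem$n0, dem$n_anc1, if (!star) dem$n_anc2)
  alpha <- c(dem$alpha, 0, if (!star) 0)
  pair <- topology_pair(dem$topology)
  # growth runs (backwards) from now to each deme's founding split
  t_end <- c(ifelse(1:3 %in% pair, dem$t1, dem$t2), Inf, if (!star) Inf)
  alive_start <- c(0, 0, 0, dem$t1, if (!star) dem$t2)
  if (star) {
    merges <- cbind(dem$t1, 0:2, 3L)
  } else {
    rest <- setdiff(1:3, pair)
    merges <- rbind(cbind(dem$t1, pair - 1L, 3L),
                    cbind(dem$t2, c(rest - 1L, 3L), 4L))
  }
  mig <- matrix(0, n_demes, n_demes)
  if (dem$M > 0) {
    rate_out <- dem$M / (4 * size)  # per-lineage backward rate per target
    for (i in seq_len(n_demes)) mig[i, -i] <- rate_out[i]
  }
  list(size = size, alpha = alpha, t_growth_end = t_end,
       alive_start = alive_start,
       merges = merges[order(merges[, 1]), , drop = FALSE], mig = mig,
       deme_names = c("east", "south", "west", "anc1", if (!star) "anc2"))
}
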