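#' Microsatellite mutation model (generalized stepwise)
#'
#' Symmetric generalized stepwise mutation model (GSM): mutations occur
#' as a Poisson process along branches at a per-locus rate drawn
#' uniformly from `[mu_low, mu_high]`; each mutation changes the repeat
#' count by `s * k` with sign `s = +/-1` equiprobable and magnitude `k`
#' geometric, `P(k) = p_step * (1 - p_step)^(k-1)` (so `p_step = 1` is
#' the strict single-step SMM and the mean step is `1/p_step`). No
#' boundary constraints are imposed on allele size.
#'
#' @param mu_low,mu_high per-locus per-generation mutation-rate bounds
#'   (defaults 2.5e-4 and 7.5e-4).
#' @param p_step geometric parameter of the step-size distribution
#'   (default 0.95).
#' @param ancestral_state root repeat count (default 100).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu_low = 0.00025, mu_high = 0.00075,
                           p_step = 0.95, ancestral_state = 100L) {
  if (!(mu_low > 0 && mu_low <= mu_high)) stop("need 0 < mu_low <= mu_high")
  if (!(p_step > 0 && p_step <= 1)) stop("need 0 < p_step <= 1")
  if (ancestral_state <= 0) stop("ancestral_state must be positive")
  structure(list(mu_low = mu_low, mu_high = mu_high, p_step = p_step,
                 ancestral_state = as.integer(ancestral_state)),
            class = "mutation_model")
}

#' Draw a per-locus mutation rate
#'
#' @param mm a [mutation_model()].
#' @param n number of draws.
#' @return Numeric vector of rates in `[mu_low, mu_high]`.
#' @export
draw_locus_mutation_rate <- function(mm, n = 1L) {
  if (mm$mu_low == mm$mu_high) rep(mm$mu_low, n)
  else runif(n, mm$mu_low, mm$mu_high)
}

#' Simulate one genealogy under a demographic model
#'
#' Exact structured-coalescent sample: within-deme coalescence with the
#' exponential-growth hazard inverted in closed form (no time
#' discretization), constant-rate backward migration between coexisting
#' demes, and deterministic lineage movements at split times. Time is in
#' generations; sizes are diploid.
#'
#' @param dem an [expansion_demography()] or [threepop_demography()].
#' @param sample_sizes haplotypes sampled per deme at present (a single
#'   number for the expansion model; `c(east, south, west)` for the
#'   three-population models).
#' @return An object of class `genealogy`: `parent` (1-based, `NA` at
#'   the root), `time` (node times in generations), `n_leaves`,
#'   `leaf_deme` (deme name per leaf). Leaves are nodes
#'   `1..n_leaves` in deme-block order; internal nodes follow in
#'   coalescence order.
#' @export
simulate_genealogy <- function(dem, sample_sizes) {
  ev <- dem_events(dem)
  ss <- integer(length(ev$size))
  ss[seq_along(sample_sizes)] <- as.integer(sample_sizes)
  if (sum(ss) < 1L) stop("need at least one sampled haplotype")
  g <- cpp_simulate_genealogy(ev$size, ev$alpha, ev$t_growth_end,
                              ev$alive_start, ev$merges, ev$mig, ss)
  structure(list(parent = ifelse(g$parent < 0, NA_integer_, g$parent + 1L),
                 time = g$time, n_leaves = g$n_leaves,
                 leaf_deme = ev$deme_names[g$leaf_deme + 1L]),
            class = "genealogy")
}

#' Total branch length of a genealogy, in generations
#' @param g a `genealogy`.
#' @return Sum of all branch lengths.
#' @export
genealogy_total_length <- function(g) {
  if (g$n_leaves < 2) return(0)
  sum(g$time[g$parent[!is.na(g$parent)]] - g$time[!is.na(g$parent)])
}

#' Time to the most recent common ancestor, in generations
#' @param g a `genealogy`.
#' @return Root node time.
#' @export
genealogy_tmrca <- function(g) max(g$time)

#' Overlay stepwise mutations on a genealogy
#'
#' Mutation counts per branch are Poisson with mean `mu` times the
#' branch length; steps follow the signed geometric distribution of the
#' GSM (see [mutation_model()]). Leaf repeat counts are the ancestral
#' state plus the signed sums along root-to-leaf paths.
#'
#' @param g a `genealogy`.
#' @param mu per-locus per-generation mutation rate (>= 0).
#' @param p_step geometric step parameter.
#' @param ancestral_state root repeat count.
#' @return Integer vector of repeat counts, one per leaf.
#' @export
mutate_genealogy <- function(g, mu, p_step = 0.95, ancestral_state = 100L) {
  stopifnot(mu >= 0)
  parent0 <- ifelse(is.na(g$parent), -1L, g$parent - 1L)
  cpp_mutate_genealogy(parent0, g$time, g$n_leaves, mu, p_step,
                       as.integer(ancestral_state))
}

#' Simulate a multi-locus microsatellite dataset
#'
#' For each of `n_loci` unlinked loci independently: draw a mutation
#' rate, simulate a genealogy under `dem`, overlay GSM mutations, and
#' pair consecutive haplotypes within each deme into diploid genotypes.
#' The output has no missing data. With a fixed RNG seed the output is
#' bit-reproducible.
#'
#' @param dem an [expansion_demography()] or [threepop_demography()].
#' @param n_diploid diploid individuals sampled per population (single
#'   number, or `c(east, south, west)`).
#' @param n_loci number of loci.
#' @param mm a [mutation_model()].
#' @return A [microsat_dataset()] with populations in deme order.
#' @export
simulate_dataset <- function(dem, n_diploid, n_loci,
                             mm = mutation_model()) {
  stopifnot(n_loci >= 1)
  hap <- sim_hap_matrix(dem, n_diploid, n_loci, mm)
  n_dip <- attr(hap, "n_diploid")
  pops <- attr(hap, "pops")
  a1 <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE]
  a2 <- hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  microsat_dataset(a1, a2,
                   pop = factor(rep(pops, n_dip), levels = pops))
}

# fast path shared with the reference-table builder: raw haplotype matrix
sim_hap_matrix <- function(dem, n_diploid, n_loci, mm) {
  ev <- dem_events(dem)
  sampled <- if (inherits(dem, "expansion_demography")) "pop"
             else c("east", "south", "west")
  n_dip <- as.integer(rep_len(n_diploid, length(sampled)))
  ss <- integer(length(ev$size))
  ss[seq_along(n_dip)] <- 2L * n_dip
  hap <- cpp_simulate_dataset(ev$size, ev$alpha, ev$t_growth_end,
                              ev$alive_start, ev$merges, ev$mig, ss,
                              as.integer(n_loci),
                              mm$mu_low, mm$mu_high, mm$p_step,
                              mm$ancestral_state)
  attr(hap, "n_diploid") <- n_dip
  attr(hap, "pops") <- sampled
  hap
}
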