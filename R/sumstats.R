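#' Per-locus allele counts
#'
#' Builds the allele-count representation of one locus from a vector of
#' allele copies (repeat numbers), the unit on which all per-locus
#' statistics operate.
#'
#' @param alleles integer vector of allele copies; `NA` dropped.
#' @return A named integer vector of counts (names = repeat numbers),
#'   class `locus_counts`.
#' @export
locus_counts <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  tab <- table(alleles)
  structure(setNames(as.integer(tab), names(tab)), class = "locus_counts")
}

counts_n <- function(c) sum(unclass(c))
counts_alleles <- function(c) as.integer(names(c))

#' Expected heterozygosity at one locus
#'
#' Nei's unbiased estimator `(n/(n-1)) * (1 - sum(p^2))`.
#'
#' @param c a [locus_counts()] (or a named count vector).
#' @return Heterozygosity in `[0, 1]`.
#' @export
locus_het <- function(c) {
  n <- counts_n(c)
  if (n < 2) stop("need at least 2 allele copies")
  p <- unclass(c) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Variance of repeat number at one locus
#'
#' Sample variance (n-1 denominator) of the allele copies.
#'
#' @param c a [locus_counts()].
#' @return Non-negative variance.
#' @export
locus_var_repeats <- function(c) {
  n <- counts_n(c)
  if (n < 2) stop("need at least 2 allele copies")
  var(rep(counts_alleles(c), unclass(c)))
}

#' Allele count, modal allele frequency, singleton count at one locus
#'
#' @param c a [locus_counts()].
#' @return `locus_num_alleles`: number of distinct alleles;
#'   `locus_max_freq`: frequency of the most frequent allele;
#'   `locus_singletons`: number of alleles observed exactly once.
#' @export
locus_num_alleles <- function(c) {
  if (counts_n(c) < 1) stop("empty locus")
  length(unclass(c))
}

#' @rdname locus_num_alleles
#' @export
locus_max_freq <- function(c) {
  n <- counts_n(c)
  if (n < 1) stop("empty locus")
  max(unclass(c)) / n
}

#' @rdname locus_num_alleles
#' @export
locus_singletons <- function(c) {
  if (counts_n(c) < 1) stop("empty locus")
  sum(unclass(c) == 1L)
}

#' Pairwise F_ST at one locus (Weir & Cockerham)
#'
#' Multi-allelic Weir & Cockerham (1984) theta for two populations,
#' computed from allele frequencies (haploid form, no within-individual
#' component since genotype phase is not used), as a ratio of sums over
#' alleles. Undefined (NA) when both populations are fixed for the same
#' single allele.
#'
#' @param cA,cB [locus_counts()] for the two populations.
#' @return Theta estimate (slightly negative values are estimator noise
#'   around 0), or `NA` when undefined.
#' @export
locus_fst <- function(cA, cB) {
  if (counts_n(cA) < 2 || counts_n(cB) < 2)
    stop("need at least 2 allele copies in each population")
  al <- sort(unique(c(counts_alleles(cA), counts_alleles(cB))))
  x1 <- setNames(rep(0L, length(al)), al); x2 <- x1
  x1[names(cA)] <- unclass(cA); x2[names(cB)] <- unclass(cB)
  m <- matrix(c(rep(al, x1), rep(al, x2)), ncol = 1)
  grp <- c(rep(0L, sum(x1)), rep(1L, sum(x2)))
  res <- cpp_locus_stats(matrix(as.integer(m), ncol = 1), grp, 2L)
  as.numeric(res$fst[1, 1])
}

the_stat_names <- c("het", "var_repeats", "num_alleles", "max_freq", "singletons")

# mean and variance across loci, NA-dropped per statistic
agg_mean_var <- function(per_locus) {
  mu <- colMeans(per_locus, na.rm = TRUE)
  v <- apply(per_locus, 2, var, na.rm = TRUE)
  list(mean = mu, var = v)
}

#' Ten-component summary vector for a single group
#'
#' For each of the five per-locus statistics (expected heterozygosity,
#' repeat-number variance, number of alleles, modal allele frequency,
#' number of singletons), the mean and the variance across loci, pooling
#' all individuals of the dataset into one group. Loci where a statistic
#' is undefined are dropped from that statistic's aggregation. Order:
#' `het_mean, het_var, var_repeats_mean, var_repeats_var,
#' num_alleles_mean, num_alleles_var, max_freq_mean, max_freq_var,
#' singletons_mean, singletons_var`.
#'
#' @param d a [microsat_dataset()].
#' @return Named numeric vector of length 10.
#' @export
summary_single <- function(d) {
  if (ncol(d$a1) < 2) stop("need at least 2 loci")
  hm <- hap_matrix(d)
  res <- cpp_locus_stats(hm$hap, rep(0L, nrow(hm$hap)), 1L)
  ag <- agg_mean_var(res$within)
  out <- as.vector(rbind(ag$mean, ag$var))
  names(out) <- as.vector(rbind(paste0(the_stat_names, "_mean"),
                                paste0(the_stat_names, "_var")))
  out
}

#' Eighteen-component summary vector for three populations
#'
#' For each of the three populations (in the fixed order given by
#' `pops`), the across-locus mean of each of the five per-locus
#' statistics (15 components), followed by the across-locus mean of each
#' pairwise F_ST in pair order (1-2, 1-3, 2-3), totalling 18. With
#' `include_variances = TRUE` the across-locus variances of the 15
#' within-population statistics are appended after the means of each
#' population (33 components).
#'
#' @param d a [microsat_dataset()] containing the three populations.
#' @param pops three population labels, fixed order (default: the first
#'   three factor levels).
#' @param include_variances append per-population across-locus variances.
#' @return Named numeric vector of length 18 (or 33).
#' @export
summary_threepop <- function(d, pops = levels(d$pop),
                             include_variances = FALSE) {
  if (length(pops) != 3) stop("exactly three populations required")
  if (!all(pops %in% levels(d$pop))) stop("population missing from dataset")
  if (any(table(d$pop)[pops] < 2)) stop("each population needs >= 2 individuals")
  hm <- hap_matrix(d, pops)
  res <- cpp_locus_stats(hm$hap, hm$group, 3L)
  ag <- agg_mean_var(res$within)
  pair_names <- c(paste(pops[1], pops[2], sep = "_"),
                  paste(pops[1], pops[3], sep = "_"),
                  paste(pops[2], pops[3], sep = "_"))
  fst_mean <- colMeans(res$fst, na.rm = TRUE)
  means <- ag$mean
  names(means) <- paste0(rep(the_stat_names, 3), "_mean_",
                         rep(pops, each = 5))
  out <- c(means, setNames(fst_mean, paste0("fst_mean_", pair_names)))
  if (include_variances) {
    vars <- ag$var
    names(vars) <- paste0(rep(the_stat_names, 3), "_var_",
                          rep(pops, each = 5))
    out <- c(means, vars, setNames(fst_mean, paste0("fst_mean_", pair_names)))
  }
  out
}

# per-locus statistic matrices straight from a simulated haplotype
# matrix (no dataset object), used by the reference-table builder
hap_summary_single <- function(hap) {
  res <- cpp_locus_stats(hap, rep(0L, nrow(hap)), 1L)
  ag <- agg_mean_var(res$within)
  out <- as.vector(rbind(ag$mean, ag$var))
  names(out) <- as.vector(rbind(paste0(the_stat_names, "_mean"),
                                paste0(the_stat_names, "_var")))
  out
}

hap_summary_threepop <- function(hap, group) {
  res <- cpp_locus_stats(hap, group, 3L)
  ag <- agg_mean_var(res$within)
  pops <- c("east", "south", "west")
  means <- ag$mean
  names(means) <- paste0(rep(the_stat_names, 3), "_mean_", rep(pops, each = 5))
  fst_mean <- colMeans(res$fst, na.rm = TRUE)
  c(means, setNames(fst_mean,
                    c("fst_mean_east_south", "fst_mean_east_west",
                      "fst_mean_south_west")))
}
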