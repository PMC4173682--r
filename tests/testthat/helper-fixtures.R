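# Hand-built fixtures and independent oracles shared across tests.

# a 4-individual, 3-locus dataset with two populations and one missing
# genotype; alleles chosen so every per-locus statistic is hand-checkable
tiny_dataset <- function() {
  a1 <- matrix(c(10L, 10L, 12L, 11L,
                 20L, 21L, 20L, NA,
                 30L, 30L, 30L, 30L), nrow = 4)
  a2 <- matrix(c(10L, 12L, 12L, 11L,
                 20L, 21L, 22L, NA,
                 30L, 30L, 30L, 30L), nrow = 4)
  microsat_dataset(a1, a2, pop = c("A", "A", "B", "B"),
                   loci = c("Lx", "Ly", "Lz"),
                   ind_id = paste0("i", 1:4))
}

# Weir-Cockerham two-population theta via R's own ANOVA machinery on
# per-allele indicator variables: an independent route to the estimator
wc_theta_oracle <- function(alleles1, alleles2) {
  y <- c(alleles1, alleles2)
  grp <- factor(rep(c("a", "b"), c(length(alleles1), length(alleles2))))
  n1 <- length(alleles1); n2 <- length(alleles2)
  nc <- n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
  num <- den <- 0
  for (al in sort(unique(y))) {
    ind <- as.numeric(y == al)
    ms <- anova(lm(ind ~ grp))[["Mean Sq"]]
    msp <- ms[1]; msg <- ms[2]
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  num / den
}

counts_to_alleles <- function(counts) {
  rep(as.integer(names(counts)), counts)
}
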