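test_that("per-locus statistics match hand computations", {
  c1 <- locus_counts(c(10, 10, 12, 12))
  expect_equal(locus_het(c1), (4 / 3) * (1 - 0.5))
  expect_equal(locus_var_repeats(c1), 4 / 3)
  c2 <- locus_counts(c(10, 11))
  expect_equal(locus_het(c2), 1.0)
  expect_equal(locus_var_repeats(locus_counts(c(10, 12))), 2.0)
  c3 <- locus_counts(c(10, 11, 11, 11, 11, 11, 12))
  expect_equal(locus_num_alleles(c3), 3L)
  expect_equal(locus_max_freq(c3), 5 / 7)
  expect_equal(locus_singletons(c3), 2L)
  mono <- locus_counts(rep(10, 6))
  expect_equal(locus_het(mono), 0)
  expect_equal(locus_var_repeats(mono), 0)
  expect_equal(locus_num_alleles(mono), 1L)
  expect_equal(locus_max_freq(mono), 1.0)
  expect_equal(locus_singletons(mono), 0L)
  allsing <- locus_counts(c(10, 11, 12))
  expect_equal(locus_num_alleles(allsing), 3L)
  expect_equal(locus_max_freq(allsing), 1 / 3)
  expect_equal(locus_singletons(allsing), 3L)
  expect_error(locus_het(locus_counts(10)), "2 allele copies")
})

test_that("pairwise F_ST agrees with an independent ANOVA oracle", {
  a <- counts_to_alleles(c(`10` = 6, `12` = 2))
  b <- counts_to_alleles(c(`10` = 2, `12` = 6))
  expect_equal(locus_fst(locus_counts(a), locus_counts(b)),
               wc_theta_oracle(a, b), tolerance = 1e-12)
  # fixed difference
  expect_equal(locus_fst(locus_counts(rep(10, 8)), locus_counts(rep(12, 8))),
               1.0)
  # identical counts: estimator noise at or below zero
  x <- counts_to_alleles(c(`10` = 5, `11` = 3, `13` = 2))
  expect_lte(locus_fst(locus_counts(x), locus_counts(x)), 0)
  # undefined when both populations share one fixed allele
  expect_true(is.na(locus_fst(locus_counts(rep(10, 4)), locus_counts(rep(10, 6)))))
  # random-case agreement with the oracle
  set.seed(21)
  for (i in 1:10) {
    a <- sample(98:103, 30, replace = TRUE)
    b <- sample(99:104, 24, replace = TRUE)
    expect_equal(locus_fst(locus_counts(a), locus_counts(b)),
                 wc_theta_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("single-group summary vector has 10 named components matching per-locus math", {
  d <- tiny_dataset()
  sv <- summary_single(d)
  expect_length(sv, 10L)
  expect_true(all(is.finite(sv)))
  # componentwise against the exported per-locus functions
  per <- sapply(1:3, function(l) {
    al <- c(d$a1[, l], d$a2[, l])
    cc <- locus_counts(al)
    c(locus_het(cc), locus_var_repeats(cc), locus_num_alleles(cc),
      locus_max_freq(cc), locus_singletons(cc))
  })
  expected <- as.vector(rbind(rowMeans(per), apply(per, 1, var)))
  expect_equal(unname(sv), expected, tolerance = 1e-12)
  expect_equal(names(sv)[1:2], c("het_mean", "het_var"))
  expect_error(summary_single(d[, 1]), "2 loci")
})

test_that("three-population summary vector has 18 components in fixed order", {
  set.seed(22)
  dem <- threepop_demography("STAR", t1 = 200, n0 = rep(1000, 3), M = 0)
  d <- simulate_dataset(dem, c(6, 6, 6), 15)
  sv <- summary_threepop(d)
  expect_length(sv, 18L)
  expect_true(all(is.finite(sv)))
  expect_equal(names(sv)[16:18],
               c("fst_mean_east_south", "fst_mean_east_west",
                 "fst_mean_south_west"))
  expect_length(summary_threepop(d, include_variances = TRUE), 33L)
  # componentwise against per-locus functions for one population
  east <- d[d$pop == "east", ]
  per_het <- sapply(seq_len(ncol(d$a1)), function(l)
    locus_het(locus_counts(c(east$a1[, l], east$a2[, l]))))
  expect_equal(unname(sv["het_mean_east"]), mean(per_het), tolerance = 1e-12)
  # pairwise fst mean against the per-locus function
  south <- d[d$pop == "south", ]
  per_fst <- sapply(seq_len(ncol(d$a1)), function(l)
    locus_fst(locus_counts(c(east$a1[, l], east$a2[, l])),
              locus_counts(c(south$a1[, l], south$a2[, l]))))
  expect_equal(unname(sv["fst_mean_east_south"]), mean(per_fst, na.rm = TRUE),
               tolerance = 1e-12)
  expect_error(summary_threepop(d, pops = c("east", "south")), "three")
})

test_that("three identical populations give F_ST means at or below zero", {
  set.seed(23)
  dem <- expansion_demography(1, 800, 800)
  base <- simulate_dataset(dem, 8, 20)
  d <- microsat_dataset(rbind(base$a1, base$a1, base$a1),
                        rbind(base$a2, base$a2, base$a2),
                        pop = rep(c("east", "south", "west"), each = 8))
  sv <- summary_threepop(d)
  expect_true(all(sv[grep("fst", names(sv))] <= 0))
})

test_that("statistics are invariant to relabeling and allele translation", {
  set.seed(24)
  dem <- expansion_demography(1, 500, 500)
  d <- simulate_dataset(dem, 10, 12)
  sv <- summary_single(d)
  perm <- sample(nrow(d$a1))
  d2 <- microsat_dataset(d$a1[perm, ], d$a2[perm, ], pop = d$pop[perm])
  expect_equal(unname(summary_single(d2)), unname(sv), tolerance = 1e-12)
  d3 <- microsat_dataset(d$a1 + 7L, d$a2 + 7L, pop = d$pop)
  expect_equal(unname(summary_single(d3)), unname(sv), tolerance = 1e-12)
})

test_that("missing copies are excluded per locus (n counts non-missing only)", {
  a1 <- matrix(c(10L, 10L, NA, 20L, 21L, 20L), 3)
  a2 <- matrix(c(12L, 10L, NA, 20L, 21L, 22L), 3)
  d <- microsat_dataset(a1, a2, pop = rep("P", 3))
  sv <- summary_single(d)
  cc <- locus_counts(c(10, 12, 10, 10))  # locus 1 without the missing pair
  expect_equal(unname(sv["het_mean"]),
               mean(c(locus_het(cc),
                      locus_het(locus_counts(c(20, 20, 21, 21, 20, 22))))),
               tolerance = 1e-12)
})
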