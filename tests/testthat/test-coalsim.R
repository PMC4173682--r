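test_that("expansion demography growth rate satisfies the size trajectory", {
  d <- expansion_demography(t_exp = 100, np = 1000, n0 = 2000)
  expect_equal(d$alpha, log(2) / 100)
  expect_equal(d$n0 * exp(-d$alpha * d$t_exp), d$np)
  expect_equal(expansion_demography(50, 5000, 5000)$alpha, 0)
  dec <- expansion_demography(50, 8000, 4000)
  expect_lt(dec$alpha, 0)
  expect_true(dec$declining)
  expect_error(expansion_demography(-1, 10, 10), "> 0")
})

test_that("three-population demographies build the correct merge schedule", {
  wes <- threepop_demography("WES", t1 = 160, delta_t = 80)
  ev <- msatABC:::dem_events(wes)
  # east (deme 0) and south (deme 1) merge into anc1 (deme 3) at 160;
  # west (2) and anc1 merge into anc2 (4) at 240
  expect_equal(ev$merges[, 1], c(160, 160, 240, 240))
  expect_setequal(ev$merges[ev$merges[, 1] == 160, 2], c(0, 1))
  expect_true(all(ev$merges[ev$merges[, 1] == 160, 3] == 3))
  expect_setequal(ev$merges[ev$merges[, 1] == 240, 2], c(2, 3))
  star <- threepop_demography("STAR", t1 = 160)
  evs <- msatABC:::dem_events(star)
  expect_equal(evs$merges[, 1], rep(160, 3))
  expect_setequal(evs$merges[, 2], 0:2)
  expect_error(threepop_demography("STAR", t1 = 160, delta_t = 10), "delta_t")
  expect_error(threepop_demography("XYZ", t1 = 160))
  # M = 0 keeps the event list but zeroes migration
  iso <- threepop_demography("ESW", t1 = 100, delta_t = 50, M = 0)
  expect_true(all(msatABC:::dem_events(iso)$mig == 0))
})

test_that("pairwise coalescence times match the constant-size expectation", {
  set.seed(11)
  n0 <- 500
  dem <- expansion_demography(1, n0, n0)
  tt <- replicate(20000, genealogy_tmrca(simulate_genealogy(dem, 2)))
  se <- sd(tt) / sqrt(length(tt))
  expect_lt(abs(mean(tt) - 2 * n0), 3 * se)
})

test_that("total branch length matches 4*N0*sum(1/i) for constant size", {
  set.seed(12)
  n0 <- 500; n <- 10
  dem <- expansion_demography(1, n0, n0)
  L <- replicate(5000, genealogy_total_length(simulate_genealogy(dem, n)))
  expected <- 4 * n0 * sum(1 / seq_len(n - 1))
  se <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - expected), 3 * se)
})

test_that("degenerate and isolation genealogies behave", {
  dem <- expansion_demography(1, 100, 100)
  g1 <- simulate_genealogy(dem, 1)
  expect_equal(g1$n_leaves, 1L)
  expect_equal(genealogy_total_length(g1), 0)
  # two demes, no migration: no coalescence across demes before the merge
  set.seed(13)
  iso <- threepop_demography("STAR", t1 = 500, n0 = rep(100, 3), M = 0)
  tm <- replicate(50, {
    g <- simulate_genealogy(iso, c(1, 1, 1))
    min(g$time[g$time > 0])
  })
  expect_true(all(tm >= 500))
})

test_that("per-locus mutation rates respect the uniform prior bounds", {
  set.seed(14)
  mm <- mutation_model()
  mu <- draw_locus_mutation_rate(mm, 10000)
  expect_true(all(mu >= 0.00025 & mu <= 0.00075))
  se <- (0.00075 - 0.00025) / sqrt(12) / sqrt(length(mu))
  expect_lt(abs(mean(mu) - 0.0005), 3 * se)
  mm0 <- mutation_model(3e-4, 3e-4)
  expect_equal(draw_locus_mutation_rate(mm0, 5), rep(3e-4, 5))
  expect_error(mutation_model(mu_low = 0), "mu_low")
  expect_error(mutation_model(p_step = 0), "p_step")
})

test_that("mutation overlay honours mu = 0 and the ancestral state", {
  set.seed(15)
  dem <- expansion_demography(1, 200, 200)
  g <- simulate_genealogy(dem, 10)
  expect_equal(mutate_genealogy(g, mu = 0), rep(100L, 10))
  states <- mutate_genealogy(g, mu = 0.01, ancestral_state = 55L)
  expect_true(is.integer(states))
  expect_length(states, 10)
})

test_that("simulate_dataset has the requested shape and is seed-reproducible", {
  dem <- threepop_demography("WES", t1 = 100, delta_t = 50,
                             n0 = rep(1000, 3), M = 0)
  set.seed(16)
  d <- simulate_dataset(dem, c(5, 6, 7), n_loci = 12)
  expect_equal(dim(d), c(18L, 12L))
  expect_equal(as.integer(table(d$pop)[c("east", "south", "west")]),
               c(5L, 6L, 7L))
  expect_false(anyNA(d$a1))
  set.seed(16)
  d2 <- simulate_dataset(dem, c(5, 6, 7), n_loci = 12)
  expect_identical(d$a1, d2$a1)
  expect_identical(d$a2, d2$a2)
  # mu = 0: single homozygous genotype at the ancestral state
  set.seed(17)
  e <- simulate_dataset(expansion_demography(1, 100, 100), 1, 1,
                        mutation_model(1e-12, 1e-12))
  expect_equal(unname(e$a1[1, 1]), 100L)
  expect_equal(unname(e$a2[1, 1]), 100L)
})
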