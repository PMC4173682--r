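test_that("half-missing genotypes are normalized and invariants enforced", {
  a1 <- matrix(c(10L, NA, 12L, 13L), 2)
  a2 <- matrix(c(10L, 11L, NA, 13L), 2)
  d <- microsat_dataset(a1, a2, pop = c("A", "A"))
  expect_true(is.na(d$a1[2, 1]) && is.na(d$a2[2, 1]))
  expect_true(is.na(d$a1[1, 2]) && is.na(d$a2[1, 2]))
  expect_error(microsat_dataset(matrix(-1L), matrix(2L), pop = "A"),
               "positive")
  expect_error(microsat_dataset(matrix(1L), matrix(2L), pop = c("A", "B")),
               "population")
})

test_that("TSV dialect round-trips a dataset and normalizes missing codes", {
  d <- tiny_dataset()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(d, f, dialect = "tsv")
  d2 <- read_genotypes(f, dialect = "tsv")
  expect_true(isTRUE(all.equal(d, d2)))
  # a hand-written table with -9 codes: 2 individuals, 3 loci
  txt <- c("ind\tpop\tL1.1\tL1.2\tL2.1\tL2.2\tL3.1\tL3.2",
           "i1\tP\t10\t12\t-9\t-9\t7\t7",
           "i2\tQ\t11\t11\t20\t21\t-9\t-9")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, f2)
  d3 <- read_genotypes(f2)
  expect_equal(dim(d3), c(2L, 3L))
  expect_true(is.na(d3$a1[1, 2]) && is.na(d3$a1[2, 3]))
  expect_equal(as.character(d3$pop), c("P", "Q"))
  expect_equal(unname(d3$a1[1, 1]), 10L)
})

test_that("GenePop dialect parses a hand-built two-population fixture", {
  txt <- c("title line",
           "locA", "locB",
           "POP",
           "w1 ,  095100 110110",
           "w2 ,  100100 000000",
           "POP",
           "e1 ,  095095 112110",
           "e2 ,  100095 110112")
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(txt, f)
  d <- read_genotypes(f, dialect = "genepop")
  expect_equal(d$loci, c("locA", "locB"))
  expect_equal(as.character(d$pop), c("pop1", "pop1", "pop2", "pop2"))
  expect_equal(unname(d$a1[1, 1]), 95L)
  expect_equal(unname(d$a2[1, 1]), 100L)
  expect_true(is.na(d$a1[2, 2]))  # 000000 is missing
  # and the writer round-trips
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genotypes(d, f2, dialect = "genepop")
  d2 <- read_genotypes(f2, dialect = "genepop")
  expect_equal(unname(d$a1), unname(d2$a1))
  expect_equal(unname(d$a2), unname(d2$a2))
})

test_that("marker filter removes missing-heavy loci and indels, and is idempotent", {
  set.seed(42)
  n_ind <- 20L; n_loci <- 10L
  a <- matrix(100L, n_ind, n_loci)
  d <- microsat_dataset(a, a, pop = rep("P", n_ind))
  # loci 1-3: 60% missing (above the 0.5 threshold); locus 4 flagged indel
  for (l in 1:3) {
    idx <- 1:12  # 60% of 20
    d$a1[idx, l] <- NA_integer_; d$a2[idx, l] <- NA_integer_
  }
  d$marker_class[4] <- "indel"
  res <- filter_markers(d, max_missing = 0.5)
  expect_equal(res$report$loci_in, 10L)
  expect_equal(res$report$loci_removed_missingness, 3L)
  expect_equal(res$report$loci_removed_class, 1L)
  expect_equal(res$report$loci_out, 6L)
  expect_equal(ncol(res$data$a1), 6L)
  expect_equal(res$data$ind_id, d$ind_id)  # individual order unchanged
  with(res$report,
       expect_equal(loci_out, loci_in - loci_removed_missingness - loci_removed_class))
  # idempotence
  res2 <- filter_markers(res$data, max_missing = 0.5)
  expect_equal(res2$report$loci_out, 6L)
  expect_equal(res2$report$loci_removed_missingness +
                 res2$report$loci_removed_class, 0L)
  # exactly-at-threshold loci are retained; clean data untouched
  clean <- microsat_dataset(a, a, pop = rep("P", n_ind))
  resc <- filter_markers(clean)
  expect_equal(resc$report$loci_out, 10L)
  expect_equal(resc$report$loci_removed_missingness, 0L)
})

test_that("result tables round-trip at full precision with metadata", {
  post <- matrix(rnorm(600, 1000, 1), 300, 2,
                 dimnames = list(NULL, c("t_exp", "np")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(post, f, meta = list(seed = 7))
  back <- read_result_table(f)
  expect_equal(nrow(back), 300L)
  expect_equal(names(back), c("t_exp", "np"))
  expect_equal(as.matrix(back), post, ignore_attr = TRUE)  # bit-exact at 17 sig digits
  expect_equal(attr(back, "meta")$seed, 7L)
  expect_error(write_result_table(post[0, ], f), "empty")
})
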