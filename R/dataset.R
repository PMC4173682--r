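#' Multi-locus microsatellite dataset
#'
#' The universal data container of the package: diploid repeat-count
#' genotypes for a set of individuals at a set of unlinked microsatellite
#' loci, with population labels and a per-locus marker class. Alleles are
#' stored as repeat numbers (positive integers), never fragment lengths.
#' Missing genotypes are `NA` in both allele matrices; half-missing
#' genotypes (one allele observed) are normalized to fully missing at
#' construction.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   allele copies of each genotype; `NA` marks missing.
#' @param pop factor or character vector of population labels, one per
#'   individual.
#' @param loci character vector of locus identifiers (defaults to
#'   `L1..Lk`).
#' @param ind_id character vector of individual identifiers.
#' @param marker_class character vector per locus, `"microsat"` or
#'   `"indel"`.
#'
#' @return An object of class `microsat_dataset`: a list with elements
#'   `a1`, `a2`, `pop`, `loci`, `ind_id`, `marker_class`.
#' @export
microsat_dataset <- function(a1, a2, pop,
                             loci = NULL, ind_id = NULL,
                             marker_class = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2)))
    stop("allele matrices must have identical dimensions")
  n_ind <- nrow(a1); n_loci <- ncol(a1)
  if (length(pop) != n_ind)
    stop("one population label per individual required")
  if (is.null(loci)) loci <- paste0("L", seq_len(n_loci))
  if (is.null(ind_id)) ind_id <- paste0("ind", seq_len(n_ind))
  if (is.null(marker_class)) marker_class <- rep("microsat", n_loci)
  if (length(loci) != n_loci || length(marker_class) != n_loci)
    stop("locus metadata length mismatch")
  if (length(ind_id) != n_ind) stop("ind_id length mismatch")
  # normalize half-missing genotypes to fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  ok <- is.na(a1) | a1 > 0L
  ok2 <- is.na(a2) | a2 > 0L
  if (!all(ok) || !all(ok2))
    stop("non-missing alleles must be positive repeat counts")
  dimnames(a1) <- dimnames(a2) <- list(ind_id, loci)
  structure(list(a1 = a1, a2 = a2, pop = factor(pop),
                 loci = loci, ind_id = ind_id,
                 marker_class = marker_class),
            class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  cat("microsat_dataset:", nrow(x$a1), "individuals x", ncol(x$a1), "loci\n")
  cat("populations:",
      paste(sprintf("%s (%d)", levels(x$pop), tabulate(x$pop)), collapse = ", "),
      "\n")
  nmiss <- sum(is.na(x$a1))
  cat(sprintf("missing genotypes: %d (%.1f%%); non-microsat loci: %d\n",
              nmiss, 100 * nmiss / length(x$a1),
              sum(x$marker_class != "microsat")))
  invisible(x)
}

#' @export
dim.microsat_dataset <- function(x) dim(x$a1)

n_loci <- function(d) ncol(d$a1)
n_ind <- function(d) nrow(d$a1)

#' Subset a microsatellite dataset
#'
#' @param x a [microsat_dataset()].
#' @param i individual index (row) selection.
#' @param j locus (column) selection.
#' @param ... ignored.
#' @return A `microsat_dataset` restricted to the selected individuals/loci.
#' @export
`[.microsat_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  microsat_dataset(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                   pop = droplevels(x$pop[i]),
                   loci = x$loci[j][seq_len(ncol(x$a1[i, j, drop = FALSE]))],
                   ind_id = x$ind_id[i],
                   marker_class = x$marker_class[j])
}

#' @exportS3Method base::all.equal
all.equal.microsat_dataset <- function(target, current, ...) {
  msg <- character()
  for (f in c("a1", "a2", "loci", "ind_id", "marker_class")) {
    ae <- all.equal(unname(target[[f]]), unname(current[[f]]), ...)
    if (!isTRUE(ae)) msg <- c(msg, paste0(f, ": ", ae))
  }
  if (!identical(as.character(target$pop), as.character(current$pop)))
    msg <- c(msg, "pop labels differ")
  if (length(msg)) msg else TRUE
}

# interleave genotypes into a haplotype matrix (2*n_ind rows), with a
# 0-based group index per row following the order of `pops` (or the
# factor levels); used by the statistics kernels
hap_matrix <- function(d, pops = levels(d$pop)) {
  keep <- d$pop %in% pops
  a1 <- d$a1[keep, , drop = FALSE]
  a2 <- d$a2[keep, , drop = FALSE]
  pop <- factor(as.character(d$pop[keep]), levels = pops)
  n <- nrow(a1)
  hap <- matrix(NA_integer_, 2L * n, ncol(a1))
  hap[seq(1L, 2L * n, 2L), ] <- a1
  hap[seq(2L, 2L * n, 2L), ] <- a2
  grp <- rep(as.integer(pop) - 1L, each = 2L)
  list(hap = hap, group = grp, n_groups = length(pops))
}
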