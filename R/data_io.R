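#' Read a microsatellite genotype table
#'
#' Supports two plain-text dialects:
#' * `"tsv"`: one row per individual; columns `ind`, `pop`, then two
#'   columns per locus named `<locus>.1` and `<locus>.2`. An optional
#'   comment line `# marker_class: ...` preserves the per-locus marker
#'   class across round trips.
#' * `"genepop"`: the classical GenePop format (title line, one locus
#'   name per line, `POP` separators, `id , aaabbb ...` rows with
#'   3-digit alleles, `000` missing). Populations are labelled `pop1`,
#'   `pop2`, ... in file order.
#'
#' Any of the `missing_codes` on input is normalized to the single
#' internal missing value (`NA`).
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"genepop"`.
#' @param missing_codes character vector of tokens treated as missing in
#'   the TSV dialect.
#' @return A [microsat_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "genepop"),
                           missing_codes = c("-9", "0", "NA")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_genotypes_tsv(path, missing_codes)
  else read_genotypes_genepop(path)
}

read_genotypes_tsv <- function(path, missing_codes) {
  lines <- readLines(path)
  mc <- NULL
  cm <- grepl("^# marker_class:", lines)
  if (any(cm))
    mc <- strsplit(sub("^# marker_class:\\s*", "", lines[which(cm)[1]]), ",")[[1]]
  lines <- lines[!grepl("^#", lines)]
  tab <- read.table(text = lines, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 4 || ncol(tab) %% 2 != 0)
    stop("malformed TSV genotype table: need ind, pop and locus column pairs")
  gcols <- names(tab)[-(1:2)]
  loci <- unique(sub("\\.[12]$", "", gcols))
  if (!identical(gcols, as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))))
    stop("locus columns must come in <locus>.1, <locus>.2 pairs")
  g <- as.matrix(tab[, -(1:2), drop = FALSE])
  g[g %in% missing_codes] <- NA
  suppressWarnings(gi <- matrix(as.integer(g), nrow(g), ncol(g)))
  if (any(is.na(gi) & !is.na(g))) stop("non-integer allele entry in table")
  a1 <- gi[, seq(1L, ncol(gi), 2L), drop = FALSE]
  a2 <- gi[, seq(2L, ncol(gi), 2L), drop = FALSE]
  microsat_dataset(a1, a2, pop = tab$pop, loci = loci, ind_id = tab$ind,
                   marker_class = mc)
}

read_genotypes_genepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("malformed GenePop file")
  body <- lines[-1]  # drop title
  is_pop <- toupper(body) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GenePop file has no POP line")
  loci <- unlist(strsplit(body[seq_len(first_pop - 1)], ",\\s*"))
  loci <- trimws(loci[nzchar(trimws(loci))])
  a1 <- list(); a2 <- list(); pop <- character(); ids <- character()
  pop_idx <- 0L
  for (ln in body[first_pop:length(body)]) {
    if (toupper(ln) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) != 2) stop("malformed GenePop individual row: ", ln)
    id <- trimws(parts[1])
    alleles <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(alleles) != length(loci))
      stop("inconsistent locus count for individual ", id)
    if (!all(nchar(alleles) %in% c(4L, 6L)))
      stop("GenePop alleles must be 2- or 3-digit pairs")
    w <- nchar(alleles[1]) / 2
    x1 <- as.integer(substr(alleles, 1, w))
    x2 <- as.integer(substr(alleles, w + 1, 2 * w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    a1[[length(a1) + 1L]] <- x1; a2[[length(a2) + 1L]] <- x2
    pop <- c(pop, paste0("pop", pop_idx)); ids <- c(ids, id)
  }
  microsat_dataset(do.call(rbind, a1), do.call(rbind, a2),
                   pop = factor(pop, levels = unique(pop)),
                   loci = loci, ind_id = ids)
}

#' Write a microsatellite genotype table
#'
#' Inverse of [read_genotypes()]; `read(write(d)) == d` up to marker
#' class for the GenePop dialect (which cannot represent it).
#'
#' @param d a [microsat_dataset()].
#' @param path output file.
#' @param dialect `"tsv"` or `"genepop"`.
#' @param missing_code token written for missing genotypes (TSV only).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(d, path, dialect = c("tsv", "genepop"),
                            missing_code = "-9") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    k <- ncol(d$a1)
    g <- matrix("", nrow(d$a1), 2L * k)
    g[, seq(1L, 2L * k, 2L)] <- ifelse(is.na(d$a1), missing_code, d$a1)
    g[, seq(2L, 2L * k, 2L)] <- ifelse(is.na(d$a2), missing_code, d$a2)
    colnames(g) <- as.vector(rbind(paste0(d$loci, ".1"), paste0(d$loci, ".2")))
    out <- data.frame(ind = d$ind_id, pop = as.character(d$pop), g,
                      check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# marker_class: ", paste(d$marker_class, collapse = ",")),
               con)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (any(d$a1 > 999 | d$a2 > 999, na.rm = TRUE))
      stop("GenePop dialect limited to 3-digit repeat counts")
    fmt <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("msatABC genotypes", d$loci), con)
    for (p in levels(d$pop)) {
      writeLines("POP", con)
      rows <- which(d$pop == p)
      for (i in rows) {
        writeLines(paste0(d$ind_id[i], " ,  ",
                          paste0(fmt(d$a1[i, ]), fmt(d$a2[i, ]), collapse = " ")),
                   con)
      }
    }
  }
  invisible(path)
}

#' Filter markers by missingness and marker class
#'
#' Removes loci whose missing-genotype fraction (computed over the
#' individuals present in `d`; subset first to scope the filter to a
#' group of populations) exceeds `max_missing`, then removes remaining
#' non-microsatellite (e.g. indel) markers. Idempotent.
#'
#' @param d a [microsat_dataset()].
#' @param max_missing maximum tolerated missing fraction per locus
#'   (default 0.5).
#' @return A list with `data` (the filtered dataset) and `report`, a
#'   one-row data.frame with columns `loci_in`, `loci_removed_missingness`,
#'   `loci_removed_class`, `loci_out`.
#' @export
filter_markers <- function(d, max_missing = 0.5) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  if (ncol(d$a1) == 0L || nrow(d$a1) == 0L) stop("empty dataset")
  miss_frac <- colMeans(is.na(d$a1))
  rm_miss <- miss_frac > max_missing
  rm_class <- !rm_miss & d$marker_class != "microsat"
  keep <- !rm_miss & !rm_class
  report <- data.frame(loci_in = ncol(d$a1),
                       loci_removed_missingness = sum(rm_miss),
                       loci_removed_class = sum(rm_class),
                       loci_out = sum(keep))
  list(data = d[, keep], report = report)
}

#' Write a numeric results table with companion metadata
#'
#' Tab-separated plain text with a header naming every column and
#' numbers rendered at 17 significant digits (lossless for doubles); a
#' companion `<path>.meta.json` records the seed, configuration and
#' package version.
#'
#' @param x matrix or data.frame of results (reference table, posterior
#'   draws, summary vector as a 1-row table, ...).
#' @param path output file.
#' @param meta named list of metadata (seed, config, ...) stored in the
#'   companion JSON.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, meta = list()) {
  x <- as.data.frame(x)
  if (nrow(x) == 0L) stop("refusing to write an empty table")
  fmt <- lapply(x, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col))
  out <- as.data.frame(fmt, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta$package_version <- as.character(utils::packageVersion("msatABC"))
  meta$columns <- names(x)
  meta$n_rows <- nrow(x)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a table written by [write_result_table()]
#'
#' @param path file to read.
#' @return A data.frame; the companion metadata (if present) is attached
#'   as attribute `"meta"`.
#' @export
read_result_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) attr(x, "meta") <- jsonlite::read_json(mp)
  x
}
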