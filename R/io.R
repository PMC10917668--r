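# Reading, writing and validating the codominant genotype CSV dialect
# (GenAlEx-style layout): metadata columns `sample_id,population[,sex]`
# followed by two adjacent columns per locus, `<locus>` and `<locus>.2`.
# Alleles are text tokens; "0" or an empty cell means missing.

META_COLUMNS <- c("sample_id", "population", "sex")

#' Read a codominant STR genotype table from CSV
#'
#' The expected layout is `sample_id,population[,sex]` followed by two
#' adjacent columns per locus named `<locus>` and `<locus>.2`. Allele cells
#' hold text tokens (digits with an optional letter suffix, e.g. `"12"` or
#' `"10in"`); `"0"` or an empty cell marks a missing allele. Allele order
#' within a pair is canonicalized on read (ascending size, ties by token), so
#' a file with swapped allele columns reads to an identical table.
#'
#' @param path path to a CSV file.
#' @param panel optional data.frame with `locus`, `motif_length`,
#'   `marker_class` columns overriding the default panel metadata inferred
#'   from the header (all loci autosomal, unknown motif).
#' @return A [genotype_table()].
#' @examples
#' tab <- simulate_study(sim_config(n_loci = 3, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_genotypes(tab, f)
#' read_genotypes(f)
#' @export
read_genotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) .stop_arg("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  nm <- names(raw)
  meta <- intersect(META_COLUMNS, nm)
  if (!all(c("sample_id", "population") %in% meta)) {
    .stop_arg("header must start with sample_id,population[,sex]")
  }
  locus_cols <- setdiff(nm, meta)
  if (length(locus_cols) %% 2L != 0L) {
    .stop_arg("odd number of allele columns after metadata; last column is ",
              sQuote(locus_cols[length(locus_cols)], q = FALSE))
  }
  first <- locus_cols[seq(1L, length(locus_cols), by = 2L)]
  second <- locus_cols[seq(2L, length(locus_cols), by = 2L)]
  bad <- second != paste0(first, ".2")
  if (any(bad)) {
    .stop_arg("malformed locus columns near ", sQuote(first[bad][1L], q = FALSE),
              ": expected ", sQuote(paste0(first[bad][1L], ".2"), q = FALSE),
              ", found ", sQuote(second[bad][1L], q = FALSE),
              " (each locus must occupy exactly two adjacent columns)")
  }
  loci <- first
  samples <- data.frame(sample_id = raw$sample_id,
                        population = raw$population,
                        sex = if ("sex" %in% meta) raw$sex else "unknown",
                        stringsAsFactors = FALSE)
  genotypes <- lapply(loci, function(l) {
    cbind(raw[[l]], raw[[paste0(l, ".2")]])
  })
  names(genotypes) <- loci
  if (is.null(panel)) {
    panel <- data.frame(locus = loci, motif_length = NA_integer_,
                        marker_class = "autosomal", stringsAsFactors = FALSE)
  } else {
    panel <- as.data.frame(panel, stringsAsFactors = FALSE)
    if (!setequal(panel$locus, loci)) {
      .stop_arg("supplied panel does not match header loci")
    }
    panel <- panel[match(loci, panel$locus), , drop = FALSE]
  }
  genotype_table(panel, samples, genotypes)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotypes()]: the written file round-trips token-for-token
#' (missing alleles are written as `0`).
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  out <- data.frame(sample_id = table$samples$sample_id,
                    population = table$samples$population,
                    sex = table$samples$sex,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in table$panel$locus) {
    m <- table$genotypes[[l]]
    m[is.na(m)] <- "0"
    out[[l]] <- m[, 1L]
    out[[paste0(l, ".2")]] <- m[, 2L]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a genotype table
#'
#' Screens a table for data-quality problems without raising errors: issues
#' are returned as rows, ready for an audit report. Checks are
#' \itemize{
#'   \item `error`: half-missing genotypes (exactly one allele of a pair
#'     missing) — such genotypes are treated as fully missing by every
#'     statistic;
#'   \item `error`: allele tokens violating the label grammar
#'     (digits + optional letter suffix);
#'   \item `warning`: autosomal loci with zero typed samples in some
#'     population.
#' }
#'
#' @param table a [genotype_table()].
#' @return A data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `sample_id`, `locus`, `message`; zero rows for a clean table.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  issues <- list()
  add <- function(severity, sample_id, locus, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, sample_id = sample_id, locus = locus,
      message = message, stringsAsFactors = FALSE)
  }
  ids <- table$samples$sample_id
  pops <- unique(table$samples$population)
  for (l in table$panel$locus) {
    m <- table$genotypes[[l]]
    half <- xor(is.na(m[, 1L]), is.na(m[, 2L]))
    for (i in which(half)) {
      add("error", ids[i], l, "half-missing genotype (one allele of the pair)")
    }
    tok <- m[!is.na(m)]
    bad <- unique(tok[!grepl(ALLELE_PATTERN, tok)])
    if (length(bad)) {
      rows <- which(apply(matrix(m %in% bad, ncol = 2L), 1L, any))
      for (i in rows) {
        add("error", ids[i], l,
            paste0("allele label violates grammar: ",
                   .quote_join(intersect(m[i, ], bad))))
      }
    }
    if (table$panel$marker_class[match(l, table$panel$locus)] == "autosomal") {
      typed <- !is.na(m[, 1L]) & !is.na(m[, 2L])
      for (p in pops) {
        if (!any(typed & table$samples$population == p)) {
          add("warning", NA_character_, l,
              paste0("no typed samples in population ", sQuote(p, q = FALSE)))
        }
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(severity = character(), sample_id = character(),
                      locus = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
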