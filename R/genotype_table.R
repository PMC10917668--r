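# The genotype_table class: a panel of STR loci plus sample records with
# unordered allele pairs. This is the universal input of every analysis in
# the package.

ALLELE_PATTERN <- "^[0-9]+[A-Za-z]*$"
MISSING_TOKENS <- c("0", "", NA_character_)

#' Parse STR allele labels
#'
#' An allele label is one or more digits (a size class: repeat count or
#' fragment length) optionally followed by a letter suffix that distinguishes
#' sequence variants of the same size class, e.g. the insertion-carrying
#' `"10in"`..`"14in"` alleles seen alongside plain `"10"`..`"14"`. Labels are
#' compared as opaque tokens; the numeric part is used only for size ordering.
#'
#' @param tokens character vector of allele labels.
#' @return A data.frame with columns `token`, `size` (integer leading digits,
#'   `NA` for malformed tokens) and `suffix` (possibly empty string).
#' @examples
#' parse_alleles(c("12", "10in", "7"))
#' @export
parse_alleles <- function(tokens) {
  tokens <- as.character(tokens)
  ok <- grepl(ALLELE_PATTERN, tokens)
  size <- rep(NA_integer_, length(tokens))
  suffix <- rep(NA_character_, length(tokens))
  size[ok] <- as.integer(sub("^([0-9]+).*$", "\\1", tokens[ok]))
  suffix[ok] <- sub("^[0-9]+", "", tokens[ok])
  data.frame(token = tokens, size = size, suffix = suffix,
             stringsAsFactors = FALSE)
}

# order allele tokens by (parsed size, token); malformed tokens sort last
.allele_order <- function(tokens) {
  p <- parse_alleles(tokens)
  order(is.na(p$size), p$size, p$token)
}

# canonicalize an n x 2 character matrix of allele pairs: ascending parsed
# size, ties by token; rows with any NA are left untouched
.canon_pairs <- function(m) {
  if (nrow(m) == 0L) return(m)
  p1 <- parse_alleles(m[, 1L])
  p2 <- parse_alleles(m[, 2L])
  # malformed tokens (no parsable size) sort after well-formed ones
  k1 <- ifelse(is.na(p1$size), .Machine$integer.max, p1$size)
  k2 <- ifelse(is.na(p2$size), .Machine$integer.max, p2$size)
  both <- !is.na(m[, 1L]) & !is.na(m[, 2L])
  swap <- both & (k2 < k1 | (k2 == k1 & m[, 2L] < m[, 1L]))
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- m[swap, 1L]
    m[swap, 1L] <- m[swap, 2L]
    m[swap, 2L] <- tmp
  }
  m
}

#' Construct a genotype table
#'
#' Bundles a locus panel, per-sample metadata and genotypes into a
#' `genotype_table`, the input object of all analyses in the package.
#' Allele pairs are canonicalized (ascending size, then token). Structural
#' requirements (unique sample ids, matching dimensions) are enforced here;
#' data-quality problems are reported by [validate_table()] instead of
#' raising errors.
#'
#' @param panel data.frame with columns `locus` (unique names), and optionally
#'   `motif_length` (2, 3 or 4 base pairs, `NA` allowed) and `marker_class`
#'   (`"autosomal"` or `"sex"`, default autosomal).
#' @param samples data.frame with columns `sample_id` (unique), `population`,
#'   and optionally `sex` (`"male"`, `"female"` or `"unknown"`).
#' @param genotypes named list, one element per panel locus, each an
#'   `nrow(samples)` x 2 character matrix of allele tokens (`NA` = missing).
#' @return An object of class `genotype_table`.
#' @seealso [read_genotypes()], [validate_table()]
#' @export
genotype_table <- function(panel, samples, genotypes) {
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"locus" %in% names(panel)) .stop_arg("'panel' needs a 'locus' column")
  panel$locus <- as.character(panel$locus)
  if (anyDuplicated(panel$locus)) {
    .stop_arg("duplicated locus names in panel: ",
              .quote_join(panel$locus[duplicated(panel$locus)]))
  }
  if (is.null(panel$motif_length)) panel$motif_length <- NA_integer_
  panel$motif_length <- as.integer(panel$motif_length)
  bad_motif <- !is.na(panel$motif_length) & !panel$motif_length %in% 2:4
  if (any(bad_motif)) {
    .stop_arg("motif_length must be 2, 3 or 4 (locus ",
              .quote_join(panel$locus[bad_motif]), ")")
  }
  if (is.null(panel$marker_class)) panel$marker_class <- "autosomal"
  if (!all(panel$marker_class %in% c("autosomal", "sex"))) {
    .stop_arg("marker_class must be 'autosomal' or 'sex'")
  }
  if (!all(c("sample_id", "population") %in% names(samples))) {
    .stop_arg("'samples' needs 'sample_id' and 'population' columns")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)
  if (anyDuplicated(samples$sample_id)) {
    .stop_arg("duplicated sample ids: ",
              .quote_join(unique(samples$sample_id[duplicated(samples$sample_id)])))
  }
  if (is.null(samples$sex)) samples$sex <- rep("unknown", nrow(samples))
  n <- nrow(samples)
  if (!setequal(names(genotypes), panel$locus)) {
    .stop_arg("genotype list names must match panel loci")
  }
  genotypes <- genotypes[panel$locus]
  genotypes <- lapply(genotypes, function(m) {
    m <- matrix(as.character(m), ncol = 2L)
    if (nrow(m) != n) .stop_arg("each genotype matrix needs one row per sample")
    m[!is.na(m) & m %in% MISSING_TOKENS] <- NA_character_
    dimnames(m) <- NULL
    .canon_pairs(m)
  })
  structure(list(panel = panel, samples = samples, genotypes = genotypes),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  npop <- length(unique(x$samples$population))
  aut <- sum(x$panel$marker_class == "autosomal")
  cat(sprintf("genotype_table: %d samples, %d loci (%d autosomal), %d population%s\n",
              nrow(x$samples), nrow(x$panel), aut, npop,
              if (npop == 1L) "" else "s"))
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  loci:", paste(utils::head(x$panel$locus, 10L), collapse = ", "),
      if (nrow(x$panel) > 10L) "..." else "", "\n")
  invisible(x)
}

#' List panel loci
#'
#' @param table a [genotype_table()].
#' @param autosomal_only drop sex markers (the default for all statistics)?
#' @return Character vector of locus names.
#' @export
panel_loci <- function(table, autosomal_only = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  p <- table$panel
  if (autosomal_only) p <- p[p$marker_class == "autosomal", , drop = FALSE]
  p$locus
}

#' List population labels
#'
#' @param table a [genotype_table()].
#' @return Character vector of distinct population labels, in order of first
#'   appearance.
#' @export
population_labels <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  unique(table$samples$population)
}

# n x 2 allele matrix for one locus, optionally restricted to a population;
# typed_only drops rows with any missing allele
.locus_matrix <- function(table, locus, population = NULL, typed_only = TRUE) {
  if (!locus %in% table$panel$locus) {
    .stop_arg("unknown locus ", sQuote(locus, q = FALSE))
  }
  m <- table$genotypes[[locus]]
  keep <- rep(TRUE, nrow(table$samples))
  if (!is.null(population)) keep <- table$samples$population %in% population
  m <- m[keep, , drop = FALSE]
  if (typed_only) m <- m[!is.na(m[, 1L]) & !is.na(m[, 2L]), , drop = FALSE]
  m
}

#' Subset a genotype table by population
#'
#' @param table a [genotype_table()].
#' @param populations character vector of population labels to keep.
#' @return A new `genotype_table` holding only the selected samples.
#' @export
subset_populations <- function(table, populations) {
  stopifnot(inherits(table, "genotype_table"))
  keep <- table$samples$population %in% populations
  genotype_table(table$panel, table$samples[keep, , drop = FALSE],
                 lapply(table$genotypes, function(m) m[keep, , drop = FALSE]))
}
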