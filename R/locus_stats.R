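# Per-locus, per-population allele frequencies and polymorphism summaries:
# Na, effective allele number Ne = 1/sum(p^2), observed heterozygosity HO,
# unbiased expected heterozygosity HE, and Botstein's polymorphism
# information content (PIC).

#' Allele frequency spectrum of a locus in a population
#'
#' Counts alleles over typed individuals only: a genotype with any missing
#' allele contributes to neither numerator nor denominator, so frequencies
#' are allele counts over `2 * n_typed`.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population population label, or `NULL` to pool all samples.
#' @return An object of class `allele_spectrum`: a list with `locus`,
#'   `population`, `n_typed`, `counts` (named integer) and `freqs` (named
#'   numeric summing to 1), alleles ordered by size then token. With zero
#'   typed individuals the spectrum is empty (`n_typed = 0`), not an error.
#' @export
allele_frequencies <- function(table, locus, population = NULL) {
  m <- .locus_matrix(table, locus, population)
  n_typed <- nrow(m)
  if (n_typed == 0L) {
    counts <- integer(0)
  } else {
    tab <- table(c(m[, 1L], m[, 2L]))
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts <- counts[.allele_order(names(counts))]
  }
  structure(list(locus = locus,
                 population = if (is.null(population)) "all" else
                   paste(population, collapse = "+"),
                 n_typed = n_typed,
                 counts = counts,
                 freqs = if (n_typed > 0L) counts / (2 * n_typed) else
                   numeric(0)),
            class = "allele_spectrum")
}

#' @export
print.allele_spectrum <- function(x, ...) {
  cat(sprintf("allele_spectrum: locus %s, population %s, n_typed = %d\n",
              x$locus, x$population, x$n_typed))
  if (x$n_typed > 0L) print(round(x$freqs, 4))
  invisible(x)
}

#' Polymorphism information content (PIC)
#'
#' Botstein's marker informativeness measure,
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2.}
#'
#' @param spectrum an [allele_frequencies()] result (or a bare numeric vector
#'   of allele frequencies).
#' @return PIC in `[0, 1]`; always `<= 1 - sum(p^2)`.
#' @export
pic <- function(spectrum) {
  p <- if (inherits(spectrum, "allele_spectrum")) spectrum$freqs else spectrum
  if (!length(p)) return(NA_real_)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - s4)
}

#' Per-locus polymorphism summary
#'
#' Computes the classical marker-panel descriptors for one locus in one
#' population: allele count `Na`, effective allele number `Ne = 1/sum(p^2)`,
#' observed heterozygosity `HO` (heterozygous typed individuals / typed
#' individuals), expected heterozygosity `HE` and `PIC`. By default `HE` uses
#' the unbiased small-sample form `2n/(2n-1) * (1 - sum(p^2))`; set
#' `unbiased = FALSE` for the plain gene-diversity `1 - sum(p^2)`.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population population label, or `NULL` to pool.
#' @param unbiased use the small-sample correction for `HE`?
#' @return A one-row data.frame with `locus`, `population`, `n_typed`, `Na`,
#'   `Ne`, `HO`, `HE`, `PIC`. `HE` is `NA` when fewer than 2 typed
#'   individuals are available.
#' @export
locus_summary <- function(table, locus, population = NULL, unbiased = TRUE) {
  spec <- allele_frequencies(table, locus, population)
  m <- .locus_matrix(table, locus, population)
  n <- spec$n_typed
  p <- spec$freqs
  if (n == 0L) {
    return(data.frame(locus = locus, population = spec$population,
                      n_typed = 0L, Na = 0L, Ne = NA_real_, HO = NA_real_,
                      HE = NA_real_, PIC = NA_real_, stringsAsFactors = FALSE))
  }
  s2 <- sum(p^2)
  he <- if (n < 2L) NA_real_ else if (unbiased) (2 * n / (2 * n - 1)) * (1 - s2)
        else 1 - s2
  data.frame(locus = locus, population = spec$population, n_typed = n,
             Na = length(p), Ne = 1 / s2,
             HO = mean(m[, 1L] != m[, 2L]),
             HE = he, PIC = pic(spec), stringsAsFactors = FALSE)
}

#' Summary statistics for every locus, by population
#'
#' Convenience wrapper applying [locus_summary()] over the autosomal panel,
#' one row per (locus, population); the reporting surface behind panel tables
#' of Na/Ne/HO/HE/PIC.
#'
#' @param table a [genotype_table()].
#' @param by_population if `FALSE`, pool all samples instead.
#' @param unbiased passed to [locus_summary()].
#' @return A data.frame, one row per locus x population, plus per-population
#'   mean rows (locus `"mean"`).
#' @export
summarize_loci <- function(table, by_population = TRUE, unbiased = TRUE) {
  loci <- panel_loci(table)
  pops <- if (by_population) population_labels(table) else list(NULL)
  out <- list()
  for (p in pops) {
    rows <- do.call(rbind, lapply(loci, function(l)
      locus_summary(table, l, p, unbiased = unbiased)))
    means <- data.frame(locus = "mean", population = rows$population[1L],
                        n_typed = NA_integer_,
                        Na = mean(rows$Na), Ne = mean(rows$Ne),
                        HO = mean(rows$HO, na.rm = TRUE),
                        HE = mean(rows$HE, na.rm = TRUE),
                        PIC = mean(rows$PIC, na.rm = TRUE),
                        stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- rbind(rows, means)
  }
  do.call(rbind, out)
}

#' Major-allele dominance flag
#'
#' Loci dominated by one frequent allele carry little identification power;
#' panel triage screens them out. A locus-population spectrum is `dominated`
#' when its most frequent allele reaches `threshold`.
#'
#' @param spectrum an [allele_frequencies()] result.
#' @param threshold dominance frequency threshold (default 0.5).
#' @return A list with `max_allele`, `max_freq` and logical `dominated`.
#' @export
major_allele_flag <- function(spectrum, threshold = 0.5) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  if (spectrum$n_typed == 0L) {
    return(list(max_allele = NA_character_, max_freq = NA_real_,
                dominated = NA))
  }
  i <- which.max(spectrum$freqs)
  list(max_allele = names(spectrum$freqs)[i],
       max_freq = unname(spectrum$freqs[i]),
       dominated = unname(spectrum$freqs[i]) >= threshold)
}
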