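# Theta-corrected genotype match probabilities (NRC-II style subdivision
# correction), multi-locus cumulative match probabilities in increasing-FST
# order, and cohort-averaged match probabilities with and without theta.

#' Theta-corrected single-locus genotype probability (closed form)
#'
#' The subdivision-aware match probability of a genotype given population
#' allele frequencies and a subdivision coefficient `theta`:
#' \deqn{P_{hom} = \frac{[2\theta + (1-\theta)p][3\theta + (1-\theta)p]}
#'   {(1+\theta)(1+2\theta)}}
#' \deqn{P_{het} = \frac{2[\theta + (1-\theta)p][\theta + (1-\theta)q]}
#'   {(1+\theta)(1+2\theta)}}
#' At `theta = 0` these reduce exactly to the product rule `p^2` and `2pq`.
#' The homozygote form is conservative (never below `p^2`); the heterozygote
#' form is not uniformly so (e.g. `p = q = 0.5, theta = 0.2` gives 0.4286,
#' below `2pq = 0.5`).
#'
#' @param p allele frequency (vectorized).
#' @param q second allele frequency for a heterozygote, or `NA`/missing for
#'   a homozygote.
#' @param theta subdivision coefficient in `[0, 1)`.
#' @return Genotype probability in `(0, 1]`.
#' @export
theta_match_prob <- function(p, q = NA_real_, theta = 0) {
  if (any(theta < 0 | theta >= 1)) .stop_arg("theta must be in [0, 1)")
  n <- max(length(p), length(q), length(theta))
  p <- rep_len(p, n)
  q <- rep_len(q, n)
  theta <- rep_len(theta, n)
  denom <- (1 + theta) * (1 + 2 * theta)
  hom <- (2 * theta + (1 - theta) * p) * (3 * theta + (1 - theta) * p) / denom
  het <- 2 * (theta + (1 - theta) * p) * (theta + (1 - theta) * q) / denom
  out <- ifelse(is.na(q), hom, het)
  if (n == 1L) out[[1L]] else out
}

#' Theta-corrected match probability of a genotype against a spectrum
#'
#' Looks up the genotype's allele frequencies in an allele spectrum (alleles
#' absent from the reference receive the rare-allele frequency `1/(2n + 1)`)
#' and applies [theta_match_prob()].
#'
#' @param genotype character vector of two allele tokens.
#' @param spectrum an [allele_frequencies()] result.
#' @param theta subdivision coefficient in `[0, 1)`.
#' @return Genotype probability in `(0, 1]`.
#' @export
single_locus_match_prob <- function(genotype, spectrum, theta = 0) {
  stopifnot(inherits(spectrum, "allele_spectrum"), length(genotype) == 2L)
  rare <- .rare_freq(spectrum$n_typed)
  f <- spectrum$freqs
  look <- function(al) if (is.na(f[al]) || f[al] <= 0) rare else f[[al]]
  p <- look(genotype[1L])
  if (genotype[1L] == genotype[2L]) {
    theta_match_prob(p, NA_real_, theta)
  } else {
    theta_match_prob(p, look(genotype[2L]), theta)
  }
}

#' Multi-locus match probability report
#'
#' Computes per-locus genotype probabilities for one sample, with and
#' without the theta correction, with loci ordered by ascending theta (ties
#' broken by locus name), and the running cumulative products along that
#' order — the standard layout of a forensic match-probability table.
#' Reference allele frequencies are taken from `population` (default: all
#' samples pooled).
#'
#' @param table a [genotype_table()].
#' @param sample_id sample identifier.
#' @param thetas a data.frame with `locus` and `theta` columns (from
#'   [per_locus_theta()]), or a single number applied to every locus
#'   (NRC-style fixed conservative theta).
#' @param population reference population label(s), `NULL` to pool all.
#' @param loci loci to report (default: autosomal panel); loci where the
#'   sample is untyped are dropped.
#' @param use_theta if `FALSE`, the with-theta columns are computed at
#'   `theta = 0` (so both column pairs coincide).
#' @return An object of class `match_report`: a data.frame with columns
#'   `locus`, `theta`, `genotype`, `p_no_theta`, `cum_no_theta`,
#'   `p_with_theta`, `cum_with_theta`, ordered by ascending theta.
#' @export
multilocus_match_probability <- function(table, sample_id, thetas,
                                         population = NULL, loci = NULL,
                                         use_theta = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(loci)) loci <- panel_loci(table)
  row <- match(sample_id, table$samples$sample_id)
  if (is.na(row)) .stop_arg("unknown sample ", sQuote(sample_id, q = FALSE))
  if (is.numeric(thetas) && length(thetas) == 1L) {
    thetas <- data.frame(locus = loci, theta = thetas,
                         stringsAsFactors = FALSE)
  }
  th <- thetas$theta[match(loci, thetas$locus)]
  keep <- !is.na(th)
  loci <- loci[keep]
  th <- th[keep]
  ord <- order(th, loci)
  loci <- loci[ord]
  th <- th[ord]
  rows <- list()
  for (i in seq_along(loci)) {
    pair <- table$genotypes[[loci[i]]][row, ]
    if (anyNA(pair)) next
    spec <- allele_frequencies(table, loci[i], population)
    p0 <- single_locus_match_prob(pair, spec, 0)
    p1 <- single_locus_match_prob(pair, spec,
                                  if (use_theta) th[i] else 0)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = loci[i], theta = th[i],
      genotype = paste(pair, collapse = "/"),
      p_no_theta = p0, p_with_theta = p1, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    .stop_arg("sample ", sQuote(sample_id, q = FALSE),
              " is typed at none of the requested loci")
  }
  out <- do.call(rbind, rows)
  out$cum_no_theta <- cumprod(out$p_no_theta)
  out$cum_with_theta <- cumprod(out$p_with_theta)
  out <- out[c("locus", "theta", "genotype", "p_no_theta", "cum_no_theta",
               "p_with_theta", "cum_with_theta")]
  class(out) <- c("match_report", "data.frame")
  out
}

#' @export
print.match_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("p_no_theta", "cum_no_theta", "p_with_theta",
                "cum_with_theta")) {
    y[[col]] <- signif(y[[col]], 3)
  }
  y$theta <- round(y$theta, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Cohort-averaged multi-locus match probability
#'
#' Averages the final cumulative match probability over all samples fully
#' typed at the panel, with and without the theta correction. The default
#' geometric mode averages on the log scale (the natural average for
#' multiplicative frequencies spanning orders of magnitude); the arithmetic
#' mode is provided for sensitivity analysis.
#'
#' @param table a [genotype_table()].
#' @param thetas per-locus thetas as in [multilocus_match_probability()].
#' @param population reference population label(s), `NULL` to pool all.
#' @param loci panel loci (default: autosomal panel).
#' @param mode `"geometric"` (default) or `"arithmetic"`.
#' @return An object of class `cohort_average`: list with
#'   `mean_freq_no_theta`, `mean_freq_with_theta`, `mode`, `n_samples`.
#' @export
cohort_average_match_probability <- function(table, thetas,
                                             population = NULL, loci = NULL,
                                             mode = c("geometric",
                                                      "arithmetic")) {
  mode <- match.arg(mode)
  if (is.null(loci)) loci <- panel_loci(table)
  typed_all <- Reduce(`&`, lapply(loci, function(l)
    !is.na(table$genotypes[[l]][, 1L]) & !is.na(table$genotypes[[l]][, 2L])))
  ids <- table$samples$sample_id[typed_all]
  if (!length(ids)) {
    return(structure(list(mean_freq_no_theta = NA_real_,
                          mean_freq_with_theta = NA_real_,
                          mode = mode, n_samples = 0L),
                     class = "cohort_average"))
  }
  f0 <- f1 <- numeric(length(ids))
  for (i in seq_along(ids)) {
    rep_i <- multilocus_match_probability(table, ids[i], thetas,
                                          population, loci)
    f0[i] <- rep_i$cum_no_theta[nrow(rep_i)]
    f1[i] <- rep_i$cum_with_theta[nrow(rep_i)]
  }
  avg <- function(x) {
    if (mode == "geometric") 10^mean(log10(x)) else mean(x)
  }
  structure(list(mean_freq_no_theta = avg(f0),
                 mean_freq_with_theta = avg(f1),
                 mode = mode, n_samples = length(ids)),
            class = "cohort_average")
}

#' @export
print.cohort_average <- function(x, ...) {
  cat(sprintf(
    "Cohort-averaged match probability (%s mean over %d fully typed samples)\n",
    x$mode, x$n_samples))
  cat(sprintf("  without theta: %.3g\n  with theta:    %.3g\n",
              x$mean_freq_no_theta, x$mean_freq_with_theta))
  invisible(x)
}
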