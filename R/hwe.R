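# Hardy-Weinberg exact testing (Monte-Carlo, conditional on allele counts),
# Bonferroni adjustment, null-allele estimators and a homozygote-excess scan
# used as a genotyping-error screen for dinucleotide loci.

# genotype id for an unordered pair of allele codes (1-based)
.pair_id <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  hi * (hi - 1L) / 2L + lo
}

# Monte-Carlo exact HWE p-value on an n x 2 integer matrix of allele codes.
# Test statistic: log conditional probability of the genotype array given the
# allele counts, which up to an array-independent constant is
# h*log(2) - sum(lgamma(n_ij + 1)) with h the heterozygote count. The p-value
# is the proportion of allele-shuffles whose array is no more probable than
# the observed one, with the +1/+1 small-sample correction.
.hwe_mc <- function(g, n_shuffles) {
  n <- nrow(g)
  k <- max(g)
  G <- k * (k + 1L) / 2L
  alleles <- c(g[, 1L], g[, 2L])
  stat_of <- function(a, b) {
    h <- sum(a != b)
    cnt <- tabulate(.pair_id(a, b), nbins = G)
    h * log(2) - sum(lgamma(cnt + 1))
  }
  stat_obs <- stat_of(g[, 1L], g[, 2L])
  B <- n_shuffles
  perm <- matrix(0L, 2L * n, B)
  for (j in seq_len(B)) perm[, j] <- sample(alleles)
  a <- perm[seq_len(n), , drop = FALSE]
  b <- perm[n + seq_len(n), , drop = FALSE]
  h <- colSums(a != b)
  idx <- .pair_id(a, b) + rep((seq_len(B) - 1L) * G, each = n)
  cnt <- tabulate(idx, nbins = B * G)
  stat <- h * log(2) - colSums(matrix(lgamma(cnt + 1), nrow = G))
  # count ties as "no more probable" (1e-9 guards float noise in lgamma sums)
  (1 + sum(stat <= stat_obs + 1e-9)) / (B + 1)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for one locus in one population: the observed
#' 2n alleles are repeatedly shuffled into n diploid genotypes, and the
#' p-value is the proportion of shuffles whose genotype array is no more
#' probable (under the multinomial conditional distribution given allele
#' counts) than the observed array, with numerator and denominator each
#' incremented by one. Well-defined for any number of alleles; a monomorphic
#' locus gives p = 1.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population population label.
#' @param n_shuffles number of Monte-Carlo shuffles (at least 1000).
#' @param seed optional integer seed; same seed and data give identical
#'   p-values.
#' @return A one-row data.frame with `locus`, `population`, `n_typed`,
#'   `p_value`, `n_shuffles`. `p_value` is `NA` when fewer than 5 typed
#'   individuals are available.
#' @seealso [bonferroni_adjust()], [hwe_test_all()]
#' @export
hwe_exact_test <- function(table, locus, population, n_shuffles = 2000L,
                           seed = NULL) {
  if (n_shuffles < 1000L) .stop_arg("n_shuffles must be at least 1000")
  m <- .locus_matrix(table, locus, population)
  n <- nrow(m)
  if (n < 5L) {
    return(data.frame(locus = locus, population = population, n_typed = n,
                      p_value = NA_real_, n_shuffles = as.integer(n_shuffles),
                      stringsAsFactors = FALSE))
  }
  lev <- unique(c(m))
  g <- matrix(match(m, lev), ncol = 2L)
  p <- with_seed(seed, .hwe_mc(g, as.integer(n_shuffles)))
  data.frame(locus = locus, population = population, n_typed = n,
             p_value = p, n_shuffles = as.integer(n_shuffles),
             stringsAsFactors = FALSE)
}

#' Run the HWE exact test over loci and populations
#'
#' @param table a [genotype_table()].
#' @param loci locus names (default: the autosomal panel).
#' @param populations population labels (default: all).
#' @param n_shuffles,seed passed to [hwe_exact_test()]; each locus x
#'   population test gets a sub-seed derived deterministically from `seed`.
#' @return Row-bound [hwe_exact_test()] results.
#' @export
hwe_test_all <- function(table, loci = NULL, populations = NULL,
                         n_shuffles = 2000L, seed = NULL) {
  if (is.null(loci)) loci <- panel_loci(table)
  if (is.null(populations)) populations <- population_labels(table)
  out <- list()
  i <- 0L
  for (p in populations) {
    for (l in loci) {
      i <- i + 1L
      s <- if (is.null(seed)) NULL else seed + i
      out[[i]] <- hwe_exact_test(table, l, p, n_shuffles, s)
    }
  }
  do.call(rbind, out)
}

#' Bonferroni adjustment of HWE test results
#'
#' Adds raw and Bonferroni-corrected significance calls: a test is raw
#' significant at `p <= alpha` and Bonferroni significant at
#' `p <= alpha / m`, `m` being the number of tests in its family.
#'
#' @param results a data.frame with a `p_value` column (e.g. from
#'   [hwe_test_all()]).
#' @param alpha family-wise significance level (default 0.05).
#' @param family `NULL` to treat all rows as one family, or the name of a
#'   grouping column (typically `"population"`, giving one family of loci per
#'   population).
#' @return `results` with added columns `m`, `significant_raw`,
#'   `significant_bonferroni`.
#' @export
bonferroni_adjust <- function(results, alpha = 0.05, family = NULL) {
  if (!nrow(results)) .stop_arg("'results' is empty")
  grp <- if (is.null(family)) rep(1L, nrow(results)) else results[[family]]
  m <- stats::ave(seq_len(nrow(results)), grp, FUN = length)
  results$m <- as.integer(m)
  results$significant_raw <- results$p_value <= alpha
  results$significant_bonferroni <- results$p_value <= alpha / m
  results
}

#' Null-allele frequency estimators
#'
#' Two moment estimators of null-allele frequency from the observed and
#' expected heterozygosity of a locus: Chakraborty's
#' `r = (HE - HO) / (HE + HO)` and Brookfield's `r = (HE - HO) / (1 + HE)`.
#' Negative values (heterozygote excess) are reported as-is; the flag fires
#' only when both estimates exceed `threshold`.
#'
#' @param HO,HE observed and expected heterozygosity in `[0, 1]`
#'   (vectorized).
#' @param threshold flagging threshold on the smaller of the two estimates
#'   (default 0.05).
#' @return A data.frame with `r_chakraborty`, `r_brookfield`, `flagged`.
#' @export
null_allele_estimates <- function(HO, HE, threshold = 0.05) {
  stopifnot(all(HO >= 0 & HO <= 1, na.rm = TRUE),
            all(HE >= 0 & HE <= 1, na.rm = TRUE))
  denom <- HE + HO
  rc <- ifelse(denom == 0, 0, (HE - HO) / denom)
  rb <- (HE - HO) / (1 + HE)
  data.frame(r_chakraborty = rc, r_brookfield = rb,
             flagged = pmin(rc, rb) > threshold)
}

#' Homozygote-excess scan across allele size classes
#'
#' A simplified genotyping-error diagnostic for stutter-prone loci: alleles
#' are binned by parsed size into `n_size_classes` equal-width classes; for
#' each class the observed count of homozygotes is compared with its
#' Hardy-Weinberg expectation by Monte-Carlo simulation from the observed
#' allele spectrum (one-sided excess test). The locus-level error flag is
#' raised when the excess is significant at `alpha` in a majority of the
#' occupied classes. Stutter mis-calls (adjacent-size heterozygotes read as
#' homozygotes) inflate homozygosity across size classes and trip this scan;
#' it is deliberately simpler than a full stutter-regression diagnostic.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population population label.
#' @param n_size_classes number of allele size bins (default 4).
#' @param n_mc Monte-Carlo replicates (default 2000).
#' @param seed optional integer seed.
#' @param alpha per-class one-sided significance level (default 0.05).
#' @return A list with `locus`, `population`, `n_typed`, `classes` (per-class
#'   data.frame: bounds, allele count, observed and expected homozygotes,
#'   p-value) and logical `flagged` (`NA` when fewer than 10 typed
#'   individuals).
#' @export
homozygote_excess_scan <- function(table, locus, population,
                                   n_size_classes = 4L, n_mc = 2000L,
                                   seed = NULL, alpha = 0.05) {
  m <- .locus_matrix(table, locus, population)
  n <- nrow(m)
  if (n < 10L) {
    return(list(locus = locus, population = population, n_typed = n,
                classes = NULL, flagged = NA))
  }
  spec <- allele_frequencies(table, locus, population)
  sizes <- parse_alleles(names(spec$freqs))$size
  k <- length(spec$freqs)
  if (diff(range(sizes)) == 0) {
    breaks <- c(sizes[1L] - 0.5, sizes[1L] + 0.5)
  } else {
    breaks <- seq(min(sizes) - 0.5, max(sizes) + 0.5,
                  length.out = min(n_size_classes, k) + 1L)
  }
  cls <- as.integer(cut(sizes, breaks, include.lowest = TRUE))
  ncls <- length(breaks) - 1L
  hom <- m[, 1L] == m[, 2L]
  code <- match(m[, 1L], names(spec$freqs))
  obs <- tabulate(cls[code[hom]], nbins = ncls)
  B <- as.integer(n_mc)
  sim <- with_seed(seed, {
    a <- matrix(sample.int(k, n * B, replace = TRUE, prob = spec$freqs), n, B)
    b <- matrix(sample.int(k, n * B, replace = TRUE, prob = spec$freqs), n, B)
    eq <- a == b
    idx <- cls[a[eq]] + (rep(seq_len(B), each = n)[eq] - 1L) * ncls
    matrix(tabulate(idx, nbins = ncls * B), nrow = ncls)
  })
  p_cls <- (1 + rowSums(sim >= rep(obs, B))) / (B + 1)
  occupied <- tabulate(cls, nbins = ncls) > 0L
  sig <- occupied & p_cls <= alpha
  classes <- data.frame(class = seq_len(ncls),
                        size_min = utils::head(breaks, -1L) + 0.5,
                        size_max = utils::tail(breaks, -1L) - 0.5,
                        n_alleles = tabulate(cls, nbins = ncls),
                        obs_hom = obs,
                        exp_hom = rowMeans(sim),
                        p_value = p_cls,
                        stringsAsFactors = FALSE)
  list(locus = locus, population = population, n_typed = n,
       classes = classes, flagged = sum(sig) > sum(occupied) / 2)
}
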