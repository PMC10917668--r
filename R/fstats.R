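# Weir-Cockerham (1984) F-statistics: per-allele variance components
# a (among populations), b (among individuals within populations) and
# c (within individuals), summed over alleles per locus and over loci for
# multi-locus ratio-of-sums estimates of FIS, FST and FIT.

# variance components for one locus; returns c(a, b, c) or NULL if fewer
# than two populations have >= 2 typed individuals
.wc_components <- function(table, locus, populations) {
  mats <- lapply(populations, function(p) .locus_matrix(table, locus, p))
  ni <- vapply(mats, nrow, 0L)
  keep <- ni >= 2L
  if (sum(keep) < 2L) return(NULL)
  mats <- mats[keep]
  ni <- ni[keep]
  r <- length(mats)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- unique(unlist(lapply(mats, c)))
  a_sum <- b_sum <- c_sum <- 0
  for (al in alleles) {
    pi <- vapply(mats, function(m) sum(m == al) / (2 * nrow(m)), 0)
    # frequency of individuals heterozygous for allele al
    hi <- vapply(mats, function(m)
      mean((m[, 1L] == al) != (m[, 2L] == al)), 0)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a_sum <- a_sum + nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_sum <- b_sum + nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_sum <- c_sum + hbar / 2
  }
  c(a = a_sum, b = b_sum, c = c_sum)
}

#' Weir-Cockerham F-statistics
#'
#' Estimates Wright's fixation indices by the Weir-Cockerham variance
#' component method: for every allele of every locus, components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals) are computed and summed over alleles, giving per-locus
#' `FST = a/(a+b+c)`, `FIS = b/(b+c)` and `FIT = (a+b)/(a+b+c)`. Multi-locus
#' estimates sum the components across loci before taking ratios
#' (ratio-of-sums, the standard weighting). Negative components are kept in
#' all sums. Loci with zero total variance (monomorphic over the analyzed
#' populations) are reported as `NA` and excluded from the multi-locus sums.
#' Missing genotypes are dropped locus-wise.
#'
#' @param table a [genotype_table()].
#' @param loci locus names (default: autosomal panel).
#' @param populations population labels (default: all; at least 2 required,
#'   each with at least 2 typed individuals per analyzed locus).
#' @return An object of class `wc_fstats`: list with `per_locus` (data.frame
#'   of components and indices per locus) and `multilocus` (named vector
#'   `FIS`, `FST`, `FIT`).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fstats <- function(table, loci = NULL, populations = NULL) {
  if (is.null(loci)) loci <- panel_loci(table)
  if (is.null(populations)) populations <- population_labels(table)
  if (length(populations) < 2L) .stop_arg("need at least 2 populations")
  comp <- lapply(loci, function(l) .wc_components(table, l, populations))
  per <- data.frame(locus = loci, a = NA_real_, b = NA_real_, c = NA_real_,
                    FIS = NA_real_, FST = NA_real_, FIT = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    x <- comp[[i]]
    if (is.null(x)) next
    per$a[i] <- x[["a"]]
    per$b[i] <- x[["b"]]
    per$c[i] <- x[["c"]]
    tot <- sum(x)
    if (abs(tot) < 1e-14) next  # zero total variance: undefined
    per$FST[i] <- x[["a"]] / tot
    per$FIT[i] <- (x[["a"]] + x[["b"]]) / tot
    if (abs(x[["b"]] + x[["c"]]) > 1e-14) {
      per$FIS[i] <- x[["b"]] / (x[["b"]] + x[["c"]])
    }
  }
  def <- !is.na(per$FST)
  A <- sum(per$a[def])
  B <- sum(per$b[def])
  C <- sum(per$c[def])
  multi <- c(FIS = B / (B + C), FST = A / (A + B + C),
             FIT = (A + B) / (A + B + C))
  structure(list(per_locus = per, multilocus = multi,
                 populations = populations),
            class = "wc_fstats")
}

#' Qualitative interpretation of an FST value
#'
#' Wright's descriptive bands for the degree of genetic differentiation.
#'
#' @param fst numeric FST value(s).
#' @return Character annotation; notes that the range of FST values from
#'   0.15 to 0.25 indicates moderate differentiation, while 0.00-0.05
#'   indicates a weak but noteworthy difference.
#' @export
fst_interpretation <- function(fst) {
  cut(fst, breaks = c(-Inf, 0.05, 0.15, 0.25, Inf),
      labels = c("weak but noteworthy differentiation (FST 0.00-0.05)",
                 "intermediate differentiation (FST 0.05-0.15)",
                 "moderate differentiation (range of FST values from 0.15 to 0.25 indicates moderate differentiation)",
                 "strong differentiation (FST > 0.25)")) |>
    as.character()
}

#' @export
print.wc_fstats <- function(x, digits = 4, ...) {
  cat("Weir-Cockerham F-statistics (populations:",
      paste(x$populations, collapse = ", "), ")\n")
  print(cbind(x$per_locus[1L],
              round(x$per_locus[-1L], digits)), row.names = FALSE)
  cat(sprintf("multilocus: FIS = %.*f  FST = %.*f  FIT = %.*f\n",
              digits, x$multilocus[["FIS"]], digits, x$multilocus[["FST"]],
              digits, x$multilocus[["FIT"]]))
  cat("  ", fst_interpretation(x$multilocus[["FST"]]), "\n")
  invisible(x)
}

#' Per-locus subdivision coefficients (theta) for forensic use
#'
#' Forensic match-probability correction uses a per-locus subdivision
#' coefficient theta, taken as the Weir-Cockerham per-locus FST truncated at
#' zero (a negative differentiation estimate carries no forensic meaning).
#' Loci with undefined FST are omitted.
#'
#' @param fstats a [wc_fstats()] result.
#' @return A data.frame with `locus` and `theta`, sorted by ascending theta
#'   (ties broken by locus name) — the locus order used in cumulative match
#'   probability reports.
#' @export
per_locus_theta <- function(fstats) {
  stopifnot(inherits(fstats, "wc_fstats"))
  per <- fstats$per_locus
  per <- per[!is.na(per$FST), , drop = FALSE]
  out <- data.frame(locus = per$locus, theta = pmax(per$FST, 0),
                    stringsAsFactors = FALSE)
  out[order(out$theta, out$locus), , drop = FALSE]
}

#' Pairwise FST matrix
#'
#' Multi-locus Weir-Cockerham FST for every pair of populations.
#'
#' @param table a [genotype_table()].
#' @param populations population labels (default: all).
#' @param loci locus names (default: autosomal panel).
#' @return A symmetric matrix with zero diagonal.
#' @export
pairwise_fst <- function(table, populations = NULL, loci = NULL) {
  if (is.null(populations)) populations <- population_labels(table)
  if (length(populations) < 2L) .stop_arg("need at least 2 populations")
  k <- length(populations)
  out <- matrix(0, k, k, dimnames = list(populations, populations))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      f <- wc_fstats(table, loci, populations[c(i, j)])
      out[i, j] <- out[j, i] <- f$multilocus[["FST"]]
    }
  }
  out
}
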