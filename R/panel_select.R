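# Locus triage for forensic panel design: a cascade of exclusion rules
# (genotyping-error scan -> null-allele burden -> major-allele dominance ->
# post-Bonferroni HWE deviation) producing an auditable per-locus report.

#' Thresholds for the locus filter cascade
#'
#' @param error_alpha per-class significance level of the
#'   [homozygote_excess_scan()] (default 0.05).
#' @param null_threshold null-allele estimate above which a population
#'   counts against a locus (default 0.05).
#' @param null_min_pops number of populations that must exceed
#'   `null_threshold` for the null rule to fire (default 2).
#' @param dominance_threshold major-allele frequency defining dominance; the
#'   rule fires only when every analyzed population is dominated
#'   (default 0.5).
#' @param hwe_alpha family-wise level of the HWE rule; the Bonferroni family
#'   is the set of tested loci within each population (default 0.05).
#' @param n_shuffles Monte-Carlo shuffles for the HWE tests (default 2000).
#' @param n_mc Monte-Carlo replicates for the error scan (default 2000).
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(error_alpha = 0.05, null_threshold = 0.05,
                            null_min_pops = 2L, dominance_threshold = 0.5,
                            hwe_alpha = 0.05, n_shuffles = 2000L,
                            n_mc = 2000L) {
  for (v in c(error_alpha, null_threshold, dominance_threshold, hwe_alpha)) {
    if (is.null(v) || is.na(v)) .stop_arg("all thresholds must be supplied")
  }
  structure(list(error_alpha = error_alpha,
                 null_threshold = null_threshold,
                 null_min_pops = as.integer(null_min_pops),
                 dominance_threshold = dominance_threshold,
                 hwe_alpha = hwe_alpha,
                 n_shuffles = as.integer(n_shuffles),
                 n_mc = as.integer(n_mc)),
            class = "filter_criteria")
}

#' Apply the locus filter cascade
#'
#' Screens candidate loci against four exclusion rules, applied in order but
#' independently (any rule firing excludes the locus):
#' \enumerate{
#'   \item genotyping-error evidence: [homozygote_excess_scan()] flags the
#'     locus in at least one population;
#'   \item null-allele burden: [null_allele_estimates()] exceeds the
#'     threshold in at least `null_min_pops` populations;
#'   \item major-allele dominance: [major_allele_flag()] fires in every
#'     population;
#'   \item Hardy-Weinberg deviation surviving Bonferroni correction
#'     ([hwe_exact_test()] + [bonferroni_adjust()], family = loci within
#'     each population) in at least one population.
#' }
#' A locus deviating at raw `p = 0.005` in every population of a 15-locus
#' panel is retained: the Bonferroni threshold `0.05/15 = 0.0033` rescues it.
#'
#' @param table a [genotype_table()].
#' @param loci candidate loci (default: autosomal panel).
#' @param populations population labels (default: all; at least 2).
#' @param criteria a [filter_criteria()] list.
#' @param seed integer seed driving every Monte-Carlo sub-test; the report
#'   is deterministic given the seed.
#' @return An object of class `filter_report`: data.frame with one row per
#'   locus (`error_flag`, `null_flag` = count of populations over the null
#'   threshold, `dominance_flag`, `hwe_flag` = count of populations
#'   Bonferroni-significant, `decision`, `reasons`), with the retained panel
#'   in attribute `"retained"`.
#' @export
apply_locus_filters <- function(table, loci = NULL, populations = NULL,
                                criteria = filter_criteria(), seed = 1L) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (is.null(loci)) loci <- panel_loci(table)
  if (is.null(populations)) populations <- population_labels(table)
  if (length(populations) < 2L) .stop_arg("need at least 2 populations")
  hwe <- hwe_test_all(table, loci, populations,
                      n_shuffles = criteria$n_shuffles, seed = seed)
  hwe <- bonferroni_adjust(hwe, alpha = criteria$hwe_alpha,
                           family = "population")
  rows <- list()
  for (i in seq_along(loci)) {
    l <- loci[i]
    err_pop <- logical(length(populations))
    null_pop <- logical(length(populations))
    dom_pop <- logical(length(populations))
    for (j in seq_along(populations)) {
      p <- populations[j]
      scan <- homozygote_excess_scan(table, l, p, n_mc = criteria$n_mc,
                                     seed = seed + 1000L * i + j,
                                     alpha = criteria$error_alpha)
      err_pop[j] <- isTRUE(scan$flagged)
      ls <- locus_summary(table, l, p)
      if (!is.na(ls$HO) && !is.na(ls$HE)) {
        ne <- null_allele_estimates(ls$HO, ls$HE, criteria$null_threshold)
        null_pop[j] <- isTRUE(ne$flagged)
      }
      spec <- allele_frequencies(table, l, p)
      maf <- major_allele_flag(spec, criteria$dominance_threshold)
      dom_pop[j] <- isTRUE(maf$dominated)
    }
    hwe_l <- hwe[hwe$locus == l, ]
    hwe_count <- sum(hwe_l$significant_bonferroni, na.rm = TRUE)
    error_flag <- any(err_pop)
    null_flag <- sum(null_pop)
    dominance_flag <- all(dom_pop)
    reasons <- character(0)
    if (error_flag) {
      reasons <- c(reasons, "genotyping-error evidence (homozygote-excess scan)")
    }
    if (null_flag >= criteria$null_min_pops) {
      reasons <- c(reasons, sprintf("null-allele burden in %d populations",
                                    null_flag))
    }
    if (dominance_flag) {
      reasons <- c(reasons, "major-allele dominance in all populations")
    }
    if (hwe_count >= 1L) {
      reasons <- c(reasons,
                   sprintf("HWE deviation after Bonferroni in %d population%s",
                           hwe_count, if (hwe_count > 1L) "s" else ""))
    }
    rows[[i]] <- data.frame(
      locus = l, error_flag = error_flag, null_flag = null_flag,
      dominance_flag = dominance_flag, hwe_flag = hwe_count,
      decision = if (length(reasons)) "exclude" else "retain",
      reasons = paste(reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("filter_report", "data.frame")
  attr(out, "retained") <- out$locus[out$decision == "retain"]
  attr(out, "criteria") <- criteria
  out
}

#' @export
print.filter_report <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  cat("retained panel:", paste(attr(x, "retained"), collapse = ", "), "\n")
  invisible(x)
}
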