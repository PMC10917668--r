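# Frequency-based population assignment: the expected frequency of an
# individual's multi-locus genotype is computed in each reference population
# (product of p^2 / 2pq over typed loci), with leave-one-out correction when
# scoring an individual against its own population, and the individual is
# assigned to the population where its genotype is most probable (smallest
# -ln frequency).

# per-locus allele counts for a population as a named integer vector
.pop_counts <- function(table, locus, population) {
  m <- .locus_matrix(table, locus, population)
  if (!nrow(m)) return(integer(0))
  tab <- table(c(m[, 1L], m[, 2L]))
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt
}

#' Negative log expected frequency of a sample's multi-locus genotype
#'
#' Computes `-ln` of the product over the sample's typed loci of the
#' Hardy-Weinberg genotype frequency (`p^2` for a homozygote, `2pq` for a
#' heterozygote) using allele frequencies from the reference `population`.
#' With `leave_one_out = TRUE` and the sample belonging to that population,
#' its own two alleles are removed from the counts before frequencies are
#' formed (avoiding the upward bias of scoring an individual against a
#' reference that contains it). An allele with zero count (possibly after
#' removal) receives the rare-allele frequency `1/(2n + 1)`, `n` being the
#' number of typed reference individuals entering the frequency denominator.
#'
#' @param table a [genotype_table()].
#' @param sample_id sample identifier.
#' @param population reference population label.
#' @param leave_one_out remove the sample's own alleles from the reference?
#' @param loci loci to use (default: autosomal panel); loci where the sample
#'   is untyped are skipped.
#' @return A positive number, or `NA` if the sample is typed at no requested
#'   locus.
#' @export
genotype_log_frequency <- function(table, sample_id, population,
                                   leave_one_out = FALSE, loci = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(loci)) loci <- panel_loci(table)
  row <- match(sample_id, table$samples$sample_id)
  if (is.na(row)) .stop_arg("unknown sample ", sQuote(sample_id, q = FALSE))
  own_pop <- table$samples$population[row] == population
  total <- 0
  n_used <- 0L
  for (l in loci) {
    pair <- table$genotypes[[l]][row, ]
    if (anyNA(pair)) next
    cnt <- .pop_counts(table, l, population)
    n_ref <- sum(cnt) / 2
    if (leave_one_out && own_pop) {
      for (al in pair) {
        if (!is.na(cnt[al])) cnt[al] <- cnt[al] - 1L
      }
      n_ref <- n_ref - 1
    }
    if (n_ref < 1) next  # empty reference after removal: locus uninformative
    denom <- 2 * n_ref
    rare <- .rare_freq(n_ref)
    p1 <- if (is.na(cnt[pair[1L]]) || cnt[pair[1L]] <= 0L) rare else
      cnt[[pair[1L]]] / denom
    if (pair[1L] == pair[2L]) {
      total <- total - log(p1^2)
    } else {
      p2 <- if (is.na(cnt[pair[2L]]) || cnt[pair[2L]] <= 0L) rare else
        cnt[[pair[2L]]] / denom
      total <- total - log(2 * p1 * p2)
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(NA_real_)
  total
}

#' Leave-one-out population assignment test
#'
#' For every sample in either of two reference populations, computes the
#' negative log expected genotype frequency against its own population
#' (with leave-one-out correction) and against the other population (full
#' reference), assigns the sample to the population with the smaller
#' `-ln` frequency, and summarizes per population the percentage of
#' self-assigned samples and the mean absolute log-frequency difference
#' (`delta`). A large mean delta indicates that the panel separates the two
#' populations strongly.
#'
#' @param table a [genotype_table()].
#' @param populations exactly two distinct population labels (default: the
#'   two largest populations in the table).
#' @param loci loci to use (default: autosomal panel).
#' @param leave_one_out apply the leave-one-out correction when scoring a
#'   sample against its own population? Defaults to `TRUE`; disabling it
#'   inflates self-assignment (useful only for quantifying that bias).
#' @return An object of class `assignment_result`: list with `per_sample`
#'   (data.frame: `sample_id`, `population`, one `neg_ln_<pop>` column per
#'   reference, `assigned`, `delta`, `self_assigned`) and `summary`
#'   (data.frame per population: `n`, `pct_self_assigned`, `mean_delta`).
#' @export
assignment_test <- function(table, populations = NULL, loci = NULL,
                            leave_one_out = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(populations)) {
    tab <- sort(table(table$samples$population), decreasing = TRUE)
    if (length(tab) < 2L) .stop_arg("need at least 2 populations")
    populations <- names(tab)[1:2]
  }
  if (length(populations) != 2L || populations[1L] == populations[2L]) {
    .stop_arg("'populations' must be two distinct labels")
  }
  for (p in populations) {
    if (sum(table$samples$population == p) < 10L) {
      .stop_arg("population ", sQuote(p, q = FALSE),
                " has fewer than 10 individuals")
    }
  }
  keep <- which(table$samples$population %in% populations)
  ids <- table$samples$sample_id[keep]
  origin <- table$samples$population[keep]
  L <- matrix(NA_real_, length(keep), 2L,
              dimnames = list(NULL, populations))
  for (i in seq_along(keep)) {
    for (j in 1:2) {
      L[i, j] <- genotype_log_frequency(
        table, ids[i], populations[j],
        leave_one_out = leave_one_out && origin[i] == populations[j],
        loci = loci)
    }
  }
  # smaller -ln frequency wins; ties resolve to the sample's own population
  own_col <- match(origin, populations)
  other_col <- 3L - own_col
  own_val <- L[cbind(seq_along(keep), own_col)]
  other_val <- L[cbind(seq_along(keep), other_col)]
  assigned <- ifelse(own_val <= other_val, origin,
                     populations[other_col])
  per_sample <- data.frame(sample_id = ids, population = origin,
                           stringsAsFactors = FALSE)
  per_sample[[paste0("neg_ln_", populations[1L])]] <- L[, 1L]
  per_sample[[paste0("neg_ln_", populations[2L])]] <- L[, 2L]
  per_sample$assigned <- assigned
  per_sample$delta <- abs(own_val - other_val)
  per_sample$self_assigned <- assigned == origin
  summ <- do.call(rbind, lapply(populations, function(p) {
    i <- origin == p
    data.frame(population = p, n = sum(i),
               pct_self_assigned = 100 * mean(per_sample$self_assigned[i]),
               mean_delta = mean(per_sample$delta[i]),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = per_sample, summary = summ,
                 populations = populations),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("Leave-one-out assignment test (", paste(x$populations, collapse = " vs "),
      ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Scatter plot of an assignment test
#'
#' Plots each sample's negative log genotype frequency in the first
#' reference population against the second, colored by population of origin;
#' the diagonal is the assignment boundary.
#'
#' @param x an [assignment_test()] result.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.assignment_result <- function(x, ...) {
  p1 <- paste0("neg_ln_", x$populations[1L])
  p2 <- paste0("neg_ln_", x$populations[2L])
  col <- ifelse(x$per_sample$population == x$populations[1L], "#1b6ca8",
                "#c0392b")
  graphics::plot(x$per_sample[[p1]], x$per_sample[[p2]], col = col,
                 pch = 19, cex = 0.7,
                 xlab = paste0("-ln f (", x$populations[1L], ")"),
                 ylab = paste0("-ln f (", x$populations[2L], ")"), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = x$populations,
                   col = c("#1b6ca8", "#c0392b"), pch = 19, bty = "n")
  invisible(x)
}
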