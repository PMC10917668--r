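# One-level analysis of molecular variance on codominant genotypes. Units
# are the 2N allele copies with the 0/1 allele-mismatch distance (so the
# fixation index Phi_ST is an FST-type quantity directly comparable to
# multi-locus Weir-Cockerham FST); the permutation test moves whole
# individuals (both allele copies together) between populations, preserving
# within-individual correlation under the null of no subdivision. With 0/1
# distances every sum of squares reduces to allele counts, so no distance
# matrix is ever formed.

# per-locus N x k allele-count matrix (rows of untyped individuals are 0)
.allele_count_matrix <- function(table, locus, keep) {
  m <- table$genotypes[[locus]][keep, , drop = FALSE]
  N <- nrow(m)
  typed <- !is.na(m[, 1L]) & !is.na(m[, 2L])
  lev <- unique(c(m[typed, ]))
  if (length(lev) == 0L) return(NULL)
  X <- matrix(0, N, length(lev))
  idx <- which(typed)
  a <- match(m[, 1L], lev)
  b <- match(m[, 2L], lev)
  X[cbind(idx, a[idx])] <- X[cbind(idx, a[idx])] + 1
  X[cbind(idx, b[idx])] <- X[cbind(idx, b[idx])] + 1
  X
}

# variance components for one locus given the N x k count matrix and an
# N x r group membership matrix; returns c(sigma_among, sigma_within) or
# NULL when undefined. For 0/1 distances among m units with type counts c,
# sum of pairwise distances = (m^2 - sum(c^2))/2 and SS = that / m.
.amova_locus_components <- function(X, G) {
  cg <- crossprod(G, X)            # r x k group allele counts
  mg <- rowSums(cg)                # allele copies per group
  occ <- mg > 0
  cg <- cg[occ, , drop = FALSE]
  mg <- mg[occ]
  r <- length(mg)
  M <- sum(mg)
  if (r < 2L) return(NULL)
  ss_w <- sum((mg - rowSums(cg^2) / mg)) / 2
  ctot <- colSums(cg)
  ss_t <- (M - sum(ctot^2) / M) / 2
  ss_a <- ss_t - ss_w
  df_a <- r - 1
  df_w <- M - r
  if (df_w <= 0) return(NULL)
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  n0 <- (M - sum(mg^2) / M) / df_a
  c(sigma_among = (ms_a - ms_w) / n0, sigma_within = ms_w)
}

# multi-locus Phi_ST: components summed across loci before the ratio
.amova_phi <- function(Xs, G) {
  comp <- vapply(Xs, function(X) {
    z <- .amova_locus_components(X, G)
    if (is.null(z)) c(0, 0) else z
  }, numeric(2))
  sig <- unname(rowSums(comp))
  c(sigma_among = sig[1L], sigma_within = sig[2L],
    phi_st = sig[1L] / (sig[1L] + sig[2L]))
}

#' One-level AMOVA with permutation test
#'
#' Partitions genetic variation among vs within populations by analysis of
#' molecular variance with allele copies as units and the 0/1
#' allele-mismatch distance, yielding variance components, their
#' percentages, and the fixation index `Phi_ST` — an FST-type quantity
#' directly comparable to the multi-locus Weir-Cockerham estimate.
#' Components are computed per locus and summed across loci before the
#' ratio. Significance is assessed by permuting whole individuals (both
#' allele copies move together, which preserves within-individual
#' correlation under the null of no subdivision): `p_perm` is the proportion
#' of permutations with `Phi_ST` at least the observed value, with the +1/+1
#' correction. Negative variance components are kept in all sums.
#'
#' @param table a [genotype_table()].
#' @param loci locus names (default: autosomal panel).
#' @param populations population labels (default: all; at least 2).
#' @param n_perm number of permutations (at least 100; default 999).
#' @param seed optional integer seed.
#' @return An object of class `amova`: list with `sigma_among`,
#'   `sigma_within`, `pct_among`, `pct_within` (summing to 100), `phi_st`,
#'   `p_perm`, `n_perm`, and `per_locus` (data.frame of per-locus percentage
#'   of among-population variability).
#' @export
amova <- function(table, loci = NULL, populations = NULL, n_perm = 999L,
                  seed = NULL) {
  if (is.null(loci)) loci <- panel_loci(table)
  if (is.null(populations)) populations <- population_labels(table)
  if (length(populations) < 2L) .stop_arg("need at least 2 populations")
  if (n_perm < 100L) .stop_arg("n_perm must be at least 100")
  keep <- table$samples$population %in% populations
  groups <- factor(table$samples$population[keep], levels = populations)
  Xs <- lapply(loci, function(l) .allele_count_matrix(table, l, keep))
  names(Xs) <- loci
  Xs <- Xs[!vapply(Xs, is.null, TRUE)]
  if (!length(Xs)) .stop_arg("no typed loci among the selected samples")
  G <- stats::model.matrix(~ groups - 1)
  obs <- .amova_phi(Xs, G)
  phi_obs <- obs[["phi_st"]]
  n_perm <- as.integer(n_perm)
  exceed <- with_seed(seed, {
    cnt <- 0L
    n <- length(groups)
    for (b in seq_len(n_perm)) {
      Gp <- G[sample.int(n), , drop = FALSE]
      if (.amova_phi(Xs, Gp)[["phi_st"]] >= phi_obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  per_locus <- data.frame(
    locus = names(Xs),
    pct_among = vapply(Xs, function(X) {
      z <- .amova_locus_components(X, G)
      if (is.null(z)) NA_real_ else 100 * z[[1L]] / sum(z)
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  pct_among <- 100 * phi_obs
  structure(list(sigma_among = obs[["sigma_among"]],
                 sigma_within = obs[["sigma_within"]],
                 pct_among = pct_among,
                 pct_within = 100 - pct_among,
                 phi_st = phi_obs,
                 p_perm = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm,
                 per_locus = per_locus,
                 populations = populations),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 4, ...) {
  cat("AMOVA (populations:", paste(x$populations, collapse = ", "), ")\n")
  cat(sprintf("  among populations: sigma^2 = %.*f  (%.2f %%)\n",
              digits, x$sigma_among, x$pct_among))
  cat(sprintf("  within populations: sigma^2 = %.*f  (%.2f %%)\n",
              digits, x$sigma_within, x$pct_within))
  cat(sprintf("  Phi_ST = %.*f, permutation p = %.4g (%d permutations)\n",
              digits, x$phi_st, x$p_perm, x$n_perm))
  invisible(x)
}
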