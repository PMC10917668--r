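# Fixture builders shared across the test files. Genotype draws here are
# written from scratch (plain sample() calls) so tests do not depend on the
# package's own simulator when they are meant to check it.

# equifrequent spectrum of k alleles with consecutive size tokens
equifreq <- function(k, start = 10L) {
  stats::setNames(rep(1 / k, k), as.character(seq(start, length.out = k)))
}

# draw n genotypes (n x 2 token matrix) from named frequencies, optional
# inbreeding: with probability fis the two alleles are identical by descent
draw_geno <- function(n, p, fis = 0) {
  k <- length(p)
  ibd <- stats::runif(n) < fis
  a <- sample.int(k, n, replace = TRUE, prob = p)
  b <- ifelse(ibd, a, sample.int(k, n, replace = TRUE, prob = p))
  cbind(names(p)[a], names(p)[b])
}

# build a genotype_table from per-population, per-locus frequency vectors:
# pop_freqs = list(popA = list(L1 = freqs, ...), popB = ...)
make_table <- function(pop_freqs, n_per_pop, fis = 0, motif = 4L) {
  pops <- names(pop_freqs)
  loci <- names(pop_freqs[[1L]])
  n_tot <- sum(n_per_pop[pops])
  population <- rep(pops, n_per_pop[pops])
  samples <- data.frame(sample_id = sprintf("s%04d", seq_len(n_tot)),
                        population = population, stringsAsFactors = FALSE)
  fis_of <- function(pn) {
    if (length(fis) == 1L) fis else fis[[pn]]
  }
  genotypes <- lapply(loci, function(l) {
    m <- matrix(NA_character_, n_tot, 2L)
    for (pn in pops) {
      rows <- which(population == pn)
      m[rows, ] <- draw_geno(length(rows), pop_freqs[[pn]][[l]], fis_of(pn))
    }
    m
  })
  names(genotypes) <- loci
  genotype_table(data.frame(locus = loci, motif_length = motif,
                            marker_class = "autosomal",
                            stringsAsFactors = FALSE),
                 samples, genotypes)
}

# tiny fully-specified table for hand-checked examples
tiny_table <- function(genotypes, populations = NULL) {
  # genotypes: list(locus -> n x 2 matrix)
  n <- nrow(genotypes[[1L]])
  if (is.null(populations)) populations <- rep("p1", n)
  genotype_table(
    data.frame(locus = names(genotypes), stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("t%03d", seq_len(n)),
               population = populations, stringsAsFactors = FALSE),
    genotypes)
}
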