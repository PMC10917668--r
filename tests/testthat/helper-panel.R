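# Builders for the panel-triage fixtures: a six-locus candidate set with one
# stutter-corrupted, one null-injected, one major-allele-dominated and three
# clean loci; and a fifteen-locus set whose deviant locus shows a raw
# Hardy-Weinberg departure mild enough for Bonferroni to rescue.

make_triage_table <- function(seed, n = 300L,
                              stutter_rate = 0.35, null_r = 0.2) {
  set.seed(seed)
  freqs <- list(L_STUT = equifreq(3), L_NULL = equifreq(8),
                L_DOM = c(`10` = 0.8, `11` = 0.1, `12` = 0.1),
                L_C1 = equifreq(6), L_C2 = equifreq(6), L_C3 = equifreq(6))
  genos <- lapply(freqs, function(p) rbind(draw_geno(n, p), draw_geno(n, p)))
  tab <- genotype_table(
    data.frame(locus = names(freqs), stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%04d", seq_len(2L * n)),
               population = rep(c("a", "b"), each = n),
               stringsAsFactors = FALSE),
    genos)
  tab <- inject_stutter_errors(tab, "L_STUT", stutter_rate, seed = seed + 1L)
  tab <- inject_null_alleles(tab, "L_NULL", "a", null_r, seed = seed + 2L)
  inject_null_alleles(tab, "L_NULL", "b", null_r, seed = seed + 3L)
}

# draw genotypes with forced heterozygote excess: with probability e a
# homozygous draw is re-drawn heterozygous (an HWE departure that mimics
# neither null alleles nor stutter nor dominance)
draw_het_excess <- function(n, p, e) {
  k <- length(p)
  a <- sample.int(k, n, replace = TRUE, prob = p)
  b <- sample.int(k, n, replace = TRUE, prob = p)
  for (i in which(stats::runif(n) < e & a == b)) {
    repeat {
      b[i] <- sample.int(k, 1L, prob = p)
      if (b[i] != a[i]) break
    }
  }
  cbind(names(p)[a], names(p)[b])
}

make_rescue_table <- function(seed = 3L, n = 150L, e = 0.7) {
  set.seed(seed)
  loci <- c(sprintf("L%02d", 1:14), "LDEV")
  genos <- lapply(loci, function(l) {
    if (l == "LDEV") {
      rbind(draw_het_excess(n, equifreq(6), e),
            draw_het_excess(n, equifreq(6), e))
    } else {
      rbind(draw_geno(n, equifreq(6)), draw_geno(n, equifreq(6)))
    }
  })
  names(genos) <- loci
  genotype_table(
    data.frame(locus = loci, stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%04d", seq_len(2L * n)),
               population = rep(c("a", "b"), each = n),
               stringsAsFactors = FALSE),
    genos)
}
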