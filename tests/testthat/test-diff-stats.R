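test_that("F-statistic identity (1-FIT) = (1-FIS)(1-FST) holds per locus", {
  set.seed(19)
  tab <- simulate_study(sim_config(n_loci = 8L, theta_between = 0.1,
                                   fis = c(a = 0.1, b = 0.2),
                                   n_per_population = c(a = 60L, b = 80L),
                                   seed = 19L))
  fs <- wc_fstats(tab)
  per <- fs$per_locus[!is.na(fs$per_locus$FST), ]
  expect_gt(nrow(per), 0L)
  expect_equal((1 - per$FIT), (1 - per$FIS) * (1 - per$FST),
               tolerance = 1e-12)
  m <- fs$multilocus
  expect_equal(1 - m[["FIT"]], (1 - m[["FIS"]]) * (1 - m[["FST"]]),
               tolerance = 1e-12)
  expect_true(all(per$a + per$b + per$c > 0))
})

test_that("FST is near zero for populations drawn from identical frequencies", {
  set.seed(23)
  freqs <- list(L1 = equifreq(5), L2 = equifreq(8), L3 = equifreq(3))
  tab <- make_table(list(a = freqs, b = freqs),
                    c(a = 1000L, b = 1000L))
  fs <- wc_fstats(tab)
  expect_lt(abs(fs$multilocus[["FST"]]), 0.01)
})

test_that("biallelic two-population FST agrees with the Hudson estimator oracle", {
  set.seed(29)
  freq_a <- list(L1 = c(`10` = 0.9, `11` = 0.1))
  freq_b <- list(L1 = c(`10` = 0.1, `11` = 0.9))
  tab <- make_table(list(a = freq_a, b = freq_b), c(a = 1000L, b = 1000L))
  fst <- wc_fstats(tab)$multilocus[["FST"]]
  # Hudson's FST from the realized sample frequencies (independent estimator)
  p1 <- allele_frequencies(tab, "L1", "a")$freqs[["10"]]
  p2 <- allele_frequencies(tab, "L1", "b")$freqs[["10"]]
  n1 <- n2 <- 1000
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(fst, num / den, tolerance = 0.02)
  expect_gt(fst, 0.5)  # strong differentiation by construction
})

test_that("per-locus theta truncates negative FST and orders ascending", {
  fs <- structure(list(per_locus = data.frame(
    locus = c("B", "A", "C", "D"),
    a = 1, b = 1, c = 1,
    FIS = 0.1, FST = c(0.158, -0.003, 0.025, NA), FIT = 0.2,
    stringsAsFactors = FALSE),
    multilocus = c(FIS = 0.1, FST = 0.05, FIT = 0.15),
    populations = c("x", "y")), class = "wc_fstats")
  th <- per_locus_theta(fs)
  expect_identical(th$locus, c("A", "C", "B"))  # NA locus omitted
  expect_equal(th$theta, c(0, 0.025, 0.158))
  expect_true(all(diff(th$theta) >= 0))
})

test_that("AMOVA percentages are conserved and the null case is flat", {
  set.seed(31)
  freqs <- list(L1 = equifreq(6), L2 = equifreq(10))
  tab <- make_table(list(a = freqs, b = freqs), c(a = 50L, b = 50L))
  am <- amova(tab, n_perm = 199, seed = 4)
  expect_equal(am$pct_among + am$pct_within, 100, tolerance = 1e-9)
  expect_lt(abs(am$pct_among), 3)
  expect_gt(am$p_perm, 0.05)  # identical populations: no signal expected
})

test_that("AMOVA Phi_ST tracks Weir-Cockerham FST on subdivided simulations", {
  for (th in c(0.02, 0.08, 0.15)) {
    tab <- simulate_study(sim_config(theta_between = th, fis = 0,
                                     n_per_population = c(a = 100L, b = 100L),
                                     seed = 1000L + round(1000 * th)))
    fst <- wc_fstats(tab)$multilocus[["FST"]]
    am <- amova(tab, n_perm = 199, seed = 5)
    expect_equal(am$phi_st, fst, tolerance = 0.02)
  }
  # subdivided case recovers the simulated level and is significant
  tab <- simulate_study(sim_config(theta_between = 0.08, fis = 0,
                                   n_per_population = c(a = 103L, b = 198L),
                                   seed = 77L))
  am <- amova(tab, n_perm = 199, seed = 6)
  expect_equal(am$phi_st, 0.08, tolerance = 0.04)
  expect_lt(am$p_perm, 0.05)
  expect_equal(am$pct_among + am$pct_within, 100, tolerance = 1e-9)
})

test_that("pairwise FST matrix is symmetric, zero-diagonal and consistent", {
  set.seed(41)
  tab2 <- simulate_study(sim_config(n_loci = 5L, theta_between = 0.1, fis = 0,
                                    n_per_population = c(a = 50L, b = 50L),
                                    seed = 13L))
  m2 <- pairwise_fst(tab2)
  expect_equal(m2["a", "b"], wc_fstats(tab2)$multilocus[["FST"]])
  expect_equal(m2, t(m2))
  expect_equal(diag(m2), c(a = 0, b = 0))

  tab4 <- simulate_study(sim_config(
    n_loci = 5L, theta_between = 0.05, fis = 0,
    n_per_population = c(g1 = 30L, g2 = 30L, g3 = 30L, g4 = 30L),
    seed = 14L))
  m4 <- pairwise_fst(tab4)
  expect_equal(m4, t(m4))
  expect_true(all(m4 >= -0.05))

  # clone populations: all off-diagonals near zero
  freqs <- list(L1 = equifreq(6), L2 = equifreq(6))
  set.seed(42)
  tabc <- make_table(list(a = freqs, b = freqs, c = freqs),
                     c(a = 200L, b = 200L, c = 200L))
  expect_true(all(abs(pairwise_fst(tabc)) < 0.02))
})

test_that("FST interpretation bands follow Wright's scale", {
  expect_match(fst_interpretation(0.03), "weak but noteworthy")
  expect_match(fst_interpretation(0.2),
               "range of FST values from 0.15 to 0.25 indicates moderate differentiation")
  expect_match(fst_interpretation(0.4), "strong")
})
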