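test_that("theta formulas reduce to the product rule at theta = 0", {
  expect_equal(theta_match_prob(0.2), 0.04)
  expect_equal(theta_match_prob(0.2, 0.3), 0.12)
  set.seed(91)
  p <- stats::runif(10000, 1e-6, 1)
  q <- stats::runif(10000, 1e-6, 1)
  hom <- theta_match_prob(p)
  het <- theta_match_prob(p, q)
  expect_true(all(abs(hom - p^2) < 1e-15))
  expect_true(all(abs(het - 2 * p * q) < 1e-15))
  expect_error(theta_match_prob(0.1, theta = 1), "theta")
  expect_error(theta_match_prob(0.1, theta = -0.01), "theta")
})

test_that("theta-corrected closed form matches hand arithmetic", {
  # theta = 0.03, homozygote p = 0.1:
  # [0.06 + 0.097][0.09 + 0.097] / (1.03 * 1.06)
  expect_equal(theta_match_prob(0.1, theta = 0.03),
               (0.06 + 0.097) * (0.09 + 0.097) / (1.03 * 1.06))
  expect_equal(round(theta_match_prob(0.1, theta = 0.03), 5), 0.02689)
  # fixed homozygote p = 1: probability 1 for any theta
  for (th in c(0, 0.01, 0.1, 0.5, 0.9)) {
    expect_equal(theta_match_prob(1, theta = th), 1)
  }
})

test_that("homozygote correction is conservative; heterozygote is not uniformly", {
  grid <- expand.grid(p = seq(0.01, 1, length.out = 100),
                      th = seq(0, 0.95, length.out = 100))
  hom <- theta_match_prob(grid$p, theta = 0) # baseline p^2
  corr <- mapply(function(p, th) theta_match_prob(p, theta = th),
                 grid$p, grid$th)
  expect_identical(sum(corr < grid$p^2 - 1e-12), 0L)
  # known non-property: p = q = 0.5, theta = 0.2 gives 3/7 < 0.5
  expect_equal(theta_match_prob(0.5, 0.5, theta = 0.2), 3 / 7)
  expect_lt(theta_match_prob(0.5, 0.5, theta = 0.2), 2 * 0.5 * 0.5)
})

test_that("spectrum lookups honor the rare-allele policy", {
  g <- list(L1 = rbind(matrix("10", 49, 2), c("10", "11")))
  tab <- tiny_table(g)
  spec <- allele_frequencies(tab, "L1", "p1")  # n = 50, p(11) = 0.01
  expect_equal(single_locus_match_prob(c("10", "10"), spec, 0), 0.99^2)
  # allele absent from the spectrum: frequency 1/(2*50+1)
  expect_equal(single_locus_match_prob(c("12", "12"), spec, 0),
               (1 / 101)^2)
  expect_equal(single_locus_match_prob(c("10", "12"), spec, 0),
               2 * 0.99 * (1 / 101))
})

test_that("multi-locus report orders by ascending theta and multiplies through", {
  set.seed(101)
  freqs <- list(A = equifreq(4), B = equifreq(6), C = equifreq(8))
  tab <- make_table(list(p = freqs), c(p = 120L))
  thetas <- data.frame(locus = c("A", "B", "C"),
                       theta = c(0.10, 0.02, 0.02))
  rep1 <- multilocus_match_probability(tab, "s0001", thetas)
  # ties at 0.02 broken by name, then the 0.10 locus
  expect_identical(rep1$locus, c("B", "C", "A"))
  expect_equal(rep1$cum_no_theta, cumprod(rep1$p_no_theta))
  expect_equal(rep1$cum_with_theta, cumprod(rep1$p_with_theta))
  expect_true(all(diff(rep1$cum_no_theta) <= 0))
  expect_true(all(rep1$p_no_theta > 0 & rep1$p_no_theta <= 1))

  # independent brute-force product oracle from raw counts
  brute <- 1
  for (l in c("A", "B", "C")) {
    pair <- tab$genotypes[[l]][1, ]
    cnt <- table(c(tab$genotypes[[l]]))
    p1 <- cnt[[pair[1]]] / sum(cnt)
    brute <- brute * if (pair[1] == pair[2]) p1^2 else
      2 * p1 * cnt[[pair[2]]] / sum(cnt)
  }
  expect_equal(rep1$cum_no_theta[3], brute, tolerance = 1e-12)

  # use_theta = FALSE collapses the two column pairs
  rep0 <- multilocus_match_probability(tab, "s0001", thetas,
                                       use_theta = FALSE)
  expect_equal(rep0$p_with_theta, rep0$p_no_theta)

  # scalar theta: every locus gets the fixed value
  repf <- multilocus_match_probability(tab, "s0001", 0.03)
  expect_true(all(repf$theta == 0.03))
})

test_that("with-theta cumulative dominates for all-homozygote profiles", {
  g <- list(L1 = rbind(c("10", "10"), c("10", "11"), c("11", "11")),
            L2 = rbind(c("12", "12"), c("12", "12"), c("13", "13")))
  tab <- tiny_table(g)
  thetas <- data.frame(locus = c("L1", "L2"), theta = c(0.05, 0.1))
  r <- multilocus_match_probability(tab, "t001", thetas)  # both loci homozygous
  expect_true(all(r$p_with_theta >= r$p_no_theta))
  expect_gte(r$cum_with_theta[2], r$cum_no_theta[2])
})

test_that("cohort averages: identity case and geometric log-midpoint", {
  # all samples identical: average equals that sample's frequency, both modes
  g <- list(L1 = matrix(rep(c("10", "11"), 20), ncol = 2, byrow = TRUE))
  tab <- tiny_table(g)
  thetas <- data.frame(locus = "L1", theta = 0.05)
  for (mode in c("geometric", "arithmetic")) {
    coh <- cohort_average_match_probability(tab, thetas, mode = mode)
    expect_equal(coh$mean_freq_no_theta, 2 * 0.5 * 0.5)
    expect_equal(coh$n_samples, 20L)
  }

  # geometric average equals 10^mean(log10 f) over per-sample finals
  set.seed(103)
  freqs <- lapply(stats::setNames(1:6, paste0("L", 1:6)),
                  function(i) equifreq(7))
  tabm <- make_table(list(p = freqs), c(p = 60L))
  th <- data.frame(locus = names(freqs), theta = 0.08)
  finals <- vapply(tabm$samples$sample_id, function(id) {
    r <- multilocus_match_probability(tabm, id, th)
    r$cum_no_theta[nrow(r)]
  }, 0)
  coh <- cohort_average_match_probability(tabm, th)
  expect_equal(coh$mean_freq_no_theta, 10^mean(log10(finals)))
  expect_equal(
    cohort_average_match_probability(tabm, th, mode = "arithmetic")$mean_freq_no_theta,
    mean(finals))
})

test_that("theta correction lifts the cohort average by an order of magnitude", {
  tab <- simulate_study(sim_config(seed = 107L, fis = 0))
  fs <- wc_fstats(tab)
  thetas <- per_locus_theta(fs)
  coh <- cohort_average_match_probability(tab, thetas)
  expect_gte(log10(coh$mean_freq_with_theta) -
               log10(coh$mean_freq_no_theta), 1)
})
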