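test_that("simulation is deterministic and respects configured bounds", {
  cfg <- sim_config(n_loci = 6L, n_per_population = c(a = 25L, b = 30L),
                    seed = 9L)
  t1 <- simulate_study(cfg)
  t2 <- simulate_study(cfg)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(t1, f1)
  write_genotypes(t2, f2)
  expect_identical(readLines(f1), readLines(f2))

  pan <- simulate_panel(cfg)
  expect_identical(pan$panel, simulate_panel(cfg)$panel)
  ks <- vapply(pan$ancestral, length, 0L)
  expect_true(all(ks >= 5L & ks <= 26L))
  expect_true(all(vapply(pan$ancestral, function(p)
    abs(sum(p) - 1) < 1e-12, TRUE)))

  # near-infinite concentration: near-equifrequent spectra
  cfg2 <- sim_config(n_loci = 5L, concentration = 1e4, seed = 10L)
  pan2 <- simulate_panel(cfg2)
  spreads <- vapply(pan2$ancestral, function(p) max(p) - min(p), 0)
  expect_true(all(spreads < 0.05))

  expect_error(sim_config(allele_count_range = c(10L, 5L)))
  expect_error(sim_config(theta_between = 1))
})

test_that("generated tables validate cleanly before corruption", {
  tab <- simulate_study(sim_config(seed = 3L))
  issues <- validate_table(tab)
  expect_false(any(issues$severity == "error"))
})

test_that("theta = 0 with no inbreeding reproduces one panmictic population", {
  tab <- simulate_study(sim_config(theta_between = 0, fis = 0,
                                   n_per_population = c(a = 1000L, b = 1000L),
                                   seed = 15L))
  expect_lt(abs(wc_fstats(tab)$multilocus[["FST"]]), 0.01)
  # HWE holds: few rejections among 15 locus tests at alpha = 0.05
  hwe <- hwe_test_all(tab, populations = "a", n_shuffles = 1000L, seed = 2L)
  expect_lte(sum(hwe$p_value <= 0.05), 3L)
})

test_that("null-allele injection follows the hidden-allele model", {
  cfg <- sim_config(n_loci = 2L, theta_between = 0, fis = 0,
                    n_per_population = c(a = 2000L), seed = 21L)
  tab <- simulate_study(cfg)
  expect_identical(inject_null_alleles(tab, "STR01", "a", 0), tab)

  r <- 0.3
  tab2 <- inject_null_alleles(tab, "STR01", "a", r, seed = 8L)
  # untouched locus is bit-identical
  expect_identical(tab2$genotypes$STR02, tab$genotypes$STR02)
  # missing rate at the locus ~ r^2
  miss <- mean(is.na(tab2$genotypes$STR01[, 1L]))
  expect_lt(abs(miss - r^2), 0.02)
  # apparent homozygote excess appears
  s <- locus_summary(tab2, "STR01", "a")
  expect_lt(s$HO, s$HE)
  expect_error(inject_null_alleles(tab, "nope", "a", 0.1), "unknown locus")
})

test_that("stutter injection only ever rewrites adjacent-size heterozygotes", {
  cfg <- sim_config(n_loci = 1L, theta_between = 0, fis = 0,
                    n_per_population = c(a = 800L), seed = 23L)
  tab <- simulate_study(cfg)
  expect_identical(inject_stutter_errors(tab, "STR01", 0), tab)
  tab2 <- inject_stutter_errors(tab, "STR01", 0.5, seed = 9L)
  before <- tab$genotypes$STR01
  after <- tab2$genotypes$STR01
  changed <- which(before[, 1L] != after[, 1L] | before[, 2L] != after[, 2L])
  expect_gt(length(changed), 0L)
  sizes <- sort(unique(parse_alleles(unique(c(before)))$size))
  for (i in changed) {
    r1 <- match(parse_alleles(before[i, 1L])$size, sizes)
    r2 <- match(parse_alleles(before[i, 2L])$size, sizes)
    expect_identical(abs(r2 - r1), 1L)           # was adjacent heterozygote
    expect_identical(after[i, 1L], before[i, 2L]) # becomes larger-allele hom
    expect_identical(after[i, 2L], before[i, 2L])
  }
})

test_that("breed substructure and sex markers are wired through", {
  cfg <- sim_config(n_loci = 4L, theta_between = 0.08, fis = 0,
                    n_per_population = c(wolf = 40L, dog = 60L),
                    substructure = list(population = "dog",
                                        groups = c(mol = 20L, sam = 20L,
                                                   she = 20L),
                                        theta = 0.03),
                    include_sex_loci = TRUE, seed = 31L)
  tab <- simulate_study(cfg)
  expect_setequal(population_labels(tab),
                  c("wolf", "dog_mol", "dog_sam", "dog_she"))
  expect_identical(nrow(tab$samples), 100L)
  # sex pseudo-loci exist but are excluded from the statistical panel
  expect_true(all(c("DBX", "DBY") %in% tab$panel$locus))
  expect_false(any(c("DBX", "DBY") %in% panel_loci(tab)))
  dby <- tab$genotypes$DBY
  females <- tab$samples$sex == "female"
  expect_true(all(is.na(dby[females, 1L])))
  expect_true(all(dby[!females, 1L] == "1"))
  # substructure is milder than the wolf/dog split
  pf <- pairwise_fst(tab)
  dogs <- grep("dog", rownames(pf))
  expect_lt(mean(pf[dogs, dogs][upper.tri(diag(3))]),
            mean(pf["wolf", dogs]))
})

test_that("the default scenario reproduces the study's qualitative envelope", {
  tab <- simulate_study(sim_config(seed = 47L))
  st <- summarize_loci(tab)
  mean_he <- mean(st$HE[st$locus == "mean"])
  expect_gt(mean_he, 0.6)
  expect_lt(mean_he, 0.85)
  am <- amova(tab, n_perm = 199L, seed = 3L)
  expect_gt(am$pct_among, 5)
  expect_lt(am$pct_among, 12)
  asg <- assignment_test(tab, populations = c("wolf", "dog"))
  expect_gte(mean(asg$per_sample$self_assigned) * 100, 99)
})
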