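test_that("allele labels parse into size and suffix; missing token is distinct", {
  p <- parse_alleles(c("12", "10in", "7", "0"))
  expect_equal(p$size, c(12L, 10L, 7L, 0L))
  expect_equal(p$suffix, c("", "in", "", ""))
  # malformed labels get NA size
  expect_true(is.na(parse_alleles("in10")$size))
  expect_true(is.na(parse_alleles("")$size))
})

test_that("CSV round trip preserves tokens, suffixed alleles and missing data", {
  g <- list(
    FH2001 = rbind(c("12", "10in"), c("10in", "10in"), c(NA, NA)),
    CPH4   = rbind(c("8", "9"), c("9", "9"), c("8", "8")))
  tab <- tiny_table(g, populations = c("wolf", "wolf", "dog"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(tab, f)
  back <- read_genotypes(f)
  expect_identical(back$genotypes, tab$genotypes)
  expect_identical(back$samples$sample_id, tab$samples$sample_id)
  expect_identical(back$panel$locus, tab$panel$locus)
  # suffixed and plain labels of the same size class coexist
  expect_setequal(names(allele_frequencies(back, "FH2001", "wolf")$freqs),
                  c("10in", "12"))
})

test_that("allele order within a pair is canonicalized on construction and read", {
  g1 <- list(L1 = rbind(c("12", "8"), c("9", "12")))
  g2 <- list(L1 = rbind(c("8", "12"), c("12", "9")))
  expect_identical(tiny_table(g1)$genotypes, tiny_table(g2)$genotypes)
  expect_identical(tiny_table(g1)$genotypes$L1[1L, ], c("8", "12"))
  # suffix breaks size ties by token
  g3 <- tiny_table(list(L1 = rbind(c("10in", "10"))))
  expect_identical(g3$genotypes$L1[1L, ], c("10", "10in"))
})

test_that("round trip is the identity on randomly simulated tables", {
  for (s in c(3L, 17L)) {
    tab <- simulate_study(sim_config(n_loci = 4L,
                                     n_per_population = c(a = 12L, b = 15L),
                                     seed = s))
    f <- withr::local_tempfile(fileext = ".csv")
    write_genotypes(tab, f)
    back <- read_genotypes(f)
    expect_identical(back$genotypes, tab$genotypes)
    expect_identical(back$samples, tab$samples)
  }
  # empty sample list: header-only file round trips
  empty <- genotype_table(data.frame(locus = c("L1", "L2")),
                          data.frame(sample_id = character(),
                                     population = character()),
                          list(L1 = matrix(character(), 0, 2),
                               L2 = matrix(character(), 0, 2)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(empty, f)
  expect_identical(nrow(read_genotypes(f)$samples), 0L)
  expect_identical(read_genotypes(f)$panel$locus, c("L1", "L2"))
})

test_that("malformed locus columns are rejected with the locus named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,population,L1,L1.2,L1.3",
               "s1,p,10,12,14"), f)
  expect_error(read_genotypes(f), "L1\\.3")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,population,L1,L1.2,L2",
               "s1,p,10,12,14"), f2)
  expect_error(read_genotypes(f2), "odd number")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1,L1.2", "s1,10,12"), f3)
  expect_error(read_genotypes(f3), "population")
})

test_that("validate_table reports half-missing genotypes, bad labels and untyped loci", {
  clean <- simulate_study(sim_config(n_loci = 3L,
                                     n_per_population = c(a = 20L, b = 20L),
                                     seed = 5L))
  expect_identical(nrow(validate_table(clean)), 0L)

  g <- list(L1 = rbind(c("10", NA), c("10", "12"), c("xx", "10")),
            L2 = rbind(c("10", "10"), c(NA, NA), c(NA, NA)))
  tab <- tiny_table(g, populations = c("a", "a", "b"))
  issues <- validate_table(tab)
  half <- issues[grepl("half-missing", issues$message), ]
  expect_identical(nrow(half), 1L)
  expect_identical(half$severity, "error")
  expect_identical(half$sample_id, "t001")
  bad <- issues[grepl("grammar", issues$message), ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$locus, "L1")
  untyped <- issues[issues$severity == "warning", ]
  expect_identical(untyped$locus, "L2")  # L2 untyped in population b
})

test_that("table construction enforces structural invariants", {
  expect_error(genotype_table(data.frame(locus = c("L1", "L1")),
                              data.frame(sample_id = "s1", population = "p"),
                              list(L1 = matrix("10", 1, 2))),
               "duplicated locus")
  expect_error(genotype_table(data.frame(locus = "L1"),
                              data.frame(sample_id = c("s1", "s1"),
                                         population = "p"),
                              list(L1 = matrix("10", 2, 2))),
               "duplicated sample")
  expect_error(genotype_table(data.frame(locus = "L1", motif_length = 5),
                              data.frame(sample_id = "s1", population = "p"),
                              list(L1 = matrix("10", 1, 2))),
               "motif_length")
})
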