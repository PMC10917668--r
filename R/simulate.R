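# Balding-Nichols simulator of differentiated populations typed at an STR
# panel: ancestral allele frequencies from a symmetric Dirichlet, population
# frequencies from the Balding-Nichols Dirichlet around them (parameterized
# by the subdivision coefficient theta), genotypes drawn with optional
# within-population inbreeding, plus corruption operators (null alleles,
# stutter-like mis-calls) for testing the screening machinery.

#' Simulation configuration
#'
#' Full parameterization of the synthetic-genotype generator. The defaults
#' describe the study conditions the package's validation targets: two
#' strongly differentiated populations — a wolf-like sample of 103 and a
#' dog-like sample of 198 individuals — typed at 15 autosomal tetranucleotide
#' STR loci carrying 5 to 26 alleles each, separated by a subdivision
#' coefficient of 0.08, with the wolf-like sample panmictic and mild
#' inbreeding (0.05) in the dog-like sample reflecting breed management.
#'
#' @param n_loci number of autosomal loci (default 15).
#' @param allele_count_range integer pair: inclusive bounds on the per-locus
#'   allele count (default `c(5, 26)`).
#' @param concentration symmetric Dirichlet concentration for ancestral
#'   frequencies (default 1: uninformative, yields a mix of balanced and
#'   skewed spectra as real STR panels show).
#' @param theta_between Balding-Nichols subdivision coefficient of each
#'   population against the ancestral pool, in `[0, 1)` (default 0.08).
#' @param fis within-population inbreeding coefficient, a single value or a
#'   named vector per population (default `c(wolf = 0, dog = 0.05)`).
#' @param n_per_population named integer vector of sample sizes
#'   (default `c(wolf = 103, dog = 198)`).
#' @param substructure optional list `list(population=, groups=, theta=)`
#'   replacing one population by named subgroups (a second-level
#'   Balding-Nichols draw inside it, emulating breed groups); `groups` is a
#'   named integer vector of subgroup sizes. Default `NULL` (off).
#' @param include_sex_loci also emit DBX/DBY presence-absence pseudo-loci
#'   (marker class `"sex"`, excluded from every statistic)? Default `FALSE`.
#' @param seed integer seed; identical configs give identical tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 15L,
                       allele_count_range = c(5L, 26L),
                       concentration = 1,
                       theta_between = 0.08,
                       fis = c(wolf = 0, dog = 0.05),
                       n_per_population = c(wolf = 103L, dog = 198L),
                       substructure = NULL,
                       include_sex_loci = FALSE,
                       seed = 1L) {
  stopifnot(n_loci >= 1L, length(allele_count_range) == 2L,
            allele_count_range[1L] >= 2L,
            allele_count_range[2L] >= allele_count_range[1L],
            concentration > 0,
            theta_between >= 0, theta_between < 1,
            all(fis >= 0 & fis < 1),
            length(n_per_population) >= 1L, all(n_per_population >= 1L),
            !is.null(names(n_per_population)))
  if (!is.null(substructure)) {
    stopifnot(is.list(substructure),
              substructure$population %in% names(n_per_population),
              !is.null(names(substructure$groups)),
              substructure$theta >= 0, substructure$theta < 1)
  }
  structure(list(n_loci = as.integer(n_loci),
                 allele_count_range = as.integer(allele_count_range),
                 concentration = concentration,
                 theta_between = theta_between,
                 fis = fis,
                 n_per_population = n_per_population,
                 substructure = substructure,
                 include_sex_loci = isTRUE(include_sex_loci),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw: Dirichlet(p_i * (1 - theta)/theta) around ancestral
# frequencies p; theta = 0 returns p exactly
.bn_draw <- function(p, theta) {
  if (theta == 0) return(p)
  g <- stats::rgamma(length(p), shape = p * (1 - theta) / theta)
  if (sum(g) == 0) {  # numerically degenerate shapes: fix the largest
    g[which.max(p)] <- 1
  }
  names(g) <- names(p)
  g / sum(g)
}

#' Simulate an STR panel with ancestral allele frequencies
#'
#' Draws per-locus allele counts uniformly from `allele_count_range` and
#' ancestral allele frequencies from a symmetric Dirichlet with the
#' configured concentration. Allele labels are consecutive size tokens
#' starting at 8 (arbitrary but realistic repeat numbers). Runs under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `panel` (data.frame: `locus`, `motif_length`,
#'   `marker_class`) and `ancestral` (named list of frequency vectors).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rng <- config$allele_count_range
    loci <- sprintf("STR%02d", seq_len(config$n_loci))
    panel <- data.frame(locus = loci, motif_length = 4L,
                        marker_class = "autosomal", stringsAsFactors = FALSE)
    ancestral <- lapply(loci, function(l) {
      k <- sample(seq(rng[1L], rng[2L]), 1L)
      g <- stats::rgamma(k, shape = config$concentration)
      p <- g / sum(g)
      names(p) <- as.character(seq(8L, length.out = k))
      p
    })
    names(ancestral) <- loci
    if (config$include_sex_loci) {
      panel <- rbind(panel,
                     data.frame(locus = c("DBX", "DBY"), motif_length = 4L,
                                marker_class = "sex",
                                stringsAsFactors = FALSE))
    }
    list(panel = panel, ancestral = ancestral)
  })
}

# draw n genotypes (n x 2 token matrix) from allele frequencies p with
# inbreeding coefficient fis: P(hom ii) = p_i^2 + fis p_i (1 - p_i),
# P(het ij) = 2 p_i p_j (1 - fis)
.draw_genotypes <- function(n, p, fis) {
  k <- length(p)
  ibd <- stats::runif(n) < fis
  a <- sample.int(k, n, replace = TRUE, prob = p)
  b <- ifelse(ibd, a, sample.int(k, n, replace = TRUE, prob = p))
  cbind(names(p)[a], names(p)[b])
}

#' Simulate genotype tables for differentiated populations
#'
#' For every population, per-locus allele frequencies are drawn from the
#' Balding-Nichols Dirichlet around the ancestral frequencies
#' (`alpha_i = p_i (1 - theta)/theta`, independent draws per population, so
#' each population sits at subdivision `theta_between` from the ancestral
#' pool); individuals are then drawn with within-population inbreeding
#' `fis` (genotype probabilities `p_i^2 + fis p_i (1-p_i)` and
#' `2 p_i p_j (1 - fis)`). With substructure enabled, the configured
#' population's frequencies become the midpoint of a second-level
#' Balding-Nichols draw for each subgroup. Runs under `config$seed + 1` so a
#' panel and its populations can be generated by separate calls yet remain
#' jointly reproducible.
#'
#' @param panel,ancestral output of [simulate_panel()].
#' @param config a [sim_config()].
#' @return A [genotype_table()].
#' @export
simulate_populations <- function(panel, ancestral, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    pops <- config$n_per_population
    # expand substructure into subgroup labels with their own frequency draw
    units <- list()  # label -> list(n, extra_theta)
    for (pn in names(pops)) {
      ss <- config$substructure
      if (!is.null(ss) && ss$population == pn) {
        for (gn in names(ss$groups)) {
          units[[paste(pn, gn, sep = "_")]] <-
            list(n = ss$groups[[gn]], parent = pn, theta2 = ss$theta)
        }
      } else {
        units[[pn]] <- list(n = pops[[pn]], parent = pn, theta2 = 0)
      }
    }
    fis_of <- function(pn) {
      f <- config$fis
      if (length(f) == 1L && is.null(names(f))) return(unname(f))
      if (pn %in% names(f)) unname(f[[pn]]) else 0
    }
    n_tot <- sum(vapply(units, function(u) u$n, 0))
    sample_id <- sprintf("S%04d", seq_len(n_tot))
    population <- rep(names(units), vapply(units, function(u) u$n, 0))
    sex <- sample(c("male", "female"), n_tot, replace = TRUE)
    aut <- panel$locus[panel$marker_class == "autosomal"]
    genotypes <- vector("list", nrow(panel))
    names(genotypes) <- panel$locus
    for (l in aut) {
      m <- matrix(NA_character_, n_tot, 2L)
      for (un in names(units)) {
        u <- units[[un]]
        pfreq <- .bn_draw(ancestral[[l]], config$theta_between)
        if (u$theta2 > 0) pfreq <- .bn_draw(pfreq, u$theta2)
        rows <- which(population == un)
        m[rows, ] <- .draw_genotypes(length(rows), pfreq, fis_of(u$parent))
      }
      genotypes[[l]] <- m
    }
    for (l in setdiff(panel$locus, aut)) {
      # sex markers as presence/absence pseudo-genotypes
      m <- matrix(NA_character_, n_tot, 2L)
      if (l == "DBY") {
        male <- sex == "male"
        m[male, ] <- "1"
      } else {
        m[, ] <- "1"
      }
      genotypes[[l]] <- m
    }
    genotype_table(panel, data.frame(sample_id = sample_id,
                                     population = population, sex = sex,
                                     stringsAsFactors = FALSE),
                   genotypes)
  })
}

#' Simulate a complete study table in one call
#'
#' [simulate_panel()] followed by [simulate_populations()].
#'
#' @param config a [sim_config()].
#' @return A [genotype_table()].
#' @examples
#' tab <- simulate_study(sim_config(n_loci = 4, seed = 7))
#' tab
#' @export
simulate_study <- function(config) {
  pan <- simulate_panel(config)
  simulate_populations(pan$panel, pan$ancestral, config)
}

#' Inject null alleles into one locus of one population
#'
#' Applies the standard null-allele model: a hidden non-amplifying allele of
#' frequency `r` segregates at the locus, so each allele copy of each
#' individual independently becomes null with probability `r`. A
#' visible/null heterozygote is observed as an apparent homozygote for the
#' visible allele; a null/null genotype is observed as missing. All other
#' loci and populations are untouched, and `r = 0` is an exact identity.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population population label.
#' @param r null-allele frequency in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A modified [genotype_table()].
#' @export
inject_null_alleles <- function(table, locus, population, r, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"), r >= 0, r < 1)
  if (!locus %in% table$panel$locus) {
    .stop_arg("unknown locus ", sQuote(locus, q = FALSE))
  }
  if (r == 0) return(table)
  with_seed(seed, {
    m <- table$genotypes[[locus]]
    rows <- which(table$samples$population %in% population &
                    !is.na(m[, 1L]) & !is.na(m[, 2L]))
    null1 <- stats::runif(length(rows)) < r
    null2 <- stats::runif(length(rows)) < r
    for (i in seq_along(rows)) {
      rw <- rows[i]
      if (null1[i] && null2[i]) {
        m[rw, ] <- NA_character_
      } else if (null1[i]) {
        m[rw, 1L] <- m[rw, 2L]
      } else if (null2[i]) {
        m[rw, 2L] <- m[rw, 1L]
      }
    }
    table$genotypes[[locus]] <- m
    table
  })
}

#' Inject stutter-like genotyping errors into one locus
#'
#' Emulates the classical stutter mis-call: with probability `rate`, a
#' heterozygote whose two alleles occupy adjacent size classes (consecutive
#' ranks in the sorted distinct allele sizes of the locus) is rewritten as a
#' homozygote for the larger allele. Non-adjacent heterozygotes and
#' homozygotes are never modified; `rate = 0` is an exact identity.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param rate mis-call probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return A modified [genotype_table()].
#' @export
inject_stutter_errors <- function(table, locus, rate, seed = NULL) {
  stopifnot(inherits(table, "genotype_table"), rate >= 0, rate < 1)
  if (!locus %in% table$panel$locus) {
    .stop_arg("unknown locus ", sQuote(locus, q = FALSE))
  }
  if (rate == 0) return(table)
  with_seed(seed, {
    m <- table$genotypes[[locus]]
    typed <- !is.na(m[, 1L]) & !is.na(m[, 2L])
    sizes <- sort(unique(parse_alleles(unique(c(m[typed, ])))$size))
    rank1 <- match(parse_alleles(m[, 1L])$size, sizes)
    rank2 <- match(parse_alleles(m[, 2L])$size, sizes)
    adjacent <- typed & m[, 1L] != m[, 2L] & abs(rank2 - rank1) == 1L
    hit <- adjacent & stats::runif(nrow(m)) < rate
    # pairs are size-canonicalized, so column 2 holds the larger allele
    m[hit, 1L] <- m[hit, 2L]
    table$genotypes[[locus]] <- m
    table
  })
}
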