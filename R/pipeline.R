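# End-to-end workflow wrapper: simulate (or read) -> validate -> summary
# statistics -> HWE / null screening -> panel triage -> F-statistics /
# AMOVA -> assignment -> match probabilities, writing one flat CSV per stage
# plus a machine-readable JSON summary for forensic audit trails.

#' Run the full analysis pipeline
#'
#' Executes every analysis stage of the package on an input genotype table
#' (or on a freshly simulated one), writing per-stage CSV reports and a JSON
#' summary to `out_dir`. All Monte-Carlo stages receive seeds derived
#' deterministically from `seed`, and the summary logs the package version,
#' seeds and thresholds, so any stage can be reproduced by calling the
#' corresponding function with the logged parameters. Fatal validation
#' errors stop the pipeline before any downstream report is written and are
#' reflected in a nonzero status.
#'
#' @param out_dir output directory (created if needed; must not contain the
#'   input file).
#' @param input path to a genotype CSV ([read_genotypes()] dialect), or
#'   `NULL` to simulate.
#' @param config a [sim_config()] used when `input` is `NULL`.
#' @param seed master integer seed.
#' @param criteria [filter_criteria()] for the triage stage.
#' @param n_perm AMOVA permutations (default 999).
#' @param assign_populations two population labels for the assignment stage
#'   (default: the two largest).
#' @param verbose print stage progress?
#' @return Invisibly, a list with `status` (0 = success, 1 = validation
#'   failure), `files` (named vector of written report paths) and `summary`
#'   (the JSON summary as a list).
#' @export
run_pipeline <- function(out_dir, input = NULL, config = sim_config(),
                         seed = 1L, criteria = filter_criteria(),
                         n_perm = 999L, assign_populations = NULL,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- character(0)
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files[name] <<- path
    path
  }

  if (is.null(input)) {
    say("stage simulate: generating study table")
    config$seed <- as.integer(seed)
    tab <- simulate_study(config)
    write_genotypes(tab, file.path(out_dir, "genotypes.csv"))
    files["genotypes"] <- file.path(out_dir, "genotypes.csv")
  } else {
    if (normalizePath(dirname(input)) == normalizePath(out_dir)) {
      .stop_arg("out_dir must not contain the input file")
    }
    say("stage read: ", input)
    tab <- read_genotypes(input)
  }

  say("stage validate")
  issues <- validate_table(tab)
  emit("validation", issues)
  if (any(issues$severity == "error")) {
    say("validation errors: pipeline aborted")
    return(invisible(list(status = 1L, files = files,
                          summary = list(error = "validation failed"))))
  }

  say("stage stats")
  emit("locus_stats", summarize_loci(tab))

  say("stage hwe/null")
  hwe <- hwe_test_all(tab, n_shuffles = criteria$n_shuffles,
                      seed = seed + 100L)
  hwe <- bonferroni_adjust(hwe, alpha = criteria$hwe_alpha,
                           family = "population")
  emit("hwe", hwe)
  st <- summarize_loci(tab)
  st <- st[st$locus != "mean", ]
  nulls <- cbind(st[c("locus", "population", "HO", "HE")],
                 null_allele_estimates(st$HO, st$HE,
                                       criteria$null_threshold))
  emit("null_alleles", nulls)

  say("stage select")
  report <- apply_locus_filters(tab, criteria = criteria,
                                seed = seed + 200L)
  emit("panel_filter", as.data.frame(report))
  retained <- attr(report, "retained")
  if (length(retained) < 2L) retained <- panel_loci(tab)

  say("stage fstats")
  fs <- wc_fstats(tab, loci = retained)
  per <- fs$per_locus
  multi <- data.frame(locus = "multilocus", a = NA, b = NA, c = NA,
                      FIS = fs$multilocus[["FIS"]],
                      FST = fs$multilocus[["FST"]],
                      FIT = fs$multilocus[["FIT"]],
                      stringsAsFactors = FALSE)
  emit("fstats", rbind(per, multi))

  say("stage amova")
  am <- amova(tab, loci = retained, n_perm = n_perm, seed = seed + 300L)
  emit("amova", data.frame(sigma_among = am$sigma_among,
                           sigma_within = am$sigma_within,
                           pct_among = am$pct_among,
                           pct_within = am$pct_within,
                           phi_st = am$phi_st, p_perm = am$p_perm,
                           n_perm = am$n_perm))

  say("stage assign")
  asg <- assignment_test(tab, populations = assign_populations,
                         loci = retained)
  emit("assignment", asg$per_sample)
  emit("assignment_summary", asg$summary)

  say("stage match")
  thetas <- per_locus_theta(fs)
  coh <- cohort_average_match_probability(tab, thetas, loci = retained)
  emit("match_cohort",
       data.frame(mode = coh$mode, n_samples = coh$n_samples,
                  mean_freq_no_theta = coh$mean_freq_no_theta,
                  mean_freq_with_theta = coh$mean_freq_with_theta))

  summary <- list(
    package_version = as.character(utils::packageVersion("strpopgen")),
    seed = seed,
    thresholds = unclass(criteria),
    n_samples = nrow(tab$samples),
    populations = as.list(table(tab$samples$population)),
    retained_panel = retained,
    multilocus_fst = unname(fs$multilocus[["FST"]]),
    amova_pct_among = am$pct_among,
    amova_p = am$p_perm,
    assignment_pct_self = stats::setNames(
      as.list(asg$summary$pct_self_assigned), asg$summary$population),
    cohort_mean_freq_no_theta = coh$mean_freq_no_theta,
    cohort_mean_freq_with_theta = coh$mean_freq_with_theta)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["summary"] <- summary_path
  say("pipeline complete: ", length(files), " reports in ", out_dir)
  invisible(list(status = 0L, files = files, summary = summary))
}
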