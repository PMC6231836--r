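#' End-to-end run configuration
#'
#' Bundles everything one reproducible run needs: generator parameters,
#' program configuration, timeline, which missing-data approaches and strata
#' to analyze, and the master seed. The seed fixes the whole run — population
#' generation, challenge-acceptance draws, and therefore every model input.
#'
#' @param params A [population_params()] (its seed is overridden by `seed`).
#' @param cfg A [program_config()].
#' @param timeline A [program_timeline()].
#' @param approaches Subset of `c("any", "completer", "imputed")`.
#' @param strata Stratum names for [run_subgroup_suite()]; NULL = all.
#' @param seed Master integer seed.
#' @param compute_f2 Compute local effect sizes in the model suite.
#' @return A `run_config` object.
#' @export
run_config <- function(params = population_params(),
                       cfg = program_config(),
                       timeline = program_timeline(cfg),
                       approaches = c("any", "completer", "imputed"),
                       strata = NULL,
                       seed = 1L,
                       compute_f2 = TRUE) {
  stopifnot(all(approaches %in% c("any", "completer", "imputed")),
            length(approaches) >= 1)
  params$seed <- as.integer(seed)
  rc <- list(params = params, cfg = cfg, timeline = timeline,
             approaches = approaches, strata = strata,
             seed = as.integer(seed), compute_f2 = compute_f2)
  class(rc) <- "run_config"
  rc
}

#' Run the full evaluation pipeline
#'
#' Generate a population, run the program engine for every participant, build
#' the analytic samples, fit the stratified model suite (and the engagement
#' moderation model) on the requested approaches, and write every artifact to
#' `out_dir`: diaries and covariates, the ledger event table, one sample CSV
#' per approach, one results CSV per approach, the weekly LS-means of the
#' total-sample fit, and a JSON manifest recording the seed, a configuration
#' hash, and the counts at every filtering stage (generated, valid baseline,
#' and per-approach n) — the participant-flow accounting of the run.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must be writable).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the manifest, samples, and suite results.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create `out_dir`", call. = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("generating population (n = ", config$params$n_participants,
      ", seed = ", config$seed, ")")
  pop <- generate_population(config$params, config$timeline)
  write_diaries(pop, out_dir)

  say("running program engine")
  ledgers <- run_program_population(pop, config$cfg, config$timeline,
                                    acceptance = "engagement",
                                    seed = config$seed + 1L)
  readr::write_csv(ledger_events(ledgers), file.path(out_dir, "ledger.csv"))
  eng <- classify_engagement(ledgers, config$cfg)

  counts <- approach_counts(pop, config$cfg,
                            n_study_weeks = config$timeline$n_study_weeks)

  samples <- list(); results <- list()
  for (ap in config$approaches) {
    say("building `", ap, "` sample and fitting models")
    smp <- build_sample(pop, config$cfg, ap, engagement = eng$labels,
                        n_study_weeks = config$timeline$n_study_weeks)
    samples[[ap]] <- smp
    readr::write_csv(smp, file.path(out_dir, paste0("sample_", ap, ".csv")))
    suite <- run_subgroup_suite(smp, strata = config$strata,
                                compute_f2 = config$compute_f2)
    results[[ap]] <- suite
    readr::write_csv(suite$table,
                     file.path(out_dir, paste0("results_", ap, ".csv")))
    if ("total" %in% suite$table$stratum &&
        !is.null(suite$fits$total$lsmeans)) {
      readr::write_csv(suite$fits$total$lsmeans,
                       file.path(out_dir, paste0("weekly_lsmeans_", ap, ".csv")))
    }
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[c("params", "cfg", "approaches",
                                       "strata")]),
    engagement_median = eng$median,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: artifacts in ", out_dir)
  invisible(list(manifest = manifest, samples = samples, results = results,
                 engagement = eng))
}

#' Summarize a completed pipeline run
#'
#' Reads the results CSVs of a run directory and formats a plain-text report:
#' per-stratum baseline and week-12 LS-means, differences with CIs, effect
#' sizes, and the percent difference of the intervention period over baseline
#' computed from the weekly LS-means file. The report performs no statistics
#' of its own beyond that percent-difference formula; every number is
#' traceable to a results CSV cell. Strata whose fit did not converge are
#' flagged rather than summarized.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @param approach Which approach's results to report.
#' @return Character vector of report lines (also printed).
#' @export
report_summary <- function(out_dir, approach = "any") {
  res_path <- file.path(out_dir, paste0("results_", approach, ".csv"))
  if (!file.exists(res_path)) {
    stop("missing results file: ", res_path, call. = FALSE)
  }
  tab <- readr::read_csv(res_path, show_col_types = FALSE)
  lines <- c(
    sprintf("Weekly mixed-model results (%s approach)", approach),
    sprintf("%-15s %6s %12s %12s %22s %8s", "stratum", "n", "baseline",
            "week12", "diff (95% CI)", "f2"))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (isTRUE(is.na(r$converged)) || !isTRUE(r$converged)) {
      lines <- c(lines, sprintf("%-15s %6d %s", r$stratum, r$n,
                                "  [no estimates: empty stratum or non-convergence]"))
      next
    }
    lines <- c(lines, sprintf(
      "%-15s %6d %12.2f %12.2f %9.2f (%0.2f, %0.2f) %8.4f",
      r$stratum, r$n, r$baseline_lsmean, r$week12_lsmean, r$diff,
      r$diff_ci_lo, r$diff_ci_hi, r$cohen_f2))
  }
  wk_path <- file.path(out_dir, paste0("weekly_lsmeans_", approach, ".csv"))
  if (file.exists(wk_path)) {
    wk <- readr::read_csv(wk_path, show_col_types = FALSE)
    base <- wk$estimate[wk$study_week == 0]
    intervention <- mean(wk$estimate[wk$study_week > 0])
    lines <- c(lines, sprintf(
      "Intervention-period mean vs baseline: %+.2f steps/day (%+.2f%%)",
      intervention - base, 100 * (intervention - base) / base))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
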