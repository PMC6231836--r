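#' Weekly validity and weekly mean steps
#'
#' Study week w (1..12) spans diary days `14 + 7(w-1) + 1 .. 14 + 7w`. A week
#' is valid when at least 4 of its 7 days are valid days (counts in
#' \[1000, 40000\]); its weekly mean averages the valid days only. Week 0 is
#' the run-in baseline: valid when the participant has a personalized
#' baseline (>= 5 valid run-in days), with mean equal to the baseline mean.
#'
#' @param diaries Long tibble (participant_id, day, steps) covering run-in
#'   plus the study weeks.
#' @param cfg A [program_config()].
#' @param n_study_weeks Number of post-run-in study weeks (default 12).
#' @return Tibble: participant_id, study_week (0..n), n_valid_days, valid,
#'   mean_steps (NA when invalid).
#' @export
weekly_means <- function(diaries, cfg = program_config(), n_study_weeks = 12L) {
  need <- cfg$baseline_days + 7L * n_study_weeks
  span <- diaries |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(t = max(.data$day), .groups = "drop")
  if (any(span$t < need)) {
    stop("diaries must cover run-in + ", 7L * n_study_weeks, " days (",
         need, " days total)", call. = FALSE)
  }
  d <- diaries[diaries$day <= need, ]
  week <- study_week_of_day(d$day, cfg$baseline_days)
  valid_day <- is_valid_day(d$steps, cfg)
  pid <- factor(d$participant_id)
  n_weeks <- n_study_weeks + 1L
  grp <- (as.integer(pid) - 1L) * n_weeks + week + 1L
  # aggregate valid-day counts and valid-step sums per participant-week in one
  # pass; rowsum keeps this linear in the diary length
  all_grp <- seq_len(nlevels(pid) * n_weeks)
  rs <- rowsum(cbind(as.numeric(valid_day), d$steps * as.numeric(valid_day)),
               grp)
  idx <- match(all_grp, as.integer(rownames(rs)))
  n_valid <- ifelse(is.na(idx), 0, rs[idx, 1])
  step_sum <- ifelse(is.na(idx), 0, rs[idx, 2])
  out <- tibble::tibble(
    participant_id = rep(levels(pid), each = n_weeks),
    study_week = rep.int(0L:n_study_weeks, nlevels(pid)),
    n_valid_days = as.integer(n_valid)
  )
  out$valid <- ifelse(out$study_week == 0L,
                      out$n_valid_days >= cfg$min_valid_days,
                      out$n_valid_days >= 4L)
  out$mean_steps <- ifelse(out$valid, step_sum / n_valid, NA_real_)
  out
}

#' Physical-activity classification at baseline
#'
#' Participants averaging fewer than 5,000 steps/day at baseline are
#' classified physically inactive (Tudor-Locke cutoff); at or above the
#' cutoff, physically active.
#'
#' @param baseline_mean Baseline mean steps/day (vectorized).
#' @param threshold Cutoff in steps/day.
#' @return Character vector, `"inactive"` or `"active"`.
#' @export
classify_activity <- function(baseline_mean, threshold = 5000) {
  stopifnot(all(is.finite(baseline_mean)))
  ifelse(baseline_mean < threshold, "inactive", "active")
}

#' Engagement metric and median split
#'
#' A participant's engagement is the percentage of challenge-phase days
#' covered by an accepted step-up challenge window (the auto-enrolled first
#' window counts, so the metric is at least 14/56 = 25% under the reference
#' timeline). Participants strictly above the sample median are labelled
#' `"high"`; ties at the median go to `"low"`.
#'
#' @param ledgers Named list of `participant_ledger` objects over a common
#'   timeline.
#' @param cfg A [program_config()].
#' @return List with `labels` (tibble: participant_id, engagement_metric,
#'   engagement) and `median` (the sample median of the metric).
#' @export
classify_engagement <- function(ledgers, cfg = program_config()) {
  if (length(ledgers) == 0) stop("empty cohort", call. = FALSE)
  metric <- vapply(ledgers, function(lg) {
    sum(lg$challenges$accepted) * cfg$challenge_window /
      (cfg$n_challenges * cfg$challenge_window)
  }, numeric(1))
  ids <- vapply(ledgers, function(lg) lg$participant_id, character(1))
  med <- stats::median(metric)
  list(
    labels = tibble::tibble(
      participant_id = unname(ids),
      engagement_metric = unname(metric),
      engagement = ifelse(metric > med, "high", "low")
    ),
    median = med
  )
}

#' Participant counts at every filtering stage
#'
#' The participant-flow accounting of one population: generated, valid
#' baseline, and the participant count of each missing-data approach,
#' regardless of which approaches a run builds.
#'
#' @param pop A `step_population`.
#' @param cfg A [program_config()].
#' @param n_study_weeks Number of study weeks (default 12).
#' @return Named list of integer counts.
#' @export
approach_counts <- function(pop, cfg = program_config(), n_study_weeks = 12L) {
  wk <- weekly_means(pop$diaries, cfg, n_study_weeks)
  base_ok <- wk$participant_id[wk$study_week == 0L & wk$valid]
  wk12_ok <- wk$participant_id[wk$study_week == n_study_weeks & wk$valid]
  anyw <- unique(wk$participant_id[wk$study_week > 0L & wk$valid])
  list(
    generated = dplyr::n_distinct(pop$diaries$participant_id),
    valid_baseline = length(base_ok),
    n_any = sum(base_ok %in% anyw),
    n_completer = sum(base_ok %in% wk12_ok),
    n_imputed = sum(!base_ok %in% wk12_ok)
  )
}

#' Build an analytic sample under one missing-data approach
#'
#' Constructs the long participant-by-study-week table fed to the mixed
#' model. Participants without a personalized baseline (fewer than 5 valid
#' run-in days) are excluded from every approach. The three approaches are:
#'
#' * `"any"` — participants with a valid baseline and at least one valid week
#'   among weeks 1..12; all their valid weeks enter.
#' * `"completer"` — participants with a valid baseline and a valid week 12.
#' * `"imputed"` — participants with a valid baseline but no valid week 12;
#'   a pseudo week-12 row equal to their baseline value is added
#'   (last-observation-carried-forward), flagged `imputed_flag = TRUE`.
#'
#' @param pop A `step_population`.
#' @param cfg A [program_config()].
#' @param approach One of `"any"`, `"completer"`, `"imputed"`.
#' @param engagement Optional engagement label table from
#'   [classify_engagement()].
#' @param n_study_weeks Number of study weeks (default 12).
#' @return Tibble: participant_id, study_week, mean_steps, approach,
#'   imputed_flag, activity_status, engagement (NA when no labels given),
#'   age, gender, province, income.
#' @export
build_sample <- function(pop, cfg = program_config(),
                         approach = c("any", "completer", "imputed"),
                         engagement = NULL, n_study_weeks = 12L) {
  approach <- match.arg(approach)
  wk <- weekly_means(pop$diaries, cfg, n_study_weeks)
  base <- wk |>
    dplyr::filter(.data$study_week == 0L, .data$valid) |>
    dplyr::select("participant_id", baseline_mean = "mean_steps")
  wk12 <- wk |>
    dplyr::filter(.data$study_week == n_study_weeks) |>
    dplyr::select("participant_id", wk12_valid = "valid")
  status <- dplyr::left_join(base, wk12, by = "participant_id")
  any_valid <- wk |>
    dplyr::filter(.data$study_week > 0L, .data$valid) |>
    dplyr::distinct(.data$participant_id) |>
    dplyr::mutate(has_week = TRUE)
  status <- dplyr::left_join(status, any_valid, by = "participant_id") |>
    dplyr::mutate(has_week = !is.na(.data$has_week))

  keep <- switch(approach,
    any = status$participant_id[status$has_week],
    completer = status$participant_id[status$wk12_valid],
    imputed = status$participant_id[!status$wk12_valid]
  )
  rows <- wk |>
    dplyr::filter(.data$participant_id %in% keep, .data$valid) |>
    dplyr::select("participant_id", "study_week", "mean_steps") |>
    dplyr::mutate(imputed_flag = FALSE)
  if (approach == "imputed") {
    pseudo <- status |>
      dplyr::filter(.data$participant_id %in% keep) |>
      dplyr::transmute(.data$participant_id,
                       study_week = as.integer(n_study_weeks),
                       mean_steps = .data$baseline_mean,
                       imputed_flag = TRUE)
    rows <- dplyr::bind_rows(rows, pseudo)
  }
  labels <- status |>
    dplyr::filter(.data$participant_id %in% keep) |>
    dplyr::transmute(.data$participant_id,
                     activity_status = classify_activity(.data$baseline_mean))
  if (!is.null(engagement)) {
    labels <- dplyr::left_join(
      labels, engagement[, c("participant_id", "engagement")],
      by = "participant_id")
  } else {
    labels$engagement <- NA_character_
  }
  rows |>
    dplyr::mutate(approach = approach) |>
    dplyr::left_join(labels, by = "participant_id") |>
    dplyr::left_join(pop$covariates, by = "participant_id") |>
    dplyr::arrange(.data$participant_id, .data$study_week) |>
    dplyr::select("participant_id", "study_week", "mean_steps", "approach",
                  "imputed_flag", "activity_status", "engagement", "age",
                  "gender", "province", "income")
}
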