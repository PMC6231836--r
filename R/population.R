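#' Population generator parameters
#'
#' Parameters of the synthetic step-diary generator. Defaults are calibrated
#' so that, at large n, the generated population reproduces the program's
#' reported baseline marginals: mean age 33.7 (SD 11.6) years, 66.1% female,
#' ~71% from British Columbia, mean baseline ~6,511 steps/day with heavy right
#' skew, and just over half of participants below 5,000 steps/day at baseline.
#'
#' The daily latent mean is `exp(N(log_steps_mu, log_steps_sigma))` plus
#' centred gender and province offsets (`gender_gap` = male minus female;
#' `province_gap` = BC minus NL). On goal-active days a participant adds
#' `response_effect * plogis(engagement_propensity)` steps, decaying by
#' `decay_rate` steps per week after `decay_onset_week`; i.i.d. Gaussian daily
#' noise is added, counts are rounded and floored at zero, and with
#' probability `nonwear_prob` a day is overwritten by a non-wear count drawn
#' uniformly from 0-999 steps.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; fixes the whole population.
#' @param age_mean,age_sd Age distribution, years (normal, floored at 13, the
#'   program's minimum age).
#' @param prop_female Fraction of female participants.
#' @param prop_bc Fraction of participants from British Columbia (the rest are
#'   from Newfoundland and Labrador).
#' @param income_mean,income_sd Median personal income, Can$1000/yr.
#' @param log_steps_mu,log_steps_sigma Lognormal parameters of the latent
#'   daily step mean (log-steps).
#' @param gender_gap Steps/day, male minus female.
#' @param province_gap Steps/day, BC minus NL.
#' @param nonwear_prob Probability that a day records a non-wear count
#'   (< 1000 steps).
#' @param response_effect Steps/day added on goal-active days for a fully
#'   engaged responder (engagement factor 1).
#' @param engagement_propensity_mean,engagement_propensity_sd Latent
#'   engagement trait distribution (dimensionless; the logistic transform of
#'   the trait is the engagement factor scaling the response and driving
#'   challenge acceptance).
#' @param decay_rate Steps/day lost from the response term per week after the
#'   onset week.
#' @param decay_onset_week Study week after which behavioral decay begins.
#' @param noise_sd Daily i.i.d. noise, steps.
#' @return A validated `population_params` object.
#' @export
population_params <- function(n_participants = 1000L,
                              seed = 1L,
                              age_mean = 33.7,
                              age_sd = 11.6,
                              prop_female = 0.661,
                              prop_bc = 0.714,
                              income_mean = 29.65,
                              income_sd = 4.1,
                              log_steps_mu = 8.20,
                              log_steps_sigma = 0.90,
                              gender_gap = 2297.5,
                              province_gap = 992.95,
                              nonwear_prob = 0.40,
                              response_effect = 800,
                              engagement_propensity_mean = 0,
                              engagement_propensity_sd = 1,
                              decay_rate = 100,
                              decay_onset_week = 9L,
                              noise_sd = 1500) {
  p <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, prop_female = prop_female,
    prop_bc = prop_bc, income_mean = income_mean, income_sd = income_sd,
    log_steps_mu = log_steps_mu, log_steps_sigma = log_steps_sigma,
    gender_gap = gender_gap, province_gap = province_gap,
    nonwear_prob = nonwear_prob, response_effect = response_effect,
    engagement_propensity_mean = engagement_propensity_mean,
    engagement_propensity_sd = engagement_propensity_sd,
    decay_rate = decay_rate, decay_onset_week = as.integer(decay_onset_week),
    noise_sd = noise_sd
  )
  class(p) <- "population_params"
  validate_population_params(p)
  p
}

validate_population_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  fracs <- c("prop_female", "prop_bc", "nonwear_prob")
  for (nm in fracs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter `", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  sds <- c("age_sd", "income_sd", "log_steps_sigma",
           "engagement_propensity_sd", "noise_sd")
  for (nm in sds) {
    if (p[[nm]] < 0) stop("parameter `", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (p$response_effect < 0) stop("`response_effect` must be >= 0", call. = FALSE)
  if (p$decay_rate < 0) stop("`decay_rate` must be >= 0", call. = FALSE)
  invisible(p)
}

# Centred covariate offsets: population-mean zero so the marginal mean of the
# latent step distribution stays at exp(mu + sigma^2/2).
gender_offset <- function(gender, p) {
  ifelse(gender == "male", p$gender_gap * p$prop_female,
         -p$gender_gap * (1 - p$prop_female))
}

province_offset <- function(province, p) {
  ifelse(province == "BC", p$province_gap * (1 - p$prop_bc),
         -p$province_gap * p$prop_bc)
}

# Study week of a diary day: 0 during run-in, 1..n after.
study_week_of_day <- function(day, baseline_days = 14L) {
  ifelse(day <= baseline_days, 0L, (day - baseline_days - 1L) %/% 7L + 1L)
}

#' Closed-form expected daily steps under the generator
#'
#' The deterministic latent mean for one participant-day: lognormal draw plus
#' centred covariate offsets plus the (possibly decayed) incentive response,
#' before noise, rounding and non-wear overwrites. With `nonwear_prob = 0` and
#' `noise_sd = 0` the generated diary equals `round()` of this value floored
#' at zero; tests use this as an independent recomputation.
#'
#' @param latent_base Participant's latent base mean (lognormal draw plus
#'   offsets), steps/day.
#' @param engagement_factor Logistic-transformed engagement propensity in
#'   \[0, 1\].
#' @param day Diary day (1-based).
#' @param params A [population_params()].
#' @param baseline_days Run-in length in days.
#' @return Expected steps (not rounded, not floored).
#' @export
expected_daily_steps <- function(latent_base, engagement_factor, day, params,
                                 baseline_days = 14L) {
  week <- study_week_of_day(day, baseline_days)
  response <- ifelse(
    week == 0L, 0,
    pmax(0, params$response_effect * engagement_factor -
              params$decay_rate * pmax(0, week - params$decay_onset_week)))
  latent_base + response
}

#' Generate a synthetic population of step diaries
#'
#' Draws covariates, a latent daily step mean per participant, and a full
#' daily diary over the reference timeline. Deterministic for a fixed seed.
#' The latent engagement propensity is returned in the separate `latent`
#' table, which is never written to the analysis-stage files.
#'
#' @param params A [population_params()].
#' @param timeline A [program_timeline()]; defines the diary length.
#' @return A `step_population`: list of tibbles `diaries` (participant_id,
#'   day, steps), `covariates` (participant_id, age, gender, province,
#'   income), and `latent` (participant_id, engagement_propensity,
#'   latent_base).
#' @export
generate_population <- function(params = population_params(),
                                timeline = program_timeline()) {
  validate_population_params(params)
  set.seed(params$seed)
  n <- params$n_participants
  t_days <- timeline$total_days
  baseline_days <- length(timeline$run_in_days)

  ids <- sprintf("P%05d", seq_len(n))
  gender <- ifelse(stats::runif(n) < params$prop_female, "female", "male")
  province <- ifelse(stats::runif(n) < params$prop_bc, "BC", "NL")
  age <- round(pmax(13, stats::rnorm(n, params$age_mean, params$age_sd)), 1)
  income <- round(pmax(0, stats::rnorm(n, params$income_mean, params$income_sd)), 1)
  propensity <- stats::rnorm(n, params$engagement_propensity_mean,
                             params$engagement_propensity_sd)
  eng_factor <- stats::plogis(propensity)

  latent_base <- exp(stats::rnorm(n, params$log_steps_mu, params$log_steps_sigma)) +
    gender_offset(gender, params) + province_offset(province, params)

  day <- rep(seq_len(t_days), times = n)
  idx <- rep(seq_len(n), each = t_days)
  mu <- expected_daily_steps(latent_base[idx], eng_factor[idx], day, params,
                             baseline_days)
  steps <- round(mu + stats::rnorm(n * t_days, 0, params$noise_sd))
  steps <- pmax(0L, as.integer(steps))
  nonwear <- stats::runif(n * t_days) < params$nonwear_prob
  steps[nonwear] <- as.integer(floor(stats::runif(sum(nonwear), 0, 1000)))

  pop <- list(
    diaries = tibble::tibble(participant_id = ids[idx], day = day,
                             steps = steps),
    covariates = tibble::tibble(participant_id = ids, age = age,
                                gender = gender, province = province,
                                income = income),
    latent = tibble::tibble(participant_id = ids,
                            engagement_propensity = propensity,
                            latent_base = latent_base)
  )
  class(pop) <- "step_population"
  pop
}

#' Write / read a population's analysis-stage files
#'
#' `write_diaries()` writes two UTF-8 CSVs with header rows: `steps.csv`
#' (participant_id, day, steps; day 1-based and contiguous) and
#' `covariates.csv` (participant_id, age, gender, province, income). The
#' latent table is deliberately not written: the engagement propensity is a
#' generator-only construct hidden from all analysis stages.
#' `read_diaries()` reads the pair back and validates the schema; the
#' round-trip is an identity on diaries and covariates.
#'
#' @param pop A `step_population`.
#' @param path Directory for the file pair (created if needed).
#' @return `write_diaries()` returns the paths invisibly; `read_diaries()`
#'   returns a `step_population` with `latent = NULL`.
#' @export
write_diaries <- function(pop, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  steps_path <- file.path(path, "steps.csv")
  cov_path <- file.path(path, "covariates.csv")
  readr::write_csv(pop$diaries, steps_path)
  readr::write_csv(pop$covariates, cov_path)
  invisible(c(steps = steps_path, covariates = cov_path))
}

#' @rdname write_diaries
#' @export
read_diaries <- function(path) {
  steps_path <- file.path(path, "steps.csv")
  cov_path <- file.path(path, "covariates.csv")
  diaries <- readr::read_csv(steps_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               participant_id = readr::col_character(),
                               day = readr::col_integer(),
                               steps = readr::col_integer()))
  covariates <- readr::read_csv(cov_path, show_col_types = FALSE,
                                col_types = readr::cols(
                                  participant_id = readr::col_character(),
                                  age = readr::col_double(),
                                  gender = readr::col_character(),
                                  province = readr::col_character(),
                                  income = readr::col_double()))
  validate_diaries(diaries)
  pop <- list(diaries = diaries, covariates = covariates, latent = NULL)
  class(pop) <- "step_population"
  pop
}

validate_diaries <- function(diaries) {
  bad <- which(diaries$steps < 0)
  if (length(bad)) {
    stop("negative step count in diary row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(diaries[, c("participant_id", "day")]))
  if (length(dup)) {
    stop("duplicate participant-day in diary row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  gaps <- diaries |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ok = all(sort(.data$day) == seq_along(.data$day)),
                     .groups = "drop")
  if (!all(gaps$ok)) {
    stop("diary days must be 1-based and contiguous for participant(s): ",
         paste(utils::head(gaps$participant_id[!gaps$ok], 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(diaries)
}
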