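#' Program configuration
#'
#' All intervention constants for the walking program: the validity range used
#' to screen step counts, the baseline/goal arithmetic, the step-up challenge
#' rules, and the loyalty-point reward schedule (denominated in Canadian
#' dollars).
#'
#' The default configuration satisfies the program's published reward cap:
#' activation ($0.60) + 70 daily rewards ($0.04 each = $2.80) + 4 challenge
#' bonuses ($0.40 each = $1.60) = $5.00.
#'
#' @param baseline_days Length of the run-in period used to compute the
#'   personalized baseline, in days.
#' @param valid_min,valid_max Inclusive bounds (steps) outside which a day is
#'   discarded: below `valid_min` the phone is assumed not worn, above
#'   `valid_max` the count is treated as a device artifact.
#' @param min_valid_days Minimum number of valid run-in days required for a
#'   personalized baseline; participants below it get `fallback_goal` and are
#'   excluded from analysis.
#' @param initial_increment Steps added to the baseline mean to form the first
#'   daily goal.
#' @param goal_rounding Rounding grain for the first goal (nearest multiple,
#'   half-up).
#' @param fallback_goal Generic daily goal for participants without a valid
#'   baseline.
#' @param challenge_window Length of one step-up challenge, in days.
#' @param challenge_required Number of goal-met days (possibly nonconsecutive)
#'   required to win a challenge.
#' @param challenge_increment Steps added to the daily goal after a successful
#'   challenge.
#' @param n_challenges Number of challenge windows in the program.
#' @param daily_reward,challenge_reward,activation_reward Reward amounts, Can$.
#' @param daily_reward_days Number of days on which the daily reward can be
#'   earned.
#' @return A `program_config` object (named list).
#' @export
program_config <- function(baseline_days = 14L,
                           valid_min = 1000L,
                           valid_max = 40000L,
                           min_valid_days = 5L,
                           initial_increment = 1000L,
                           goal_rounding = 100L,
                           fallback_goal = 5000L,
                           challenge_window = 14L,
                           challenge_required = 10L,
                           challenge_increment = 500L,
                           n_challenges = 4L,
                           daily_reward = 0.04,
                           challenge_reward = 0.40,
                           activation_reward = 0.60,
                           daily_reward_days = 70L) {
  cfg <- list(
    baseline_days = as.integer(baseline_days),
    valid_min = as.integer(valid_min),
    valid_max = as.integer(valid_max),
    min_valid_days = as.integer(min_valid_days),
    initial_increment = as.integer(initial_increment),
    goal_rounding = as.integer(goal_rounding),
    fallback_goal = as.integer(fallback_goal),
    challenge_window = as.integer(challenge_window),
    challenge_required = as.integer(challenge_required),
    challenge_increment = as.integer(challenge_increment),
    n_challenges = as.integer(n_challenges),
    daily_reward = as.numeric(daily_reward),
    challenge_reward = as.numeric(challenge_reward),
    activation_reward = as.numeric(activation_reward),
    daily_reward_days = as.integer(daily_reward_days)
  )
  class(cfg) <- "program_config"
  validate_program_config(cfg)
  cfg
}

validate_program_config <- function(cfg) {
  stopifnot(inherits(cfg, "program_config"))
  if (cfg$challenge_required > cfg$challenge_window) {
    stop("`challenge_required` must not exceed `challenge_window`", call. = FALSE)
  }
  if (cfg$valid_min >= cfg$valid_max) {
    stop("`valid_min` must be below `valid_max`", call. = FALSE)
  }
  rewards <- c(cfg$daily_reward, cfg$challenge_reward, cfg$activation_reward)
  if (any(rewards < 0)) stop("reward amounts must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' Total reward cap implied by a configuration
#'
#' Activation bonus plus every earnable daily reward plus every challenge
#' bonus; $5.00 under the default configuration.
#'
#' @param cfg A [program_config()].
#' @return Can$ amount.
#' @export
program_cap <- function(cfg = program_config()) {
  cfg$activation_reward +
    cfg$daily_reward * cfg$daily_reward_days +
    cfg$challenge_reward * cfg$n_challenges
}

#' Reference program timeline
#'
#' Days are 1-based and contiguous; no calendar logic. The timeline is:
#' a 14-day run-in (baseline) period; a 14-day phase with daily rewards only;
#' then four consecutive 14-day step-up challenge windows. Daily rewards are
#' earnable on exactly `daily_reward_days` (70) days: the daily-only phase plus
#' the challenge phases. The evaluation horizon extends two further weeks
#' (study weeks 11-12) during which goals remain in force but no rewards
#' accrue, so the full diary spans `total_days` (98) days covering study weeks
#' 0 through 12.
#'
#' @param cfg A [program_config()].
#' @param n_study_weeks Number of post-run-in study weeks in the evaluation
#'   horizon (default 12).
#' @return A `program_timeline` object with elements `run_in_days`,
#'   `daily_only_days`, `challenge_windows` (list of day vectors),
#'   `reward_days`, `goal_days`, and `total_days`.
#' @export
program_timeline <- function(cfg = program_config(), n_study_weeks = 12L) {
  run_in <- seq_len(cfg$baseline_days)
  daily_only <- cfg$baseline_days + seq_len(cfg$challenge_window)
  ch_start <- cfg$baseline_days + cfg$challenge_window
  windows <- lapply(seq_len(cfg$n_challenges), function(k) {
    ch_start + (k - 1L) * cfg$challenge_window + seq_len(cfg$challenge_window)
  })
  reward_days <- c(daily_only, unlist(windows))
  if (length(reward_days) != cfg$daily_reward_days) {
    stop("timeline inconsistent: reward-eligible days != `daily_reward_days`",
         call. = FALSE)
  }
  total <- cfg$baseline_days + 7L * as.integer(n_study_weeks)
  tl <- list(
    run_in_days = run_in,
    daily_only_days = daily_only,
    challenge_windows = windows,
    reward_days = reward_days,
    goal_days = (cfg$baseline_days + 1L):total,
    n_study_weeks = as.integer(n_study_weeks),
    total_days = total
  )
  class(tl) <- "program_timeline"
  tl
}

#' Is a day's step count valid?
#'
#' A valid day records between `valid_min` and `valid_max` steps, both bounds
#' inclusive. Counts below the floor are treated as non-wear days; counts
#' above the ceiling as artifacts.
#'
#' @param steps Non-negative step count(s); vectorized.
#' @param cfg A [program_config()].
#' @return Logical vector.
#' @export
is_valid_day <- function(steps, cfg = program_config()) {
  stopifnot(all(steps >= 0))
  steps >= cfg$valid_min & steps <= cfg$valid_max
}

#' Baseline mean from the run-in period
#'
#' Averages the valid days among the first `baseline_days` days. Participants
#' with fewer than `min_valid_days` valid days get no personalized baseline:
#' they receive the generic `fallback_goal` and are flagged excluded from
#' analysis.
#'
#' @param steps Integer vector of daily step counts covering at least the
#'   run-in period (day 1 onward).
#' @param cfg A [program_config()].
#' @return List with `baseline_mean` (NA if excluded), `excluded` flag and
#'   `n_valid_days`.
#' @export
compute_baseline <- function(steps, cfg = program_config()) {
  if (length(steps) < cfg$baseline_days) {
    stop("diary covers fewer days than the baseline period", call. = FALSE)
  }
  run_in <- steps[seq_len(cfg$baseline_days)]
  valid <- is_valid_day(run_in, cfg)
  n_valid <- sum(valid)
  if (n_valid >= cfg$min_valid_days) {
    list(baseline_mean = mean(run_in[valid]), excluded = FALSE,
         n_valid_days = n_valid)
  } else {
    list(baseline_mean = NA_real_, excluded = TRUE, n_valid_days = n_valid)
  }
}

# Half-up rounding to the nearest multiple of `grain` (2350 -> 2400 at grain
# 100), unlike round()'s banker's rounding.
round_half_up <- function(x, grain) {
  grain * floor(x / grain + 0.5)
}

#' First personalized daily step goal
#'
#' Baseline mean plus `initial_increment`, rounded to the nearest
#' `goal_rounding` steps; exact half-way values round up.
#'
#' @param baseline_mean Personalized baseline, steps/day.
#' @param cfg A [program_config()].
#' @return Goal in steps.
#' @export
initial_goal <- function(baseline_mean, cfg = program_config()) {
  stopifnot(is.finite(baseline_mean))
  round_half_up(baseline_mean + cfg$initial_increment, cfg$goal_rounding)
}

#' Evaluate one step-up challenge window
#'
#' A challenge succeeds when the daily goal was met on at least
#' `challenge_required` days of the window; the days need not be consecutive.
#'
#' @param goal_met Logical vector of length `challenge_window`.
#' @param cfg A [program_config()].
#' @return TRUE if the challenge succeeded.
#' @export
evaluate_challenge <- function(goal_met, cfg = program_config()) {
  if (length(goal_met) != cfg$challenge_window) {
    stop("`goal_met` must have length `challenge_window` (",
         cfg$challenge_window, ")", call. = FALSE)
  }
  sum(goal_met) >= cfg$challenge_required
}

#' Challenge acceptance policies
#'
#' The first challenge is always auto-enrolled by the program; a policy
#' decides the remaining windows. `accept_all_policy` accepts every window,
#' `accept_none_policy` declines every optional window, and
#' `probabilistic_policy(p)` accepts each optional window independently with
#' probability `p` (used by the synthetic generator to tie acceptance to a
#' participant's engagement propensity).
#'
#' @param p Acceptance probability in \[0, 1\].
#' @return A function `(window_index) -> logical`.
#' @export
accept_all_policy <- function() function(window_index) TRUE

#' @rdname accept_all_policy
#' @export
accept_none_policy <- function() function(window_index) FALSE

#' @rdname accept_all_policy
#' @export
probabilistic_policy <- function(p) {
  stopifnot(p >= 0, p <= 1)
  function(window_index) stats::runif(1) < p
}

#' Run the walking program for one participant
#'
#' Executes the day-by-day program over the reference timeline: computes the
#' baseline and first goal (or the generic fallback for participants without
#' enough valid run-in days), credits the activation bonus, credits the daily
#' reward on every reward-eligible day on which steps reach the current goal,
#' evaluates each accepted challenge window when it closes, and on success
#' credits the challenge bonus and raises the goal by `challenge_increment`
#' effective the next day. Declined windows record no challenge progress but
#' daily rewards continue. The goal never decreases, and after `n_challenges`
#' successes it freezes.
#'
#' @param steps Integer vector of daily steps covering `timeline$total_days`.
#' @param cfg A [program_config()].
#' @param timeline A [program_timeline()].
#' @param acceptance_policy Function `(window_index) -> logical` deciding
#'   whether each challenge window beyond the auto-enrolled first is accepted.
#' @param participant_id Optional identifier carried into the ledger.
#' @return A `participant_ledger`: list with `participant_id`,
#'   `baseline_mean`, `excluded`, `initial_goal`, `final_goal`, `goal_by_day`
#'   (steps, for days after run-in), `reward_events` (tibble: day, kind,
#'   amount), `challenges` (tibble: window, accepted, met_days, success), and
#'   `total_earned`.
#' @export
run_program <- function(steps, cfg = program_config(),
                        timeline = program_timeline(cfg),
                        acceptance_policy = accept_all_policy(),
                        participant_id = NA_character_) {
  if (length(steps) < timeline$total_days) {
    stop("diary length (", length(steps), ") shorter than the timeline (",
         timeline$total_days, " days)", call. = FALSE)
  }
  bl <- compute_baseline(steps, cfg)
  goal0 <- if (bl$excluded) cfg$fallback_goal else initial_goal(bl$baseline_mean, cfg)

  goal_days <- timeline$goal_days
  goal_by_day <- rep(NA_real_, timeline$total_days)
  ev_day <- integer(0); ev_kind <- character(0); ev_amount <- numeric(0)

  # activation bonus at enrolment (recorded as day 0)
  ev_day <- c(ev_day, 0L); ev_kind <- c(ev_kind, "activation")
  ev_amount <- c(ev_amount, cfg$activation_reward)

  window_of_day <- rep(NA_integer_, timeline$total_days)
  for (k in seq_along(timeline$challenge_windows)) {
    window_of_day[timeline$challenge_windows[[k]]] <- k
  }
  reward_day <- logical(timeline$total_days)
  reward_day[timeline$reward_days] <- TRUE

  accepted <- logical(cfg$n_challenges)
  met_days <- integer(cfg$n_challenges)
  success <- logical(cfg$n_challenges)
  n_success <- 0L

  goal <- goal0
  goal_met <- logical(timeline$total_days)
  for (d in goal_days) {
    goal_by_day[d] <- goal
    goal_met[d] <- steps[d] >= goal
    if (reward_day[d] && goal_met[d]) {
      ev_day <- c(ev_day, d); ev_kind <- c(ev_kind, "daily")
      ev_amount <- c(ev_amount, cfg$daily_reward)
    }
    k <- window_of_day[d]
    if (!is.na(k) && d == max(timeline$challenge_windows[[k]])) {
      # window closes today; first window is auto-enrolled
      accepted[k] <- if (k == 1L) TRUE else isTRUE(acceptance_policy(k))
      if (accepted[k]) {
        window_met <- goal_met[timeline$challenge_windows[[k]]]
        met_days[k] <- sum(window_met)
        success[k] <- evaluate_challenge(window_met, cfg) &&
          n_success < cfg$n_challenges
        if (success[k]) {
          n_success <- n_success + 1L
          ev_day <- c(ev_day, d); ev_kind <- c(ev_kind, "challenge")
          ev_amount <- c(ev_amount, cfg$challenge_reward)
          goal <- goal + cfg$challenge_increment  # effective next day
        }
      }
    }
  }

  ledger <- list(
    participant_id = participant_id,
    baseline_mean = bl$baseline_mean,
    excluded = bl$excluded,
    initial_goal = goal0,
    final_goal = goal,
    goal_by_day = goal_by_day,
    goal_met = goal_met,
    reward_events = tibble::tibble(day = ev_day, kind = ev_kind,
                                   amount = ev_amount),
    challenges = tibble::tibble(window = seq_len(cfg$n_challenges),
                                accepted = accepted, met_days = met_days,
                                success = success),
    total_earned = sum(ev_amount)
  )
  class(ledger) <- "participant_ledger"
  validate_ledger(ledger, cfg)
  ledger
}

validate_ledger <- function(ledger, cfg) {
  goals <- ledger$goal_by_day[!is.na(ledger$goal_by_day)]
  if (length(goals) > 1 && any(diff(goals) < 0)) {
    stop("ledger invariant violated: goal decreased", call. = FALSE)
  }
  if (abs(ledger$total_earned - sum(ledger$reward_events$amount)) > 1e-9) {
    stop("ledger invariant violated: total_earned != sum of events", call. = FALSE)
  }
  if (ledger$total_earned > program_cap(cfg) + 1e-9) {
    stop("ledger invariant violated: earnings exceed program cap", call. = FALSE)
  }
  n_succ <- sum(ledger$challenges$success)
  if (ledger$final_goal - ledger$initial_goal !=
      cfg$challenge_increment * n_succ) {
    stop("ledger invariant violated: goal increase != increment * successes",
         call. = FALSE)
  }
  invisible(ledger)
}

#' Run the program for every participant in a population
#'
#' @param pop A `step_population` (see [generate_population()]).
#' @param cfg A [program_config()].
#' @param timeline A [program_timeline()].
#' @param acceptance One of: `"all"` (accept every challenge), `"none"`
#'   (decline every optional window), or `"engagement"` (each participant
#'   accepts optional windows with probability equal to their latent
#'   engagement factor; requires the population's latent table).
#' @param seed Optional seed controlling probabilistic acceptance draws.
#' @return Named list of `participant_ledger` objects.
#' @export
run_program_population <- function(pop, cfg = program_config(),
                                   timeline = program_timeline(cfg),
                                   acceptance = c("engagement", "all", "none"),
                                   seed = NULL) {
  acceptance <- match.arg(acceptance)
  ids <- pop$covariates$participant_id
  wide <- tidyr::pivot_wider(pop$diaries, id_cols = "participant_id",
                             names_from = "day", values_from = "steps")
  wide <- wide[match(ids, wide$participant_id), , drop = FALSE]
  step_mat <- as.matrix(wide[, -1, drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  if (acceptance == "engagement" && is.null(pop$latent)) {
    stop("acceptance = \"engagement\" needs the generator's latent table",
         call. = FALSE)
  }
  ledgers <- vector("list", length(ids))
  names(ledgers) <- ids
  for (i in seq_along(ids)) {
    policy <- switch(acceptance,
      all = accept_all_policy(),
      none = accept_none_policy(),
      engagement = probabilistic_policy(
        stats::plogis(pop$latent$engagement_propensity[i])))
    ledgers[[i]] <- run_program(step_mat[i, ], cfg, timeline, policy,
                                participant_id = ids[i])
  }
  ledgers
}

#' Export ledgers as a long event table
#'
#' One row per participant-day over the goal-active period, with the goal in
#' force, whether it was met, and any reward event that day (activation rows
#' appear as day 0).
#'
#' @param ledgers List of `participant_ledger` objects.
#' @return Tibble with columns participant_id, day, event_kind, amount,
#'   goal_at_day, goal_met.
#' @export
ledger_events <- function(ledgers) {
  purrr::map_dfr(ledgers, function(lg) {
    ev <- lg$reward_events
    days <- which(!is.na(lg$goal_by_day))
    base <- tibble::tibble(
      participant_id = lg$participant_id,
      day = c(0L, days),
      goal_at_day = c(NA_real_, lg$goal_by_day[days]),
      goal_met = c(NA, lg$goal_met[days])
    )
    agg <- dplyr::summarise(dplyr::group_by(ev, .data$day),
                            event_kind = paste(.data$kind, collapse = "+"),
                            amount = sum(.data$amount), .groups = "drop")
    dplyr::left_join(base, agg, by = "day")
  })
}
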