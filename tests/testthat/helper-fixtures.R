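# Shared fixture builders. Everything is constructed in code; no stored data.

default_cfg <- program_config()
default_tl <- program_timeline(default_cfg)

# A diary with a constant run-in (personalized baseline = `baseline`) followed
# by constant intervention-period steps.
constant_diary <- function(baseline = 5000L, intervention = 10000L,
                           tl = default_tl) {
  as.integer(c(rep(baseline, length(tl$run_in_days)),
               rep(intervention, tl$total_days - length(tl$run_in_days))))
}

# Known-truth simulation conditions: a cohort whose realized week-12 effect on
# the weekly valid-day mean equals `effect` exactly. The latent step level is
# kept well inside the [1000, 40000] validity window (log-mean 8.7, log-sd 0.3,
# noise 500) so the valid-day filter cannot truncate the noise distribution and
# shrink the realized effect; the engagement factor is pinned at 1 and decay is
# off, so every participant adds exactly `effect` steps on intervention days;
# non-wear missingness stays on (30%/day) and is missing completely at random.
known_truth_params <- function(seed, n = 2000L, effect = 500) {
  population_params(
    n_participants = n, seed = seed,
    log_steps_mu = 8.7, log_steps_sigma = 0.3,
    gender_gap = 0, province_gap = 0,
    nonwear_prob = 0.3,
    response_effect = effect,
    engagement_propensity_mean = 20, engagement_propensity_sd = 0,
    decay_rate = 0, noise_sd = 500)
}

# Minimal analytic-sample tibble for direct model tests.
make_sample <- function(participant_id, study_week, mean_steps,
                        age = 30, gender = "female", province = "BC",
                        income = 30, engagement = NA_character_,
                        activity_status = "inactive") {
  tibble::tibble(
    participant_id = participant_id, study_week = study_week,
    mean_steps = mean_steps, approach = "any", imputed_flag = FALSE,
    activity_status = activity_status, engagement = engagement,
    age = age, gender = gender, province = province, income = income)
}

# Fast week-only mixed-model estimate of the week-12 effect and its Wald SE,
# used in replicate loops.
week12_estimate <- function(sample) {
  dat <- sample
  dat$study_week <- stats::relevel(factor(dat$study_week), ref = "0")
  fit <- lme4::lmer(mean_steps ~ study_week + (1 | participant_id),
                    data = dat, REML = TRUE)
  est <- unname(lme4::fixef(fit)["study_week12"])
  se <- unname(sqrt(diag(as.matrix(stats::vcov(fit)))["study_week12"]))
  c(est = est, se = se)
}
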