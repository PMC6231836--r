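#' Fit the weekly random-intercept mixed model
#'
#' Fits `mean_steps ~ study_week + age + gender + income + province +
#' (1 | participant_id)` by REML, with study week categorical and baseline
#' (week 0) as the reference level. Least-square means per week are evaluated
#' with continuous covariates at their sample means and categorical
#' covariates balanced over levels; intervals and p-values are Wald z
#' (asymptotic). The week-12 effect is the LS-mean contrast week 12 minus
#' baseline. Covariates constant within the fitted rows (e.g. province inside
#' a provincial stratum) are dropped automatically.
#'
#' With `moderation = TRUE` the model adds an engagement main effect and a
#' study week x engagement interaction; the headline estimand becomes the
#' difference-in-differences contrast (high vs low engagers, week 12 minus
#' baseline) and the local effect size is computed for the interaction term.
#'
#' @param sample Analytic sample from [build_sample()].
#' @param covariates Use the adjustment covariates (age, gender, income,
#'   province)? The unadjusted model keeps only study week.
#' @param moderation Add engagement main effect + week x engagement
#'   interaction (requires engagement labels in `sample`).
#' @param compute_f2 Compute the local Cohen f-squared for the focal term
#'   (refits a reduced model; skip for speed in replicate loops).
#' @return A `weekly_model_result`: list with `lsmeans` (tibble: study_week,
#'   estimate, se, ci_lo, ci_hi), `diff` (week-12 minus baseline: estimate,
#'   se, ci_lo, ci_hi, p_value), `cohen_f2`, `n_participants`, `n_rows`,
#'   `converged`, `moderation`, and for moderation fits `lsmeans` by
#'   engagement level plus `diff` as the interaction contrast.
#' @export
fit_weekly_model <- function(sample, covariates = TRUE, moderation = FALSE,
                             compute_f2 = TRUE) {
  if (nrow(sample) == 0) stop("empty analytic sample", call. = FALSE)
  dat <- dplyr::mutate(
    sample,
    study_week = factor(.data$study_week,
                        levels = sort(unique(sample$study_week))),
    participant_id = factor(.data$participant_id)
  )
  if (!"0" %in% levels(dat$study_week)) {
    stop("every analytic sample must include baseline (week 0) rows",
         call. = FALSE)
  }
  dat$study_week <- stats::relevel(dat$study_week, ref = "0")

  covs <- character(0)
  if (covariates) {
    for (v in c("age", "gender", "income", "province")) {
      if (length(unique(dat[[v]])) > 1) covs <- c(covs, v)
    }
  }
  terms <- c("study_week", covs)
  if (moderation) {
    if (all(is.na(dat$engagement))) {
      stop("moderation fit requires engagement labels", call. = FALSE)
    }
    dat$engagement <- factor(dat$engagement, levels = c("low", "high"))
    terms <- c(terms, "engagement", "study_week:engagement")
  }
  fml <- stats::as.formula(
    paste("mean_steps ~", paste(terms, collapse = " + "),
          "+ (1 | participant_id)"))

  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = dat, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !lme4::isSingular(fit) &&
    !any(grepl("converge", msgs, ignore.case = TRUE))

  res <- list(
    lsmeans = NULL, diff = NULL, cohen_f2 = NA_real_,
    n_participants = dplyr::n_distinct(dat$participant_id),
    n_rows = nrow(dat), converged = converged, moderation = moderation,
    fit = fit
  )
  class(res) <- "weekly_model_result"
  if (!converged) return(res)

  if (!moderation) {
    emm <- emmeans::emmeans(fit, ~study_week, lmer.df = "asymptotic")
    res$lsmeans <- tidy_emm(emm, "study_week")
    k <- nlevels(dat$study_week)
    cvec <- stats::setNames(rep(0, k), levels(dat$study_week))
    cvec["0"] <- -1
    cvec[as.character(max(as.integer(levels(dat$study_week))))] <- 1
    res$diff <- tidy_contrast(
      emmeans::contrast(emm, method = list(week12_vs_baseline = unname(cvec)),
                        infer = c(TRUE, TRUE)))
  } else {
    emm <- emmeans::emmeans(fit, ~ study_week * engagement,
                            lmer.df = "asymptotic")
    res$lsmeans <- tidy_emm(emm, c("study_week", "engagement"))
    grid <- as.data.frame(emm)[, c("study_week", "engagement")]
    last <- as.character(max(as.integer(as.character(grid$study_week))))
    cvec <- numeric(nrow(grid))
    cvec[grid$study_week == last & grid$engagement == "high"] <- 1
    cvec[grid$study_week == "0" & grid$engagement == "high"] <- -1
    cvec[grid$study_week == last & grid$engagement == "low"] <- -1
    cvec[grid$study_week == "0" & grid$engagement == "low"] <- 1
    res$diff <- tidy_contrast(
      emmeans::contrast(emm, method = list(did_high_vs_low = cvec),
                        infer = c(TRUE, TRUE)))
  }

  if (compute_f2) {
    reduced_terms <- if (moderation) setdiff(terms, "study_week:engagement")
                     else setdiff(terms, "study_week")
    rhs <- if (length(reduced_terms)) paste(reduced_terms, collapse = " + ")
           else "1"
    fml_r <- stats::as.formula(
      paste("mean_steps ~", rhs, "+ (1 | participant_id)"))
    fit_r <- suppressWarnings(lme4::lmer(fml_r, data = dat, REML = TRUE))
    res$cohen_f2 <- cohen_f2_local(fit, fit_r)
  }
  res
}

tidy_emm <- function(emm, keys) {
  df <- as.data.frame(emm)
  out <- tibble::as_tibble(df[, keys, drop = FALSE])
  if ("study_week" %in% keys) {
    out$study_week <- as.integer(as.character(out$study_week))
  }
  out$estimate <- df$emmean
  out$se <- df$SE
  out$ci_lo <- df$asymp.LCL %||% df$lower.CL
  out$ci_hi <- df$asymp.UCL %||% df$upper.CL
  out
}

tidy_contrast <- function(ctr) {
  df <- as.data.frame(ctr)
  list(estimate = df$estimate[1], se = df$SE[1],
       ci_lo = (df$asymp.LCL %||% df$lower.CL)[1],
       ci_hi = (df$asymp.UCL %||% df$upper.CL)[1],
       p_value = df$p.value[1])
}

#' Marginal (fixed-effects) R-squared of a mixed model
#'
#' Variance of the fixed-effects linear predictor over the total outcome
#' variance decomposition (fixed + random-intercept + residual). This is the
#' fixed-effects R-squared analog used to form local effect sizes.
#'
#' @param fit A fitted `lmerMod`.
#' @return R-squared in \[0, 1\].
#' @export
marginal_r2 <- function(fit) {
  var_fix <- stats::var(as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ran <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- stats::sigma(fit)^2
  var_fix / (var_fix + var_ran + var_res)
}

#' Local Cohen f-squared for a model term
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)` on the marginal
#' (fixed-effects) R-squared, where the reduced model drops the focal term and
#' is fitted on the identical rows. Values that are negative from numerical
#' noise are clipped to zero. Interpretation bands: 0.02 small, 0.15 medium,
#' 0.35 large (see [effect_size_label()]).
#'
#' @param full_model,reduced_model Fitted `lmerMod` objects on the same rows.
#' @return Non-negative effect size.
#' @export
cohen_f2_local <- function(full_model, reduced_model) {
  if (stats::nobs(full_model) != stats::nobs(reduced_model)) {
    stop("full and reduced models must be fitted on identical rows",
         call. = FALSE)
  }
  r2_f <- marginal_r2(full_model)
  r2_r <- marginal_r2(reduced_model)
  max(0, (r2_f - r2_r) / (1 - r2_f))
}

#' Effect-size interpretation band for Cohen f-squared
#'
#' @param f2 Non-negative effect size(s).
#' @return `"large"` (>= 0.35), `"medium"` (>= 0.15), `"small"` (>= 0.02), or
#'   `"below small"`.
#' @export
effect_size_label <- function(f2) {
  stopifnot(all(f2 >= 0))
  dplyr::case_when(
    f2 >= 0.35 ~ "large",
    f2 >= 0.15 ~ "medium",
    f2 >= 0.02 ~ "small",
    TRUE ~ "below small"
  )
}

subgroup_filters <- function() {
  list(
    total = function(d) d,
    inactive = function(d) dplyr::filter(d, .data$activity_status == "inactive"),
    active = function(d) dplyr::filter(d, .data$activity_status == "active"),
    BC = function(d) dplyr::filter(d, .data$province == "BC"),
    NL = function(d) dplyr::filter(d, .data$province == "NL"),
    low_engager = function(d) dplyr::filter(d, .data$engagement == "low"),
    high_engager = function(d) dplyr::filter(d, .data$engagement == "high"),
    inactive_low = function(d) dplyr::filter(d, .data$activity_status == "inactive",
                                             .data$engagement == "low"),
    inactive_high = function(d) dplyr::filter(d, .data$activity_status == "inactive",
                                              .data$engagement == "high"),
    active_low = function(d) dplyr::filter(d, .data$activity_status == "active",
                                           .data$engagement == "low"),
    active_high = function(d) dplyr::filter(d, .data$activity_status == "active",
                                            .data$engagement == "high"),
    BC_low = function(d) dplyr::filter(d, .data$province == "BC",
                                       .data$engagement == "low"),
    BC_high = function(d) dplyr::filter(d, .data$province == "BC",
                                        .data$engagement == "high"),
    NL_low = function(d) dplyr::filter(d, .data$province == "NL",
                                       .data$engagement == "low"),
    NL_high = function(d) dplyr::filter(d, .data$province == "NL",
                                        .data$engagement == "high")
  )
}

#' Stratified weekly-model suite
#'
#' Fits the adjusted weekly model on the total sample and within each
#' stratum: physical-activity status, province, engagement level, and the
#' crossed activity x engagement and province x engagement strata. Strata
#' needing engagement labels are skipped (with a warning) when labels are
#' absent. An empty stratum yields a row with `n = 0` and no estimates.
#'
#' @param sample Analytic sample from [build_sample()].
#' @param strata Character vector of stratum names to run; default all.
#' @param compute_f2 Compute local effect sizes per stratum.
#' @return List with `table` (one row per stratum: stratum, n, baseline and
#'   week-12 LS-means with CIs, difference with CI and p, cohen_f2,
#'   converged) and `fits` (named list of `weekly_model_result`).
#' @export
run_subgroup_suite <- function(sample, strata = NULL, compute_f2 = TRUE) {
  filters <- subgroup_filters()
  if (is.null(strata)) strata <- names(filters)
  stopifnot(all(strata %in% names(filters)))
  has_eng <- !all(is.na(sample$engagement))
  rows <- list(); fits <- list()
  for (s in strata) {
    if (!has_eng && grepl("engager|_low|_high", s)) {
      warning("stratum `", s, "` skipped: no engagement labels", call. = FALSE)
      next
    }
    d <- filters[[s]](sample)
    if (nrow(d) == 0) {
      rows[[s]] <- tibble::tibble(
        stratum = s, n = 0L, baseline_lsmean = NA_real_,
        baseline_ci_lo = NA_real_, baseline_ci_hi = NA_real_,
        week12_lsmean = NA_real_, week12_ci_lo = NA_real_,
        week12_ci_hi = NA_real_, diff = NA_real_, diff_ci_lo = NA_real_,
        diff_ci_hi = NA_real_, p_value = NA_real_, cohen_f2 = NA_real_,
        converged = NA)
      next
    }
    res <- fit_weekly_model(d, covariates = TRUE, compute_f2 = compute_f2)
    fits[[s]] <- res
    rows[[s]] <- summarize_result_row(res, s)
  }
  list(table = dplyr::bind_rows(rows), fits = fits)
}

summarize_result_row <- function(res, stratum) {
  if (!res$converged) {
    return(tibble::tibble(
      stratum = stratum, n = res$n_participants, baseline_lsmean = NA_real_,
      baseline_ci_lo = NA_real_, baseline_ci_hi = NA_real_,
      week12_lsmean = NA_real_, week12_ci_lo = NA_real_,
      week12_ci_hi = NA_real_, diff = NA_real_, diff_ci_lo = NA_real_,
      diff_ci_hi = NA_real_, p_value = NA_real_, cohen_f2 = NA_real_,
      converged = FALSE))
  }
  ls <- res$lsmeans
  b <- ls[ls$study_week == 0L, ]
  w <- ls[ls$study_week == max(ls$study_week), ]
  tibble::tibble(
    stratum = stratum, n = res$n_participants,
    baseline_lsmean = b$estimate[1], baseline_ci_lo = b$ci_lo[1],
    baseline_ci_hi = b$ci_hi[1],
    week12_lsmean = w$estimate[1], week12_ci_lo = w$ci_lo[1],
    week12_ci_hi = w$ci_hi[1],
    diff = res$diff$estimate, diff_ci_lo = res$diff$ci_lo,
    diff_ci_hi = res$diff$ci_hi, p_value = res$diff$p_value,
    cohen_f2 = res$cohen_f2, converged = TRUE)
}

#' Percent difference of the intervention period over baseline
#'
#' `(mean of the week-1..12 LS-means - baseline LS-mean) / baseline LS-mean`,
#' in percent.
#'
#' @param result A converged `weekly_model_result` (non-moderation).
#' @return Percent difference.
#' @export
percent_difference <- function(result) {
  if (!isTRUE(result$converged)) stop("model did not converge", call. = FALSE)
  ls <- result$lsmeans
  base <- ls$estimate[ls$study_week == 0L]
  intervention <- mean(ls$estimate[ls$study_week > 0L])
  100 * (intervention - base) / base
}
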