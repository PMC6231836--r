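#' Published participant-flow counts
#'
#' The participant accounting reported for the program evaluation: eligible
#' app users, walking-program activations, participants with a valid
#' baseline, and the analytic-sample and subgroup numerators. Two slightly
#' different activation denominators were printed (35,014 in the
#' participant-flow text, 35,019 in the analytic-approach text); both are
#' kept and used exactly where the corresponding published proportion uses
#' them.
#'
#' @return Named list of integer counts.
#' @export
study_flow_counts <- function() {
  list(
    eligible = 78882L,
    activated = 35014L,
    activated_analysis_denominator = 35019L,
    valid_baseline = 32229L,
    female = 21306L,
    bc = 23016L,
    inactive = 16336L,
    completer = 19964L,
    imputed = 29261L,
    high_engager = 15511L,
    low_engager = 16718L,
    inactive_high_engager = 7022L
  )
}

#' Published proportions recomputed from their printed counts
#'
#' Each rate is the printed numerator over the printed denominator, expressed
#' in percent and rounded to two decimals (the precision at which the rates
#' were published).
#'
#' @param counts Count list, by default [study_flow_counts()].
#' @return Named numeric vector of percentages.
#' @export
participant_flow_rates <- function(counts = study_flow_counts()) {
  pct <- function(num, den) round(100 * num / den, 2)
  c(
    activation_rate = pct(counts$activated, counts$eligible),
    valid_baseline_rate = pct(counts$valid_baseline,
                              counts$activated_analysis_denominator),
    female_share = pct(counts$female, counts$valid_baseline),
    bc_share = pct(counts$bc, counts$valid_baseline),
    inactive_share = pct(counts$inactive, counts$valid_baseline),
    completer_rate = pct(counts$completer, counts$valid_baseline),
    imputed_rate = pct(counts$imputed, counts$valid_baseline),
    high_engager_share = pct(counts$high_engager, counts$valid_baseline),
    low_engager_share = pct(counts$low_engager, counts$valid_baseline),
    inactive_high_engager_share = pct(counts$inactive_high_engager,
                                      counts$valid_baseline)
  )
}
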