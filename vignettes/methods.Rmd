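---
title: "Models and methods: simulating and evaluating an adaptive step-goal micro-incentive program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

`stepincentives` is an executable model of a population-scale mobile walking
program in which participants earn very small loyalty-point rewards
(Can $0.04/day) for reaching personalized daily step goals, plus bonus
rewards for 14-day "step up challenges" that adaptively raise the goal — and
of the quasi-experimental, single-group pre-post evaluation such a program
receives. The package has four layers:

1. a **synthetic step-diary generator** calibrated to the published baseline
   marginals of such a cohort,
2. the **program state machine** (validity filtering, baseline goal
   assignment, challenge lifecycle, reward ledger),
3. **analytic-sample construction** under three missing-data approaches, and
4. the **weekly mixed-effects analysis** producing covariate-adjusted
   least-square means, week-12 contrasts, local Cohen $f^2$ effect sizes,
   subgroup stratification, and engagement moderation.

The real program's raw data are proprietary; every layer is therefore
exercised on generated data whose structure is known, which also means the
estimators can be validated against known truth — something the original
observational analysis could not do.

## The program mechanics

Days are 1-based and contiguous; there is no calendar logic.

* **Valid day**: a recorded count in $[1000, 40000]$ steps, both bounds
  inclusive. Below 1000 the phone is assumed not worn; above 40,000 the count
  is treated as a device artifact.
* **Baseline (run-in)**: days 1–14. With $\ge 5$ valid days the personalized
  baseline is the mean of the valid days; otherwise the participant receives
  a generic 5000-step goal and is excluded from analysis.
* **First goal**: baseline mean + 1000, rounded to the nearest 100 steps.
  Exact ties (…50) round up; the convention is half-up because the program
  description does not specify tie behavior and half-up is the conventional
  reading of "rounded to the nearest 100."
* **Rewards**: Can $0.60 for activation; Can $0.04 each day the goal is met
  (steps $\ge$ goal, inclusive); Can $0.40 for each successful challenge.
* **Step Up Challenge**: a 14-day window is successful when the daily goal is
  met on $\ge 10$ (possibly nonconsecutive) days; success raises the goal by
  500 steps from the next day. The first window is auto-enrolled; later
  windows must be accepted, and acceptance is window-level (no mid-window
  joining). After four successes the goal freezes.

**Timeline reconciliation.** The published reward ledger (cap
$5.00 = 0.60 + 2.80 + 1.60$) implies exactly 70 daily-reward days
($2.80/0.04$), yet the evaluation horizon spans 12 post-run-in weeks
(84 days). The unique timeline consistent with the printed ledger is adopted
as the reference: 14 run-in days, a 14-day daily-rewards-only phase, four
14-day challenge windows (days 29–84 after activation), and two final weeks
(study weeks 11–12) in which goals remain in force but no rewards accrue.
Diaries therefore span 98 days covering study weeks 0–12.

The ledger obeys four invariants, enforced at run time and property-tested:
earnings $= 0.60 + 0.04\,n_{daily} + 0.40\,n_{success}$; earnings $\le 5.00$;
the goal trajectory is non-decreasing; and the final goal exceeds the initial
goal by exactly $500 \times n_{success}$ (so at most baseline + 3000 after
the initial +1000 and four successes).

## The synthetic-data generator

Each participant $i$ has covariates (age, gender, province, median personal
income) and a latent daily step level

$$\mu_i = \exp(Z_i) + g_i + p_i, \qquad Z_i \sim N(\mu_{\log}, \sigma_{\log}^2),$$

where $g_i$ and $p_i$ are centred gender and province offsets parameterized
by the male-minus-female gap (2297.5 steps/day) and the BC-minus-NL gap
(992.95 steps/day). On post-run-in days a participant adds an incentive
response

$$r_{iw} = \max\{0,\; \beta \cdot \operatorname{logit}^{-1}(\eta_i) -
  \delta \,(w - w_0)_+\},$$

with $\beta$ the response effect (steps/day for a fully engaged responder),
$\eta_i \sim N(m_\eta, s_\eta^2)$ a latent engagement propensity, $\delta$ a
weekly decay rate and $w_0$ the decay onset week. Daily counts are
$\max\{0, \operatorname{round}(\mu_i + r_{iw} + \varepsilon_{it})\}$ with
i.i.d. noise $\varepsilon_{it} \sim N(0, \sigma_d^2)$; independently, with
probability $q$ a day is overwritten by a non-wear count drawn uniformly from
0–999, which the validity filter then catches mechanically.

The same latent trait $\eta_i$ drives challenge acceptance (acceptance
probability $\operatorname{logit}^{-1}(\eta_i)$ per optional window), so the
engagement median split downstream is a meaningful moderator: high engagers
genuinely respond more.

### Default calibration

Defaults were chosen once, by simulation at $n = 20{,}000$, to reproduce the
published cohort marginals *after* the valid-day filter is applied — the
filter left-truncates the noise distribution and biases naive closed-form
calibration:

| parameter | default | rationale |
|---|---|---|
| age | $N(33.7, 11.6^2)$, floored at 13 | published mean/SD; app minimum age |
| female share | 0.661 | published |
| BC share | 0.714 | published |
| income (Can$1000/yr) | $N(29.65, 4.1^2)$ | published mean; completer SD |
| $\mu_{\log}, \sigma_{\log}$ | 8.20, 0.90 | generated baseline mean $\approx 6520$ (target 6511.22) with $\Pr(\text{baseline} < 5000) \approx 0.52$ (target just over half) |
| non-wear prob $q$ | 0.40/day | reproduces the published completer rate ($\approx 61\%$ vs 61.94%) under the 4-of-7 weekly validity rule |
| response $\beta$ | 800 steps/day | population-mean response $\beta/2 \approx 400$, matching the published intervention-period average gain ($\approx 354$ steps/day) |
| engagement $\eta$ | $N(0, 1)$ | engagement factor spread across (0, 1), median 0.5 |
| decay $\delta$, onset $w_0$ | 100 steps/day/week, week 9 | matches the published late-week decline ($\approx 49$ steps/week at the population level from week 9) |
| daily noise $\sigma_d$ | 1500 steps | realistic day-to-day variability without excessive zero-flooring |

Two published quantities are deliberately *not* matched, because they are
jointly unattainable within this model family; the package's tests do not
assert them:

* the published baseline **SD** (4220.7): once the mean is ~6511 and more
  than half the cohort must sit below 5000 after truncation, the implied
  between-person SD is ~5150;
* the published **any-approach rate** (92.03% of activations): homogeneous
  non-wear cannot simultaneously give a ~62% completer rate and a ~92%
  valid-baseline rate; the completer rate was prioritized because the
  completer/imputed split drives the missing-data comparisons.

### What the generator does not emulate

No within-person day-to-day autocorrelation (noise is i.i.d.; an AR
extension would be natural), no weekday/weekend structure, no weather or
seasonal effects, no informative missingness (non-wear is missing completely
at random), and no dependence of the incentive response on the baseline
level. Passing tests therefore demonstrate that the pipeline's estimators
work when their assumptions hold — not that the real program's effect
estimates are unbiased under, say, informative non-wear.

## Analytic samples

Weekly means use only valid days; study week $w$ covers days
$14 + 7(w-1)+1$ to $14+7w$ (the published analysis gives no explicit
day-to-week map; this contiguous mapping is the natural one). A week is
valid with $\ge 4$ of 7 valid days. Three approaches handle missing week-12
data:

* **any** — valid baseline and $\ge 1$ valid week among 1–12; *all* valid
  weeks enter the model (the published analysis models every study week);
* **completer** — valid baseline and valid week 12;
* **imputed** — valid baseline, invalid week 12; a pseudo week-12 row equal
  to the baseline value is added (last observation carried forward).

Completer and imputed partition the valid-baseline cohort; completer
$\subseteq$ any. LOCF makes each imputed participant's week-12 change exactly
zero, so when dropout is concentrated among responders the imputed estimate
is attenuated toward zero — a directional property the tests verify by
construction.

**Engagement metric.** "Percentage of days on which a challenge was
accepted" is ambiguous; it is implemented as the fraction of challenge-phase
days covered by an accepted window (auto-enrollment makes the floor
$14/56 = 25\%$). Under equal window lengths this reduces to the
accepted-window fraction. Participants strictly above the sample median are
"high" engagers; ties go to "low" (the published description labels *above*
the median as high).

## The weekly mixed model

For participant $i$ in study week $w \in \{0, \dots, 12\}$ (categorical,
baseline reference):

$$y_{iw} = \alpha + \gamma_w + x_i^\top \beta + b_i + \epsilon_{iw}, \qquad
  b_i \sim N(0, \sigma_b^2),\; \epsilon_{iw} \sim N(0, \sigma_e^2),$$

with covariates age, gender, median personal income (Can$1000/yr), and
province, and a per-participant random intercept. Estimation is REML
(`lme4`); inference is Wald with asymptotic (z) reference distributions
(`emmeans`). These are conventional defaults for this model class; the
published analysis names neither its estimation method nor its df treatment.

* **Least-square means** per week: continuous covariates at their sample
  means, categorical covariates averaged with equal weights over levels.
  Whether the original analysis balanced or population-weighted the
  categorical covariates is unstated; equal weighting is this package's
  declared choice (the `emmeans` convention).
* **Week-12 effect**: LS-mean(week 12) − LS-mean(week 0), with Wald 95% CI
  and z-test p-value.
* **Local Cohen $f^2$**:
  $f^2 = (R^2_{full} - R^2_{reduced}) / (1 - R^2_{full})$ where the reduced
  model drops the focal term (study week; or the week × engagement
  interaction in moderation fits) and both models are fitted on identical
  rows. $R^2$ is the **marginal** (fixed-effects) $R^2$ analog for mixed
  models — variance of the fixed-effect predictions over total variance
  (fixed + random intercept + residual). How the original analysis computed
  $f^2$ inside a mixed model is unspecified; the marginal analog is this
  package's documented interpretive choice. Negative values from numerical
  noise are clipped to 0. Bands: $\ge 0.02$ small, $\ge 0.15$ medium,
  $\ge 0.35$ large.
* **Moderation**: engagement main effect + study week × engagement
  interaction; the headline estimand is the week-12 difference-in-differences
  (high − low). The published wording ("allows the difference … to differ at
  baseline and study week 12") could describe a two-timepoint contrast; the
  full interaction is implemented, with the DiD contrast extracted from it,
  because it nests the two-timepoint reading.
* **Stratified fits**: total, inactive/active (baseline < 5000 vs
  $\ge$ 5000), BC/NL, low/high engager, and the crossed
  activity × engagement and province × engagement strata. Covariates constant
  within a stratum (province inside BC, say) are dropped from that fit.
  Singular or non-converged fits return a flagged row with estimands
  withheld.

Degenerate inputs are contracts, not crashes: an empty stratum yields an
$n = 0$ row with no estimates; unknown approach labels, wrong-length
challenge windows, short diaries and duplicate participant-days raise named
errors.

## Numerical and design choices

* **Reward amounts** are plain doubles; ledger identities are asserted to
  $10^{-9}$, far below the $0.01 grain of the currency.
* **Goal rounding** is half-up via `floor(x/100 + 0.5) * 100`, avoiding
  banker's rounding surprises at …50 ties.
* **Determinism**: a single integer seed fixes the population (one
  `set.seed` at generation) and a second derived seed fixes acceptance
  draws; a fixed seed reproduces every artifact byte-for-byte.
* **Known-truth validation** uses a cohort whose latent levels sit well
  inside the validity window (log-mean 8.7, log-SD 0.3, noise SD 500, MCAR
  non-wear 30%), engagement factor pinned at 1 and decay off, so a
  `response_effect` of 500 *is* the realized week-12 effect on the weekly
  valid-day mean. Under the default heavy-tailed calibration this is not
  true — the valid-day filter truncates low-level participants' noise and
  shrinks the realized effect below the nominal one — which is itself a
  finding about measurement-filtered step data, and the reason the recovery
  conditions pin the latent scale.
* **Problem sizes**: marginal-calibration tests use $n = 5000$; estimator
  validation uses $n = 2000$ with 200 replicates (bias within 5% of truth,
  95% CI coverage within 92–98%); the worked analysis scripts use
  $n = 5000$. These sizes put Monte-Carlo error well below every asserted
  tolerance while keeping a full run in minutes on one core.

## Known limitations

The generator's missingness is MCAR, so the three analytic approaches agree
more closely on synthetic data than they would under informative non-wear.
The engagement metric is behaviorally downstream of a single latent trait;
real engagement is multidimensional. The decay model is linear in weeks with
a hard onset. And the package deliberately does not model recruitment,
reward redemption, notifications, weather, or device heterogeneity.
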