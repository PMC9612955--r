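---
title: "Models and methods behind medistract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind medistract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`medistract` re-implements, as a tested pipeline, the statistical workflow
of a within-subjects pain-distraction experiment: participants perform
either a demanding 2-back working-memory task or an easy left--right arrow
task, under a monetary reward or no reward, while a calibrated low (warm)
or high (painful) thermal stimulus is applied; afterwards they rate the
stimulus on a 0--100 scale. The scientific question is whether rewards
amplify task-induced hypoalgesia, and whether trial-by-trial task
performance mediates the effect of task demands on pain. This vignette
explains the models, the choices we made where the design was open, and
what the synthetic cohort does and does not emulate.

```{r setup}
library(medistract)
```

## Trial scoring: the nonparametric sensitivity statistic A

Per-trial 2-back performance is scored from hits (`"same"` responses to
2-back matches) and false alarms (`"same"` responses to non-matches) with
the nonparametric sensitivity index A rather than d', because short
streams routinely produce hit or false-alarm rates of exactly 0 or 1,
where d' diverges. We use the three-case piecewise form

$$A = \tfrac34 + \tfrac{H-F}{4} -
\begin{cases}
F(1-H) & F \le 0.5 \le H\\
F/(4H) & F \le H < 0.5\\
(1-H)/(4(1-F)) & 0.5 < F \le H
\end{cases}$$

extended below the chance diagonal by $A(H,F) = 1 - A(F,H)$. Two
conventions close the formula's 0/0 gaps: $F/(4H) := 0$ when $F = 0$, and
$A := 0.5$ on the whole diagonal $H = F$, including the corners $(0,0)$
and $(1,1)$. The corner convention is deliberate: it is the only choice
that preserves both the symmetry identity $A(H,F) + A(F,H) = 1$ and
monotonicity on the full unit square, and a stream with $H = F$ carries no
evidence of discrimination wherever it sits. Omitted responses count as
implicit "different" responses (misses on targets, correct rejections on
non-targets), the standard n-back scoring convention. On the arrow task
the left arrow is arbitrarily the signal category; A is invariant to
swapping the assignment, which the test suite checks.

## Calibrations

Three per-participant calibrations precede the main task.

**Thermal.** A method-of-constant-stimuli session (7 temperatures from 40
to 49 degrees C, 4 sites, 28 stimulations) yields warmth ratings on
nonpainful trials and pain-intensity ratings on painful trials.
`fit_thermal_curve()` fits an ordinary least-squares line per branch and
inverts it at warmth 80/100 (the low temperature) and pain 60/100 (the
high temperature), clipping to the stimulated range. A straight line per
branch is the simplest monotone response curve that the 7-point design can
support; when a branch's least-squares slope is not positive the function
falls back to isotonic regression and inverts the step function by
interpolation, and a flat branch is an explicit error rather than a
fabricated threshold.

**Task speed.** `run_isi_staircase()` titrates the interstimulus interval
(ISI) of the 2-back over at most 15 trials toward an A band of
0.75--0.85. The step rule is multiplicative (start x1.5), halving the
factor's distance from 1 after each direction reversal, with the ISI
clamped to the presentable 19--2583 ms range; multiplicative steps match
the roughly logarithmic effect of ISI on difficulty and settle inside the
trial budget. A trial with A above the band speeds the task up, below the
band slows it down, inside the band holds.

**Money.** `fit_money_acceptance()` fits a maximum-likelihood logistic
regression of 26 accept/reject pain-for-money choices on the offer (0--3
dollars) and inverts it at 95% acceptance, clamping to the allowed
\$0.50--\$3.00. Plain `glm` maximum likelihood is used, with complete
separation detected explicitly and resolved by the midpoint between the
highest rejected and lowest accepted offers (an all-accept table clamps to
\$0.50, all-reject to \$3.00), and a non-positive slope clamped to \$3.00
with a warning; a ridge penalty would solve the same problem less
transparently. By construction the fitted curve evaluated at the
unclamped amount returns exactly 0.95, which is the module's contract.

## Preprocessing

`preprocess_trials()` applies the validity rules: ratings given faster
than 150 ms are removed (exactly 150 ms is kept — the rule is strictly
"faster than"), high-temperature trials judged "not painful" have their
pain rating set to 0, ratings are rescaled to 0--1 (which also conditions
the mixed-model optimisation), and trial number $t$ and $\log t$ are
derived. Because it is not documented whether the published 1.1% removal
rate was computed over all trials or only the analysed high-temperature
trials, the filter report carries both denominators. Pain analyses use
only high-temperature trials; performance analyses only 2-back trials.

## Repeated-measures ANOVA and contrasts

`rm_anova_2x2()` runs the within-subject 2x2 ANOVA on per-participant cell
means (base `aov` with the participant error strata). Every effect of a
2x2 within design has 1 numerator df, so each F is identically the square
of the paired t of the corresponding difference score — the suite asserts
this equivalence to 1e-8 — and sphericity corrections are moot. Effect
sizes are partial eta squared, $SS_{\text{effect}} / (SS_{\text{effect}} +
SS_{\text{error}})$ within the effect's own stratum. `planned_contrasts()`
tests the four simple effects (task within each reward level, reward
within each task) by paired t, each with its own paired-difference SE
(robust to any covariance structure across cells), Holm-adjusted as one
four-member family per outcome. `within_subject_se()` produces
Cousineau-style error bars: participant-centred cell values, re-centred on
the grand mean, with the $\sqrt{C/(C-1)}$ bias correction for $C$ cells.

## The multilevel moderated mediation engine

The core model is a 1-1-1 mediation with reward moderation, estimated by
row-stacking: each analysed trial contributes a mediator row (response =
performance $M$) and an outcome row (response = 0--1 pain rating $Y$),
with selector variables switching each equation's predictors on:

$$M_{ij} = \alpha_M + (a + a_W W + u_{aj})X + r_M W + \gamma_{1M} t +
\gamma_{2M}\log t + e_{Mij}$$
$$Y_{ij} = \alpha_Y + (b + b_W W + u_{bj})M + (c' + c'_W W + u_{c'j})X +
r_Y W + \gamma_{1Y} t + \gamma_{2Y}\log t + e_{Yij}$$

Random effects are jointly normal with unstructured covariance $\Psi$, and
residuals are independent with one variance per outcome type. Fitting
both equations as one mixed model is what lets $\Psi$ carry
$\sigma_{ab} = \mathrm{cov}(u_{aj}, u_{bj})$, and the indirect effect is
covariance-inclusive: $ab = \hat a\hat b + \hat\sigma_{ab}$, with
conditional versions $IE(w) = (\hat a + \hat a_W w)(\hat b + \hat b_W w) +
\hat\sigma_{ab}$ at $w \in \{0,1\}$ and their difference as the moderated
mediation index.

Estimation is profiled restricted maximum likelihood: the fixed effects
and the residual scale have closed forms given the covariance parameters,
which are optimised as the log-Cholesky factor of $\Psi/\sigma^2$ plus the
log residual-variance ratio (quasi-Newton, relative tolerance 1e-10, up to
three jittered restarts; a "false convergence" report from the optimiser
is accepted only if re-polishing from that point cannot improve the
deviance further, which distinguishes a flat, ill-scaled optimum from a
genuine failure). The objective is evaluated from per-group sufficient
statistics, so a participant-level bootstrap replicate refits from the
original participants' statistics without touching rows. The test suite
cross-checks the whole engine against `nlme::lme` (the toolchain the
stacked formulation is usually run in) and against per-equation OLS in the
zero-variance limit.

Two random-effect presets exist: `"default"` adds random intercepts for
both equations to the three path slopes (the standard formulation), and
`"paper"` uses random a, b, c' paths only. A diagonal-$\Psi$ option pins
all covariances at zero, in which case $ab$ reduces exactly to
$\hat a \hat b$.

Reported per-coefficient degrees of freedom use the deliberately rough
large-sample convention (stacked rows minus fixed effects); inference on
indirect quantities should come from `bootstrap_mediation()`, which
resamples participants with replacement (each draw entering as its own
cluster), refits warm-started from the full-sample estimates, drops and
counts non-convergent replicates (erroring above 10%), and returns
percentile intervals. The separate total-effect model
(`fit_total_effect()`) regresses the pain rating on task, reward, their
interaction and the trial covariates with random intercept and task slope,
giving $c$ and its reward moderation.

## The synthetic cohort

`cohort_config()` + `simulate_participants()` + `simulate_trials()`
generate everything the real study collected. The generative model is the
mediation model above run forward — that is exactly the structure the
downstream analyses assume, which is what makes parameter-recovery and
coverage testing meaningful. Defaults are the study's conditions: 57
participants, 64 trials in a balanced 2x2x2 factorial ordered by
permuted-block randomisation with at most 3 consecutive trials at the same
temperature, fixed effects at the published point estimates (e.g. task
demands on performance $-0.13$, its reward moderation $0.04$, performance
on ratings $-0.16$, direct task effect $-0.04$), a small positive log-trial
coefficient on ratings (early pain sensitization), zero linear-trial
coefficients, and calibration parameters drawn to match the reported
cohort summaries (low temperature $45.3 \pm 1.9$ C, high $48.4 \pm 0.6$ C,
ISI log-normal around a mean of about 880 ms, calibrated reward averaging
about \$2). Rating reaction times are log-normal with a 1.1% fast-guess
admixture below the 150 ms cutoff, so the validity filter has realistic
work to do. The proportion of high-temperature trials judged "painful" is
not reported for the study; it is exposed as `painful_prob_high` and
defaults to 1, which keeps the generative truth identical to the analysis
model (the calibration targets a clearly painful 60/100 stimulus).

Performance and the latent rating are clipped to [0, 1] after the linear
model, which slightly attenuates effects near the bounds. Two
consequences are documented rather than hidden: with the published
performance intercept (0.96) the easy-task scores sit close to the ceiling
and clipping mildly attenuates recovered coefficients, so the recovery and
coverage simulations in the test suite centre the intercepts mid-scale
(0.8 / 0.5); and a random-slope covariance as large as 0.05 forces slope
SDs whose extremes would clip, so the covariance-recovery study uses
mid-scale means and asymmetric slope SDs (0.18 / 0.32) to keep clipping
negligible.

The simulated 2-back observer is an equal-variance Gaussian responder
whose d' falls with shorter ISIs as $d'(\text{ISI}) = \min\{1.35
(\text{ISI}/700)^{0.4}, 4.5\}$; the shallow exponent means one staircase
step changes expected A only moderately, so a 15-trial staircase reliably
lands where mean A sits inside (or within noise of) the 0.75--0.85 band.
The simulator does not model letter-identity confusability, thermode
physics, skin-temperature dynamics, site-wise sensitization, or
questionnaire measures — so passing tests certify the statistical
machinery under the assumed generative structure, not robustness to the
many ways real psychophysical data violate it.

## Problem sizes used by the automated checks

The parameter-recovery study runs 50 cohorts of 60 participants by 64
trials; the covariance-inclusive indirect-effect study 10 such cohorts;
the bootstrap coverage study 200 cohorts of 30 participants by 16 analysed
trials with 300 bootstrap replicates each (the full analysis default of
10,000 replicates is reserved for the `"paper"` pipeline preset); these
sizes give Monte-Carlo error well inside each check's tolerance. The
bootstrap coverage fit uses the minimal random set `{a, b}`, which is the
smallest model that carries the covariance-inclusive indirect effect.

## An end-to-end run

```{r, eval = FALSE}
cfg <- run_config(seed = 1,
                  cohort = cohort_config(n_participants = 57,
                                         n_trials = 64),
                  bootstrap_B = 1000)
bundle <- run_pipeline(cfg, out_dir = "run1")
print(bundle)
summary(bundle$mediation$fit)
```

The run writes the cohort and calibration tables, the filter report, the
ANOVA/contrast tables, the mediation coefficient table in the two-block
layout with bootstrap confidence limits, a path-diagram text summary, and
a manifest (seed, preset, config hash) sufficient to reproduce every
number; the same seed and config always reproduce identical files. Each
pipeline stage draws from its own named substream of the top-level seed,
so changing, say, the bootstrap size never changes the simulated cohort.

## Known limitations

- The engine fits the canonical stacked formulation: independent residuals
  with outcome-specific variances and no within-trial residual covariance
  between mediator and outcome rows.
- Percentile intervals from 30-participant resamples are near the lower
  edge of nominal coverage, as percentile bootstraps typically are with
  few clusters.
- The coefficient p-values use a rough large-sample df convention and are
  secondary to bootstrap intervals by design.
- Clipping to [0, 1] makes the generative model only approximately linear
  near the response bounds; defaults keep means away from the bounds.
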