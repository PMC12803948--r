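---
title: "PEST-MLE threshold hunting: model, algorithm, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PEST-MLE threshold hunting: model, algorithm, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestmle)
```

## The psychometric model

A resting motor threshold (RMT) procedure asks, at each stimulator
intensity `x` (in %MSO), whether the evoked MEP exceeded a target
amplitude. We model the probability of that event as a cumulative
Gaussian with a single free parameter, the threshold `t`:

$$P(\text{MEP} > \text{target} \mid x) \;=\; \Phi\!\left(\frac{x - t}{\sigma}\right).$$

`t` is the intensity of 50 % success — exactly the conventional
definition of the motor threshold. The spread `σ` is *not* estimated:
estimating a slope from 30 binary trials concentrated near threshold is
ill-conditioned, and the sequential procedure only needs the location.
Two parameterisations are supported:

* **absolute** (default): `σ` fixed in %MSO, default **3.5 %MSO**. A
  fixed spread makes the log-likelihood a sum of log-concave terms in
  `t`, hence convex, and gives the model exact mirror symmetry
  (reflecting intensities and inverting outcomes reflects the
  estimate), which the test suite exploits.
* **relative**: `σ = s·t` with dimensionless `s` (a typical value is
  0.07), following the original PEST formulation where curve width
  scales with intensity. Provided for fidelity; the absolute mode is
  the package default because its invariances are cleaner and nothing
  in the 30-trial protocol distinguishes the two in practice.

Two *virtual anchors* enter the likelihood as pseudo-trials of weight
1: an assumed failure at 0 %MSO and an assumed success at 100 %MSO.
They encode the physical boundary assumptions, keep the likelihood
bounded before both outcome classes have been observed, and wash out as
real trials accumulate (at `t = 50`, each anchor sits ~14 spreads into
its tail). They are weighted pseudo-observations rather than hard
constraints so the objective stays smooth.

## Fitting

`pest_mle()` minimises the negative log-likelihood (the likelihood is
maximised; we work with the negated log for numerical convention) over
a bounded interval, default **[1, 150] %MSO**. The upper bound
deliberately exceeds the device maximum: a subject whose threshold lies
beyond 100 %MSO should produce an estimate above 100, which the session
layer then caps and flags rather than silently truncating.

Numerical choices:

* Likelihood terms are computed on the log scale
  (`pnorm(..., log.p = TRUE)` for both tails), so success and failure
  terms have symmetric accuracy even 20 standard deviations into a
  tail; log-probabilities are floored at `log(epsilon)` with
  `epsilon = 1e-12` so the anchor terms can never produce `-Inf`.
* The minimiser brackets the optimum with a coarse 1 %MSO vectorised
  grid and refines with `stats::optimize()` (tolerance 1e-7). For
  absolute spread the objective is convex, so this finds the global
  minimum; a fine-grid fallback runs (and is flagged on the fit object)
  only if the optimiser fails or the bracket is beaten, which can in
  principle happen in the relative mode.
* `grid_search_threshold()` is the deliberately naive alternative: an
  exhaustive scan at a given resolution, ties broken toward the lower
  intensity. The suite requires the two routes to agree within
  0.1 %MSO on hundreds of randomized instances.

## The session loop

`run_session()` reproduces the adaptive protocol:

1. the first intensity is an integer drawn uniformly from
   **20–60 %MSO** — wide enough that convergence is demonstrated
   without prior knowledge of the threshold;
2. after every valid trial the threshold is re-fit over all trials so
   far, and the next tested intensity is the estimate rounded
   half-away-from-zero to the stimulator resolution (default 1 %MSO)
   and clamped to [1, 100]. No additional step schedule or
   perturbation is applied: the tested intensity simply tracks the
   estimate;
3. **30 valid trials** complete a session. Deliveries rejected for
   pre-stimulus voluntary EMG are repeated at the same intensity and do
   not consume the budget (the repeat count is logged); a cap of 10
   consecutive rejections guarantees termination, after which the
   session is returned truncated and flagged rather than erroring, so
   batch simulations degrade gracefully.

The running estimates are stored at full precision; the rounded tested
intensities are what the stimulator actually delivered. All evaluation
functions default to the real-valued series, with the rounded variant
behind a switch, because rounding is a property of the device, not of
the estimator. The half-away-from-zero rounding rule is fixed and
documented so tests can be exact.

EMG-derived outcomes follow the online rules: a trial is rejected if
the peak-to-peak amplitude in the pre-stimulus window exceeds 0.05 mV
(strict), and the MEP is the peak-to-peak value in the 15–40 ms
post-stimulus window. The rejection window is taken as `[-65, 0)` ms —
the stimulus sample itself belongs to the response — and window
endpoints are converted to sample indices by rounding to the nearest
sample, closed on both ends. "Greater than the target" is read
strictly, so a peak-to-peak exactly equal to the target is a failure; a
measure-zero event in practice, but fixing it keeps the classifier
deterministic.

## Convergence criteria

* **Precision** at trial `k` (defined from `k = 3`): the running
  estimates at trials `k-2, k-1, k` span at most **2 %MSO**
  (inclusive). Since consecutive ±1 %MSO steps are unavoidable at
  device resolution, 2 %MSO is the smallest span exceeding that
  fluctuation.
* **Accuracy** at trial `k`: the estimate lies within **±5 %** of the
  session's *reference value* — the mean tested intensity over trials
  25–30 (six trials, both endpoints included). The band is relative (a
  0.05 tolerance level); an absolute ±%MSO band is available behind a
  flag. Both criterion boundaries are inclusive ("within" read
  inclusively). The reference uses tested intensities by default — in
  the late trials the tested intensity is the rounded previous
  estimate, so the two readings differ only by rounding — with an
  ML-estimate-based reference behind a flag.
* A session's **convergence trial** is the first trial of the *final*
  run of satisfied flags extending to the end of the session; a
  criterion satisfied transiently and then broken does not count. Over
  a collection of sessions, the reported criterion trial is the first
  trial by which at least 95 % of sessions have converged.

## Reliability statistics

For paired sessions (within-day: sessions 1 vs 2; between-day:
sessions 1 vs 3), at every trial index 1–30:

* **ICC(2,1)** — two-way random-effects, absolute agreement, single
  measurement, computed from the ANOVA mean squares
  `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))` with `k = 2`.
  The implementation computes the mean squares directly from the sums
  of squares; the test suite cross-checks it against `aov()` to 1e-10.
  A zero-variance matrix leaves the ICC undefined and returns `NA`
  with a warning. The first trial with ICC strictly above 0.80 is
  reported as the reliability convergence point.
* **Sw** — within-subject SD, `sqrt(Σ dᵢ² / 2n)`; **RC** — the
  reproducibility coefficient `1.96·√2·Sw`, the 95 % bound on a
  test–retest difference; **SEM** — `SD·√(1 − ICC)`. The
  between-subject SD feeding the SEM is taken from the per-subject
  means pooled across the two sessions — the symmetric choice.
* **Bland–Altman** — mean and sample SD (n−1 denominator) of the
  ordered differences (session 1 minus the comparison session), with
  limits of agreement `mean ± 1.96·SD`.

## The virtual subject

`virtual_subject()` is the package's generative model, and its defaults
define the simulated study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| cohort thresholds | Uniform(35, 65) %MSO | plausible adult RMT range |
| `gen_spread` | 3.5 %MSO | true response-curve steepness |
| `amp_sigma_log` | 0.9 | lognormal shape of MEP amplitude |
| `day_sd` | 3.0 %MSO | between-day threshold drift |
| `session_sd` | 1.0 %MSO | within-day, between-session drift |

The amplitude model is tied to the response curve in closed form: the
lognormal median at intensity `x` is
`target · exp(amp_sigma_log · z(x))` with
`z(x) = (x − t)/gen_spread`, so
`P(amplitude > target | x) = Φ(z(x))` *identically* — thresholding a
sampled amplitude and drawing a Bernoulli outcome are the same process.
This reproduces the right-skewed MEP amplitude distribution at fixed
intensity with zero free calibration, and it fixes the relation between
the thresholds for different MEP targets: the threshold for target `A`
is `t + gen_spread · log(A / A₀) / amp_sigma_log` above the threshold
for `A₀` (≈ 5.4 %MSO for 0.2 mV vs 0.05 mV at the defaults), so the
two targets hunted in one session are generated by one consistent
amplitude process and are correlated within subject, as in real
cohorts.

Drift enters additively: each subject draws two day effects
(`N(0, day_sd)`) and four session effects (`N(0, session_sd)`);
sessions 1–2 share day 1, sessions 3–4 share day 2. This is the
minimal structure that makes within-day reliability exceed between-day
reliability. The drift SDs and `amp_sigma_log` are simulation knobs
chosen to produce within/between-day contrasts of realistic character,
not estimates of any cohort: no published generative parameters exist
for this protocol. They were fixed once, up front.

What the generator deliberately does **not** emulate: input–output
curve saturation (no plateau — the sigmoid is a probability, not an
amplitude curve), serial correlation or fatigue trends within a
session, attentional lapses (no lapse/guess rates), coil-repositioning
geometry, or stimulator charge interactions. Passing tests therefore
demonstrate the *algorithmic* properties of the estimator — unbiased
convergence, correct criterion arithmetic, the reliability contrast
induced by day-level drift — not the physiological variability of human
data; human reliability coefficients can only be qualitatively, not
numerically, reproduced here.

The engine's assumed spread (default 3.5 %MSO) and the generator's
true spread are deliberately independent settings: matching them is the
well-specified case, and mismatch experiments (a shallow assumed curve
hunting a steep subject, or vice versa) only require overriding one of
them.

## A session end to end

```{r example-session}
vs  <- virtual_subject(47)
log <- run_session(vs, session_config(seed = 42))
log

ref <- reference_value(log)
c(precision = convergence_trial(precision_flags(log$trials$estimate)),
  accuracy  = convergence_trial(accuracy_flags(log$trials$estimate, ref)))
```

```{r example-plot, fig.width = 6, fig.height = 4}
plot(log)
```

## Simulated studies

`simulate_study()` runs the full design — each subject measured in four
sessions (two per day), both MEP targets per session, 0.05 mV first —
and `analyze_study()` produces the convergence curves, the per-trial
reliability reports, and the late-trial (19–30) success-rate and
amplitude summaries. The default cohort is 50 subjects (400 sessions
for the two targets together), which the package uses as its standard
evaluation size; the acceptance script uses 200 independent
single sessions for the late-trial success-rate summary and the test
suite uses 500 for parameter recovery. At these sizes a full study
simulates and analyses in well under a minute.

```{r example-study, eval = FALSE}
study  <- simulate_study(study_config(n_subjects = 50, seed = 424242))
report <- analyze_study(study)
report
```

Everything is deterministic under the master seed: per-session seeds
are derived from it and recorded in each log, so any session can be
replayed in isolation (`running_estimates()` reproduces the logged
estimate series exactly).

## Known limitations

* The step size of the hunt shrinks as the estimate stabilises, so the
  precision criterion can be met before the estimate is close to the
  true threshold — precision converging earlier than accuracy is a
  property of the method, and accuracy (or a minimum trial count)
  should gate real use, not precision alone.
* The reference value is itself an estimate (trials 25–30 of the same
  session), so "accuracy" here is internal consistency with the
  session's own endpoint, not closeness to ground truth; in simulation
  the two can be compared, and the suite checks recovery of the true
  generative threshold separately.
* The one-parameter fit inherits any mis-specification of the spread;
  with a fixed 3.5 %MSO spread and data concentrated near threshold,
  location estimates are robust to moderate spread mismatch, but the
  package makes no attempt to estimate slope.
* Roll-back rules, minimum-step-size schedules, and Bayesian adaptive
  variants are out of scope.
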