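---
title: "The trigger-failure race model: simulation, estimation and checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The trigger-failure race model: simulation, estimation and checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stopsignal)
```

## The model

Response inhibition in the stop-signal task is modelled as an independent
horse race. On a stop trial, a go runner (triggered by the go stimulus)
races a stop runner (triggered by the stop signal, which arrives after the
stop-signal delay, SSD). If the go runner finishes first a response slips
out — a *signal-respond* trial; otherwise the response is inhibited. The
stop runner's latency, the stop-signal reaction time (SSRT), is never
observed directly and must be inferred.

Both finishing-time distributions are ex-Gaussian: the convolution of a
Normal(`mu`, `sigma`) with an Exponential of mean `tau`, the standard
positively skewed RT model. The distribution's mean is `mu + tau`, so the
mean go RT is `mu_go + tau_go` and the mean SSRT is `mu_stop + tau_stop`.

Two deficiencies of triggering augment the plain race:

* `P(TF)` — *stop trigger failure*: the stop runner never starts on a stop
  trial, so a response is executed regardless of the SSD;
* `P(GF)` — *go failure*: the go runner never starts, producing an
  omission on a go trial (and a trivially successful stop on a stop
  trial).

The trial likelihood follows from the race:

* go trial with response at `t`: `(1 - P(GF)) f_go(t)`;
* go omission: `P(GF)`;
* stop trial with response at `t` given SSD `d`:
  `(1 - P(GF)) f_go(t) [P(TF) + (1 - P(TF)) (1 - F_stop(t - d))]`;
* inhibited stop trial: one minus the integral of the previous line over
  `t`, i.e. `1 - p_respond_given_ssd()`.

Ignoring trigger failures inflates nonparametric SSRT estimates because
trigger-failure responses behave like ordinary go responses at any SSD;
the model separates the two sources, which is the reason for fitting it
at all. Failure probabilities are estimated on the probit scale
(`z`, with `P = pnorm(z)`), where a normal group distribution is natural.

## The hierarchy

Participants are nested in a group. Each of the eight participant-level
parameters gets a population *location* and *scale*: truncated-normal
group distributions for the six ex-Gaussian parameters (truncation
`[0.001, 2]` s, `mu_go` up to 3 s) and normal (truncated to `[-6, 6]`)
for `z_tf`, `z_gf`. Hyper-locations are uniform over the same bounds and
hyper-scales uniform over `[0.001, 1]`. These are deliberately weak: wide
enough that the likelihood dominates at usual sample sizes, bounded
enough that impossible regions (negative scales, probabilities pinned to
0/1) are excluded. The model is fitted separately per experimental
condition; nothing is pooled across conditions.

## What the simulator emulates — and what it does not

`task_design()` defaults encode the gamified session this package is
built around: 450 trials in 9 blocks, 25% stop trials scheduled by
within-block permutation, go-stimulus deadline 2 s, SSD staircase
starting at 250 ms moving in 50 ms steps (1-up/1-down, clamped to
`[0.05, 2]` s), inter-trial interval uniform on 0.5–1.5 s. The staircase
targets 50% responding on stop trials by construction. Go choice errors
occur at 1% (`p_choice_error`), matching typical go accuracy of 0.99.
The stop-trial proportion is not part of the published task description;
25% is the field-standard default and is exposed in the design object.

`simulate_cohort()` draws participant parameters from the population and
simulates every subject in every condition — a within-subject design, as
in the crossover studies this emulates. A subject's draw quantiles are
fixed once and mapped through each condition's population: identical
populations give identical participant parameters across conditions, and
condition effects act on a common cohort. This idealises the crossover
(no session-to-session parameter drift, no fatigue, no sequence
effects), so passing tests demonstrate correctness of the estimation
machinery under the model, not robustness to real-data violations such
as RT autocorrelation, practice effects, or context-dependent strategy
shifts.

`population_defaults()` centres the group at typical healthy-adult
values (mean go RT 0.967 s, mean SSRT 0.463 s, P(TF) near 0.06, P(GF)
near 0.02). Across-subject scales are not published quantities; they
were fixed once so that the simulated between-subject spread matches
typical descriptive SDs (go RT SD near 0.16 s, SSRT SD near 0.05 s):
`mu_go` 0.12, `sigma_go` 0.03, `tau_go` 0.04, `mu_stop` 0.04,
`sigma_stop` 0.012, `tau_stop` 0.02, probit scales 0.35.

```{r}
des <- task_design(n_trials = 450, n_blocks = 9)
r <- race_params(go = c(0.87, 0.09, 0.10), stop = c(0.42, 0.04, 0.04))
sim <- simulate_session(des, r, seed = 1)
mean(sim$response[sim$trial_type == "stop"])  # staircase-tracked ~0.5
```

## Data reduction

`qc_cohort()` reproduces the standard screen: anticipatory responses
(< 0.2 s) removed; mean signal-respond RT must be strictly faster than
mean correct go RT (the race model's testable implication);
p(respond|signal) must lie in `[0.25, 0.75]`; go accuracy outliers are
flagged cohort-wide by Tukey fences (type-7 quartiles — the convention
is not dictated by anything, so the most common one is used); and
subjects need the full set of complete sessions. A near-uniform go-RT
distribution (Kolmogorov–Smirnov distance to a uniform on its own range
below 0.09) raises an advisory *strategic responding* flag with a
warning but never excludes on its own, because no operational rule for
that judgement exists — it is a reviewer's call.

## Integration-method SSRT

`estimate_ssrt()` implements the integration method with replacement of
omissions: build the go-RT distribution from all go trials (choice
errors included, each omission replaced by the maximum observed go RT),
find the `ceil(p * N_go)`-th smallest go RT at `p = p(respond|signal)`,
subtract the mean SSD over all stop trials. The ceiling rule (clamped to
`[1, N_go]`) is a documented choice; no rounding convention is canonical.
Mean SSD is taken over all stop trials, not a staircase-converged
subset. With no trigger failures this estimator converges on
`mu_stop + tau_stop`; with trigger failures it overestimates —
the package's tests assert both directions.

## Sampling the posterior

The sampler is blocked adaptive random-walk Metropolis-within-Gibbs,
compiled for the per-trial likelihood:

1. each subject's 8-vector is updated as one block (multivariate normal
   proposal whose covariance tracks the running posterior residuals,
   global step tuned to ~23% acceptance during burn-in, frozen after);
2. each subject's stop-side subspace (`mu_stop`, `sigma_stop`,
   `tau_stop`, `z_tf`) gets an additional dedicated block update with
   its own adapted covariance — these four trade off against each other
   and move too slowly inside the full block alone;
3. each subject's `z_tf` and `z_gf` are refreshed from their conditional
   group priors (independence proposals whose acceptance is a pure
   likelihood ratio), which teleports through the flat regions of the
   failure-probability likelihoods at realistic trial counts;
4. each population (location, scale) pair is updated as a 2-block;
5. *translation* moves shift a population location together with all
   subject values, and *scale-expansion* moves rescale a group scale
   together with the subject deviations (both for `sigma_stop`,
   `tau_stop`, `z_tf`; Jacobian `c^(n+1)` for the expansion). These mix
   along the location ridge and through the scale funnel of the weakly
   identified stop-side hierarchy, where plain Gibbs crawls.

No gradients are required, which suits the truncated/probit
parameterisation. The race integral inside the likelihood is evaluated
by a fixed Gauss–Legendre rule *over the stop runner's density* (two
panels: Gaussian body and exponential tail, 48 nodes), which keeps the
integrand resolved however small `sigma_stop` becomes; the user-facing
`p_respond_given_ssd()` instead uses adaptive quadrature at absolute
tolerance 1e-9, and the two routes are cross-checked in the tests.
Per-trial log-likelihoods are floored at −700 so proposals into
impossible regions are rejected smoothly rather than producing `-Inf`
arithmetic.

Defaults are 3 chains of 5000 iterations (half burn-in). The recovery
and null-calibration analyses in the test suite run 10 subjects at 450
trials with 20000 (3 chains) and 8000 (2 chains) iterations — sizes
chosen as a demonstration scale at which the Gelman–Rubin diagnostics
(univariate and multivariate, threshold 1.1) pass with margin.
Convergence is always reported, never assumed: `rhat()` implements the
between/within-chain formula directly and `glance()` carries the
verdict.

At 8–10 subjects the trigger-failure location `z_tf_loc` is only weakly
identified: each subject contributes a handful of trigger-failure
trials, the subject-level likelihood is flat below some `z`, and the
posterior develops a long left tail toward the prior bound. The
posterior mean of P(TF) then sits below the generating value while the
credible interval remains calibrated. This is a property of the
posterior at that sample size, not of the sampler; it disappears as
trials accumulate (the likelihood profile peaks at the true value by
20000 trials).

## Posterior summaries and comparison

`summarise_posterior()` reports means and central 95% credible intervals
(2.5th/97.5th percentiles of the pooled post-burn-in draws); probit
parameters are additionally transformed to probabilities *per draw*
before averaging. `derived_mean_posterior()` forms the posterior of a
finishing-time mean by summing the `mu` and `tau` draws on each
iteration, collapsed across chains. `bayesian_p()` is the proportion of
draws in one condition exceeding the other's, paired by iteration index
after collapsing chains (independently fitted conditions make this a
cross-product estimate in expectation; iteration pairing keeps it
reproducible); ties count one half, so `BP(A,B) + BP(B,A) = 1` always.
`posterior_predictive()` re-simulates each subject under the *observed*
SSD sequences at drawn parameters and compares go-RT deciles,
signal-respond-RT deciles and inhibition rates per SSD bin against 95%
predictive bands.

## Degenerate inputs and numerical edges

* `p = 0` or `1` responding on stop trials makes the integration method
  undefined — an error, not an NA.
* A single subject cannot identify group scales; `fit_beests()` fixes
  them and samples only that subject's parameters.
* Zero population scales in the generator produce a deliberately
  degenerate cohort (all subjects at the location); negative scales are
  rejected.
* The ex-Gaussian density and CDF are computed in log space and remain
  finite for `tau` down to machine-reasonable values (`tau`, `sigma`
  must be strictly positive).
* Time is seconds everywhere internally; the readers/writers convert
  milliseconds at the boundary only.

## Known limitations

* The 2 s response deadline is not modelled as right-censoring; deadline
  misses are absorbed into P(GF). At realistic parameters the censored
  mass is negligible (the go density beyond 2 s is ~1e-5), but the
  choice would matter for much slower populations.
* TF and GF hierarchies are independent probit-normals; a TF–GF
  correlation is not modelled.
* Signal-respond choice accuracy is ignored (the task does not record
  it), so stop trials with wrong-side responses enter the likelihood
  like any signal-respond trial.
* Only ex-Gaussian runners are provided; no Wald or lognormal variants,
  and no dependent-race models.
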