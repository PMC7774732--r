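---
title: "A hidden Markov model of prostate-cancer active surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hidden Markov model of prostate-cancer active surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashmm)
```

## The estimation problem

Men diagnosed with low-risk prostate cancer are increasingly managed by
active surveillance (AS): treatment is deferred, and the cancer is monitored
with periodic PSA tests and surveillance biopsies until there is evidence of
reclassification. Two quantities govern how well any biopsy schedule works,
and neither is directly observable. First, biopsies under-sample the
prostate: a man whose cancer has already progressed can return a reassuring
Gleason 6 biopsy. Second, cancer grade can progress during surveillance, so a
man correctly enrolled as favorable risk may not stay that way. Estimates of
under-sampling made under a no-progression assumption, or of progression made
under a perfect-biopsy assumption, confound the two.

`ashmm` models a surveillance cohort as a discrete-time hidden Markov model
that identifies both quantities jointly:

* **Hidden states.** Two transient states — favorable risk (`FR`, the cancer
  still meets the cohort's AS inclusion criteria) and non-favorable risk
  (`NFR`, it no longer does). Progression `FR -> NFR` happens with a constant
  annual probability (the annual progression rate, `apr`) and is
  irreversible: grade progression does not reverse biologically, so the
  reverse transition is a structural zero.
* **Initial distribution.** Every patient enters AS *diagnosed* favorable,
  but with probability `pi_nfr` the diagnosis was wrong and the patient is
  already `NFR` at year 0. This misclassification-at-diagnosis probability is
  exactly the initial distribution of the chain.
* **Absorbing exits.** Each year a patient may leave surveillance. If they
  leave to radical prostatectomy, the surgical pathology reveals the true
  grade, so the two RP exits (`RP_FAVORABLE`, `RP_NONFAVORABLE`) anchor the
  hidden state: `RP_FAVORABLE` is reachable only from `FR` and
  `RP_NONFAVORABLE` only from `NFR` (two more structural zeros). Leaving
  without prostatectomy (`NO_RP`) is uninformative about the state and is
  reachable from both. Exit probabilities are state-dependent but
  observation-independent: they live in the transition matrix, not in a
  decision model.
* **Emissions.** While transient, a patient emits at most one biopsy result
  per year — positive (Gleason >= 7) with probability `sens` from `NFR` and
  `1 - spec` from `FR` — and one log-PSA value drawn from a state-specific
  two-component Gaussian mixture. A missing test is a *null observation*
  contributing likelihood 1: missingness is assumed non-informative, so
  missingness rates are not model parameters. PSA mixtures are state-specific
  because the validation compares PSA distributions separately for favorable
  and non-favorable patients.

A patient-year record needs only: year index since diagnosis, most recent
log PSA of the year (or missing), the year's biopsy result (or missing), and
an exit record. `read_cohort()`/`write_cohort()` handle a plain CSV layout;
patients still under surveillance at the end of the extract are `CENSORED`,
which is distinct from the `NO_RP` leaving state: a censored series
contributes the remaining transient-state mass to the likelihood and no
leaving-state factor. (Whether an ongoing patient should instead be coded as
an exit is a data-preparation decision; both codings are representable.)

### Within-year event order (likelihood)

The annual time step needs a convention the data sources do not dictate. The
package fixes: the year-`t` transition happens at the start of year `t`; an
exit replaces that year's observation slot (the leaving state *is* the
observation); a surviving patient's tests are emitted at the end of year `t`
and reflect the post-transition state. Consequently a non-censored exit in
year `t` implies observation years `1 .. t-1`, and the exit-year biopsy that
may have triggered treatment is subsumed by the leaving state. This is an
estimation-affecting convention, stated here once and enforced by the cohort
invariants.

## Estimation

`fit_hmm()` maximizes the cohort likelihood by Baum-Welch EM. The E-step
(`e_step()`, compiled) runs scaled forward-backward recursions per patient;
the M-step (`m_step()`) is closed-form: ratio updates for all probability
parameters and responsibility-weighted moments for the mixtures. Numerical
choices:

* **Scaling.** Per-year normalization of the forward variables; the
  recursions are exact (they match brute-force path enumeration to 1e-10 on
  short sequences, which is how the tests check them) and stable beyond
  50-year sequences.
* **Stopping rule.** Relative change of the cohort log-likelihood below
  `rel_tol = 1e-6`, capped at `max_iter = 500` iterations.
* **Restarts.** EM only finds local maxima, so `fit_hmm()` runs
  `n_restarts = 20` randomized starts. Starting probabilities are drawn
  uniformly on plausible boxes (initial/progression/exit rates in
  `[0.005, 0.3]`, sensitivity in `[0.5, 0.95]`, specificity in
  `[0.9, 0.999]`); mixtures start from the cohort's log-PSA quartiles with
  jitter. Restarts use a short-run/long-run strategy: every start runs
  `short_iter = 40` iterations, and only the best is polished to
  convergence. This is the standard emEM economy; setting
  `short_iter = max_iter` runs every start to convergence.
* **Degeneracy guards.** Mixture variances are floored at `1e-4`; a state
  with zero expected occupancy (e.g. a cohort of all-null censored
  sequences, where emissions are unidentified) keeps its previous emission
  parameters and the fit is flagged (`emission_held`).
* **Label order.** Mixture components are reported with `mu1 <= mu2`; the
  two hidden states are *not* interchangeable (the RP exits anchor them), so
  no state relabelling is needed.

Restart seeding depends only on the seed, not on the data, so fitting a
patient-shuffled cohort reproduces the same best log-likelihood.

## Uncertainty

`bootstrap_hmm()` implements the nonparametric patient bootstrap: `B = 100`
resamples of whole patients with replacement, each refitted; empirical SDs
and 2.5/97.5 percentile intervals are reported per parameter. Percentile
intervals (not BCa) are the simplest reading of "empirical standard errors
and confidence intervals". Refitting 100 resamples from 20 cold restarts
each would be wasteful; replicate fits reuse the point estimate as a warm
start plus `restarts - 1` random starts (default `restarts = 3`). This is a
documented economy knob, not part of the model. `bootstrap_t_test()` runs
the one-sided bootstrap-t positivity test (studentized statistic against the
centered, studentized replicate distribution), used to establish that
misclassification, progression and the biopsy false-negative rate are all
strictly positive.

## Comparing biopsy schedules

`simulate_protocol()` evaluates a schedule by Monte Carlo: patients are
diagnosed favorable-risk at age 50, progress with the fitted `pi_nfr`/`apr`,
and leave surveillance only on a positive biopsy or at age 75 (the fitted
exit-to-treatment probabilities are deliberately switched off so that every
protocol is compared on the same population). The two endpoints are the mean
number of follow-up biopsies per patient and the mean detection delay — the
months between first entering `NFR` and the positive biopsy — averaged over
patients with a true-positive detection; undetected progression has no
observable delay, and the rare false-positive exits of still-favorable
patients have none defined. Patients misclassified at diagnosis have their
first non-favorable year at 0.

The published schedules are time-based, so sampled PSA plays no scheduling
role; `simulate_trajectories()` exposes a hook should a PSA-reactive rule
ever be added. "Every 1 to 2 years" (UCSF) is instantiated as biennial after
year 1 (years 1, 3, ..., 25), the only reading consistent with that
protocol's published biopsy counts; the Toronto/PRIAS schedule is years
1, 4, ..., 25.

**Within-year order (simulation).** Here too a convention is needed, and the
package deliberately does *not* reuse the likelihood's order. A scheduled
biopsy samples the state the patient *carried into* the year, and the year's
progression step is applied after the year's tests; the delay to a detection
in year `t` is measured to `t - 1`, the year whose state the biopsy sampled.
With the alternative (progress-then-test) order, simulated patients leave
surveillance systematically about one year too early and misclassified
patients carry a spurious 12-month delay offset: the published comparison
table is reproducible only under the test-then-progress order (all 12
biopsy-count cells then agree within +-10% and all 12 delay cells within
+-20%, which is what the acceptance checks verify). The residual
discrepancies absorb whatever finer within-year timing the original
simulation used; the sharpest cell (Toronto parameters under the annual
schedule) sits near the edge of the +-20% band.

`reproduce_table4()` crosses the four packaged cohort parameter sets with
the three distinct schedules. The packaged files carry the published
probability estimates; their exit probabilities and PSA mixtures are
synthetic illustrative values (the fitted ones were not published) and have
no effect on the schedule comparison, which uses only `pi_nfr`, `apr`,
`sens` and `spec`.

An analytic check is available for the annual schedule: without censoring,
the delay in years is geometric on `{0, 1, ...}` with success `sens`, so the
mean delay is `12 (1 - sens) / sens` months (`closed_form_annual_delay()`).

## The synthetic-cohort generator

Real GAP-style surveillance extracts are access-restricted, so
`generate_cohort()` provides the package's test bed: it forward-samples the
model itself (same event order as the likelihood) with an annual observation
grid, a biopsy offer schedule, and non-informative missingness, returning
both the observable cohort and the hidden truth. Defaults are chosen to look
like a surveillance extract: the offer schedule mirrors each cohort's
protocol; offered biopsies are skipped with probability 0.2 and PSA is
missing with probability 0.1 (invented realism knobs); follow-up is censored
at 10 years; exit probabilities default to small non-zero values
(0.02-0.05) so that all three leaving states occur.

What the generator does *not* emulate: informative missingness (sicker
patients skipping biopsies), PSA age-trends or autocorrelation within
patient, covariate-driven progression, or treatment decisions that react to
test results (in real cohorts a positive biopsy usually *causes* the exit;
in the model exits are state-dependent only). Passing parameter-recovery
tests therefore shows that the estimator is correct *under the model's own
assumptions* — a necessary check that says nothing about violations of
those assumptions in real data.

## What the tests compute, and at what scale

The test suite checks, among other things: exact agreement of the
recursions with path enumeration (sequences up to 8 years, tolerance
1e-10); EM monotonicity (slack 1e-8); recovery of each cohort's published
parameter set within three bootstrap standard errors from synthetic cohorts
of 5,000 patients (20 replicate fits per cohort, 20 restarts each; the SE
behind the band is averaged over three independent reference cohorts, a
single B = 25 bootstrap being too noisy to set a stable band);
bootstrap positivity at the Johns Hopkins cohort size (1,428 patients,
B = 100); percentile-interval coverage at a reduced desk scale (50 cohorts
of 400 patients, B = 50); and the full schedule comparison at 10^6
simulated patients per cell so that Monte-Carlo noise is negligible next to
the comparison bands. These sizes are the package's chosen desk scale; all
of them can be raised through the corresponding function arguments.

## Known limitations

* Two hidden states and annual time steps deliberately compress a complex
  disease; the model discriminates exactly the states the cohorts' own
  inclusion criteria define, no more.
* Exit probabilities are observation-independent; modelling
  treatment-seeking as a response to test results is out of scope.
* No covariates (clinical stage, core counts, MRI, PSA density) enter the
  model.
* The bootstrap-t positivity test studentizes with the overall replicate
  SD rather than per-replicate standard errors (a double bootstrap would be
  needed for the latter).
* Cross-cohort formal hypothesis tests (is `apr` in one cohort larger than
  in another?) are not provided; only per-parameter positivity is tested.
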