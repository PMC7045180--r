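---
title: "Modelling the acute stroke thrombolysis pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the acute stroke thrombolysis pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokesim)
```

## The problem

Intravenous thrombolysis (IVT) for ischaemic stroke is licensed only within
4.5 hours of symptom onset, and its benefit decays steeply within that
window.  Whether a patient is treated therefore depends on a chain of
delays: how long the patient (or a bystander) waits before calling for help,
which door they knock on first (general practitioner, emergency number,
self-presentation, or an in-hospital stroke), ambulance response, on-scene
and transport times, and the intrahospital door-to-needle (DTN) interval.
`strokesim` simulates patient trajectories through this chain and evaluates
what-if scenarios — "what if the median patient delay were 15 minutes?",
"what if 60% called 911 directly?" — in terms of IVT utilisation,
onset-to-treatment time (OTT) and derived patient benefit.

## The trajectory model

Each simulated patient draws a referral route from the mix (baseline
46% GP, 30% emergency call, 21% self-referral, 3% in-hospital) and
accumulates route-specific stage delays into an onset-to-door time:

* emergency call: patient delay + responder response + on-scene + transport;
* GP: the same chain plus a GP-consult delay;
* self-referral: patient delay + own transport;
* in-hospital onset: zero.

Treatment requires four conditions: arrival within the `arrival_window`
(240 min — the working interpretation of "arriving in time for acute
treatment"), needle time (door + DTN) within the `treatment_window`
(270 min, the licence limit), no intrinsic contraindication (probability
`p_contra`), and a positive diagnostic work-up (probability
`diagnostic_quality`).  Both windows are configurable; keeping the arrival
gate at 240 min rather than 270 min matters only for patients arriving in
the last half hour of the window and was fixed before any calibration.

Stages are sampled independently: the model deliberately carries no
inter-stage correlation and no capacity constraints or queueing (stroke
patients queue-jump in practice), so it is a pure trajectory model.

## Delay distributions from median/IQR summaries

The only published information about each activity is a median and an IQR.
All delays are positive and right-skewed, so a two-parameter lognormal is
used throughout, fitted in closed form:

* location: `meanlog = log(median)` (the median is matched exactly);
* spread: `sdlog = (log(q3) − log(q1)) / (2·z₀.₇₅)` with `z₀.₇₅ ≈ 0.6745`,
  i.e. the quartiles are matched symmetrically on the log scale.

A degenerate summary yields an explicit point mass, which also represents
"delay eliminated" scenarios.  For log-asymmetric summaries — the
onset-to-call row is 41 (5–130) — no median-anchored two-parameter lognormal
can match both quartile endpoints; the fit preserves the quartile *ratio*
(relative dispersion) exactly and reports the endpoint residuals in the
`fit` attribute (+61% on both endpoints for the onset-to-call row, under 5%
for the near-log-symmetric rows).  The family sits behind a small S3 class
(`duration_dist`), so a heavier-tailed family could be substituted without
touching the rest of the package.

```{r fit}
fit_quantiles(35, 25, 45)   # door-to-needle: lognormal(3.5553, 0.4357)
```

Scenario transformations operate on these objects:
`dd_scale_median()` shifts the log-location (median rescaling, spread and
quartile ratio preserved — used for "reduced to X min" interventions);
`dd_truncate()` imposes a hard cap under which probability mass accumulates
at the cap (used for "no more than X min" rules; a hard cap keeps scenario
effects monotone, unlike rejection resampling); point masses at zero encode
"delay eliminated".

## Calibration

Three parameters are unobserved and are fixed against four published cohort
statistics (IVT rate 21.8%, arrival within 4.5 h 44.6%, treated within
90 min 17.0%, optimised-pathway rate 97.7%):

* `p_contra` is identified analytically: with all delays at zero and perfect
  diagnostics the treatment rate is `1 − p_contra`, so the optimised-pathway
  rate gives `p_contra = 0.023`.
* The GP-consult and self-transport medians (no such rows exist in the
  published summaries; their log-spreads are held at prior shapes, 30
  (15–60) min for the consult and the ambulance-transport shape for
  self-transport) are searched by a coarse log-scale grid followed by
  golden-section refinement per coordinate, minimising the summed squared
  error of the simulated arrival, IVT-rate and band-1 statistics.  Every
  objective evaluation simulates 500 cohorts of 280 patients from a common
  seed (common random numbers), making the search deterministic and smooth.
* `diagnostic_quality` is profiled analytically inside each evaluation: the
  expected rate factorises as `eligible × (1 − p_contra) × quality`.

Keeping `diagnostic_quality` free is a deliberate design choice: with
quality pinned at 1, the emergency-call and in-hospital routes alone already
imply a baseline IVT rate near 24% once the arrival target pulls GP/self
arrivals into the window, so the observed 21.8% is unreachable.  A quality
parameter below 1 is also what the optimised scenario's "diagnostic quality
set to 100%" wording presupposes.  The calibrated baseline lands at a
consult median near 196 min, a self-transport median near 313 min and
quality near 0.55 — long unobserved prehospital delays for the non-EMS
routes, with roughly half of time-eligible patients worked up to treatment.

Two caveats, both visible in the package's own diagnostics:

* **Joint identifiability.**  The two medians trade off along a ridge —
  (125, 320), (150, 250), (175, 200) minutes all reproduce the targets to
  within simulation noise — because the arrival and band-1 statistics
  respond to them almost interchangeably.  `p_contra`, the quality
  parameter and every downstream patient-flow statistic are stable along
  the ridge; the individual medians are not, and the self-calibration test
  asserts exactly that contract.
* **Residual misfit.**  The equal-weight least-squares compromise leaves the
  arrival fraction ≈ 1.5 pp above 44.6% and the band-1 share ≈ 3 pp above
  17.0% while matching the IVT rate exactly; a smooth two-parameter
  lognormal model cannot park enough probability mass just outside the
  eligibility cut-offs to fit all three simultaneously.

## Scenarios

Scenarios are ordered lists of primitive transforms
(`set_median`, `truncate`, `zero_out`, `set_route_share`, `set_dtn_cap`,
`set_quality`, `set_p_contra`) applied to a configuration; composites
concatenate transform lists, and because the built-in composites touch
disjoint fields their composition is order-invariant.  Three readings fixed
where the published wording was open:

* *"DTN reduced to X min"* (scenario family 8) is modelled as a median
  rescale **plus** a hard cap at `2X`: a target-driven hospital protocol
  both shifts typical performance and curbs the long tail.  Pure rescaling
  alone demonstrably under-delivers the published OTT response.
* *Referral-mix shifts* take share from the GP and self-referral routes
  proportionally, holding the in-hospital share fixed (scenario 2B zeroes
  it, giving an all-911 mix).
* *Mobile stroke unit* scenarios eliminate transport (7A) or response +
  transport (7B) only; on-scene time is varied separately (family 6).

Scenario 12 combines everything: every delay a point mass at zero, perfect
diagnostics, so the rate equals `1 − p_contra = 97.7%` and OTT is exactly 0.

## Outcome models

Outcomes are aggregated over replications (default 1000 × 280 patients,
seeded per replication from a master seed): IVT rate and mean treated OTT
with normal-approximation confidence intervals across replications (the
published intervals are far too narrow for a single 280-patient cohort, so
they must be replication-based; the original replication count is unknown
and interval widths are therefore not comparison targets), band shares
pooled over treated patients, and two deterministic benefit models:

* attributable excellent outcome (mRS 0–1): the band-share-weighted mean of
  per-band benefit fractions 1/4.5, 1/9, 1/14.1 — reciprocal
  numbers-needed-to-treat for treatment within (0, 90], (90, 180],
  (180, 270] minutes.  These coefficients reproduce the published mRS
  column to one decimal in 20 of 22 rows (the other two were evidently
  computed from unrounded shares).  Band shares are conditional on
  treatment: the fully optimised scenario prints 22.2% — the first
  coefficient itself — not 22.2% × 97.7%.
* extra healthy-life days: 1.8 days per minute of mean-OTT reduction versus
  baseline (regressing the published extra-days column on the published OTT
  reductions gives 1.79 days/min).

Scenario-versus-baseline rate differences are flagged by Pearson χ² without
continuity correction on the 2×2 table at cohort scale (n = 280 per arm).
The OTT column is a mean over treated patients (configurable; the published
baseline value 129 sits between the observed median 127 and our mean).

## The synthetic cohort generator

`synth_cohort()` emulates the patient-level observational dataset: routes
from the referral mix, route-consistent stage delays, intrahospital
diagnostic times, demographics as marginals, and 46% of onset-to-call times
deleted completely at random (no missingness mechanism was reported; MCAR
is the neutral choice, and the single fitted onset-to-call distribution
serves all patients).  It exists so the fit → calibrate → simulate pipeline
is testable end-to-end without external data.  What it deliberately does
*not* emulate: inter-stage correlation, informative missingness (in reality
unknown-onset strokes are likely the late arrivals), secular trends, or any
re-identifiable detail.  Passing tests on synthetic data therefore validate
the pipeline's internal consistency, not the epidemiology of any real
cohort.

## Numerical choices

* Desk-scale problem sizes, chosen once: 1000 replications × 280 patients
  for reported outcomes (CI half-widths ≈ 0.15 pp on the baseline rate),
  500 × 280 pooled per calibration evaluation, ~170 evaluations per
  calibration.  Distributional tests use 10⁵–10⁶ draws.
* All randomness flows from explicit integer seeds; replications and
  scenarios draw per-unit sub-seeds so runs are bit-reproducible and
  insensitive to how many other units run.
* Band edges are closed on the right; OTT = 0 falls in the first band.
* Degenerate cases are explicit: a zero-treated replication reports `NA`
  OTT and band shares and is dropped from OTT averaging; point masses are a
  first-class family, not a `sdlog → 0` limit.

## Known limitations

The original simulation model was calibrated on patient-level data and its
fitted input distributions were published only in an unavailable
supplement.  Rebuilt from printed medians/IQRs alone, this model matches
the observed baseline (IVT rate, arrival fraction) and the deterministic
outcome algebra, and it reproduces the *direction and ordering* of every
published scenario response — but the *magnitude* of the combined-scenario
responses is muted: smooth median-anchored lognormals place less
probability mass near the eligibility cut-offs than the original inputs
evidently did, and the uniform diagnostic-quality thinning caps zero-delay
scenarios (e.g. patient-delay elimination) well below the published 64%.
The analysis scripts print achieved-versus-published side by side rather
than hiding the gap; closing it would require the original patient-level
delay data, not more tuning.
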