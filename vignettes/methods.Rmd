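---
title: "Methods: scoring, exclusions, moderated regression and simulated power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, exclusions, moderated regression and simulated power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatpower)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It covers the D-score procedure, the exclusion
cascade, the explicit measures, the moderated regression, the power engine,
and the synthetic cohort generator that drives the test suite — including
the places where the design was genuinely open and a choice had to be made.

## The D score

The IAT's behavioural signature is a latency difference between two key
mappings: *rich + good* versus *poor + good*. The improved scoring
algorithm uses the dual-categorization practice blocks (3 and 6, 20 trials)
and critical blocks (4 and 7, 40 trials). `score_iat()` implements the nine
steps literally and in order: trials slower than 10 000 ms are removed
(strictly "exceeding", so a 10 000 ms trial survives); block means of
correct latencies come next; the two pooled SDs are **sample** SDs
(denominator n − 1) over *all* retained trials of a block pair — correct
and error alike — computed *before* error replacement, because the step
list places the SD computation before the replacement step; error latencies
are then replaced by their block's correct mean + 600 ms; the two adjusted
mean differences are divided by their pooled SDs and averaged with equal
weight, regardless of trial counts.

Two consequences deserve emphasis:

* The score is **pairing-role based**, not block-order based. Block order
  is counterbalanced across participants; the sign convention (positive =
  pro-rich) comes from which blocks carried the *poor + good* mapping.
  Swapping the roles negates the score exactly, which the tests assert.
* The score is scale-invariant (multiplying all latencies by a constant
  leaves it unchanged) *only* for error-free data: the 600 ms penalty is
  absolute, so error replacement breaks the invariance deliberately.

There is a genuine ambiguity in whether archived AIID D scores pooled the
SD over correct trials only or over all trials; the step list is followed
literally here (all retained trials). Anyone comparing this package's
scores against archived values should check that convention first.

A related caveat: converting a correct trial to an error raises its block's
adjusted mean only when the trial's latency is at or below roughly the
block mean + 600 ms; for very slow correct trials the replacement value can
be *smaller* than the original latency. The test suite asserts the
monotone sub-case, which is the one that matters for typical latencies.

## The exclusion cascade

Participant-level exclusions run in three phases with a fixed attribution
order and full audit output (`exclusion_cascade()`):

1. **Deduplication** — repeated participant IDs keep only the record with
   the earliest timestamp.
2. **Eight careless-responding criteria**, all evaluated for every
   participant on the trials *as administered* (before the 10 000 ms
   trial removal, which belongs to scoring): fast-response proportions
   (≥35% under 300 ms in any practice block; ≥25% in any critical block;
   ≥10% pooled over critical blocks), error rates (≥50% any practice
   block; ≥40% pooled practice; ≥40% any critical block; ≥30% pooled
   critical), and ≥10% of critical-block responses over 10 000 ms.
   Thresholds are inclusive and compared in exact integer arithmetic
   (`100 * count >= pct * n`), so a participant at exactly 35% is excluded
   and floating-point rounding can never flip a boundary case.
3. **Ordered demographic exclusions** — missing income (including the
   "I don't know" response), then missing education, then missing gender.
   A participant missing several is attributed to the earliest in that
   order.

Which blocks count as "practice" for the criteria is not fully pinned down
by the source procedure: the single-task introductory blocks 1, 2 and 5
could arguably be included. The default maps *practice* to the
dual-categorization practice blocks {3, 6} and *critical* to {4, 7} — the
four blocks the D score uses — and the mapping is a function argument for
anyone who wants the wider reading.

## Explicit measures

Fourteen self-report measures about the rich and the poor are scored from
item-level ratings (`build_measures()`). Separately-rated measures are
rich-minus-poor differences, with multi-item components averaged within
target first (items are randomized subsets, so equal weighting over
whichever items are present is assumed, and `n_items_used` is recorded).
The bipolar others'-evaluations and relative-preference items are
reverse-coded so positive always means pro-rich; polarity is the plain
average of its two items and is the only measure tested against its scale
midpoint (3.5) rather than zero.

The **ambivalence index** for one target is

$$A = \frac{\min(P, N)}{6 + \max(P, N) - \min(P, N)}$$

for 1–6 monopolar positivity (P) and negativity (N) ratings: bounded in
[1/11, 1], symmetric, increasing in the weaker of the two intensities, and
deliberately weighting equally-*high* pairs above equally-low ones. The
analysed quantity is the rich-minus-poor difference of the two indices;
item codes 7 (positive) and 8 (negative) feed the single scored measure,
reported under code 7. Measures 15–18 exist in the item pool but are never
analysed, and the scorer tolerates them silently.

## Moderated regression and simple effects

The omnibus model regresses z-scored D on gender, z-scored income and
education and all their products. Standardization happens once, on the
analysis sample after all exclusions.

**Gender coding is inferred, not given.** The source analyses never state
their contrast. Women = −0.5 / men = +0.5 is the unique coding under which
the printed decomposition is internally consistent: the Gender × Income
coefficient (0.132) equals the men-minus-women difference in income slopes
(0.106 − (−0.026)); the gender coefficient (0.084) equals the gender
difference at mean income; and the education coefficient (0.111) equals
the average of the four printed education simple slopes (0.11125). The
package's pilot-consistency test suite asserts all ten printed simple
effects to ±0.002 under this coding.

Simple effects are computed as linear combinations c′b with se = √(c′Σc)
on the omnibus residual df — algebraically identical to re-centring the
predictors and refitting, which the tests verify to 1e−10. Evaluation
points default to ±1.5 s.d. of the moderator.

**Multicollinearity contingency.** Per-predictor VIFs are the diagonal of
the inverse correlation matrix of the seven non-intercept design columns
(the classical column-wise definition; generalized VIFs for term groups
would blur exactly the per-term diagnostic wanted here). If any exceeds
10, income is residualized on education and the model refit. The source's
description of the orthogonalization direction is self-contradictory
("residuals for income in a model predicting education as a function of
income"); this package residualizes *income on education*, keeping
education's full variance, and flags the refit in the output. At the
realistic r ≈ 0.22 the contingency never fires.

## The power engine

`estimate_power()` draws `n_reps` participant-level datasets, fits the
omnibus OLS once per dataset (QR decomposition; a rank-deficient replicate
is redrawn from a pre-drawn seed pool and counted), evaluates every
registered test two-sided at α (strict `p < alpha`), and reports per-test
proportions with binomial Monte-Carlo standard errors. Per-replicate seeds
are pre-drawn from the master seed, so results are bit-reproducible and
replicates are independent.

Generating parameters default to the study conditions: 115:60 women:men,
observed income–education correlation 0.22, α = 0.05, 1000 replicates,
n = 1000 per dataset at stage 1 and n = 767 (the final confirmatory
sample) at stage 2, and the pilot-derived coefficient vector
`pilot_coef_vector()`.

**Residual SD calibration.** The analyses standardized D, so no error SD
is ever printed. It is instead pinned down by the printed standard errors:
`calibrate_residual_sd()` solves for the σ at which the expected se of the
Gender × Income coefficient at the pilot design (n = 175) equals the
printed 0.055, using the design's expected moment matrix (approximated
once by a large fixed-seed draw, cached per session). The result, σ ≈
0.34 of a standardized-D unit, also reproduces the printed women's (0.032)
and men's (0.044) income-slope standard errors at n = 175, and the test
suite checks that the simulated sampling SD of the Gender × Income
estimate matches 0.055 within 10%.

**Outcome standardization.** Whether the original simulations re-z-scored
the outcome within each replicate is unknown. Two-sided t statistics are
invariant to rescaling the outcome, so power is unaffected either way;
the default is *not* to re-standardize (`standardize_outcome = FALSE`),
which keeps fitted coefficients on the generating scale and lets the
parameter-recovery tests compare them directly. Predictors *are* z-scored
within each replicate, matching the analysis convention; ordinal versus
continuous predictor simulation is likewise configurable
(`sample_standardize_predictors`), with ordinal the default since the
analysed variables are 5-level scales.

`sensitivity()` multiplies one generating coefficient by (1 − shrink)
over a grid, reusing the same replicate seeds at every grid point (common
random numbers), and reports the power curve plus the largest shrink that
keeps power at or above 80%.

## The synthetic cohort generator

`generate_cohort()` produces the three tables the pipeline consumes.
What it emulates:

* the 7-block IAT with counterbalanced pairing order and the two attribute
  word-set conditions in roughly the observed 9:1 split;
* 5-level income and education cut from a latent bivariate normal at the
  pilot marginal frequencies. Discretization attenuates correlation, so
  the latent correlation is inflated by the closed-form first-order
  Hermite factor (λ_income · λ_education ≈ 0.89) to make the *observed*
  correlation hit the configured 0.22; higher-order terms are negligible
  at this magnitude and the tests confirm the observed value by
  simulation;
* group-level D structure: each participant's true D is x′β + ε from the
  pilot coefficient vector, translated into a log-latency shift on the
  incompatible pairing by inverting the lognormal mixture moments
  (`shift_for_d()`), so the scored D tracks the model-implied value;
* careless-responding archetypes (fast-responder, high-error, ultra-slow),
  one per exclusion-criterion family, assigned at a configurable rate;
* missingness of income/education at configurable rates, strictly
  increasing timestamps, and on-request duplicate IDs for the
  deduplication fixtures.

Latencies are lognormal (default location log 700 ms, scale 0.35 log-ms),
truncated below at 150 ms and rounded to integer milliseconds. **These are
conventions, not estimates** — the latency distribution of the archived
data is not described in the source — so trial-level tests establish
algorithmic correctness (oracle equivalence, monotonicity of scored D in
the latency shift, counterbalancing invariance), not distributional
realism. Sequential effects (practice, fatigue), stimulus-word effects and
the identity-IAT arm are deliberately not modelled; passing tests say
nothing about those features of real data.

## Numerical choices and problem sizes

* Exact integer comparison at exclusion thresholds; strict inequality at
  the 10 000 ms scoring cap and for significance (`p < alpha`).
* Degenerate inputs raise classed errors (`iatpower_empty_block_error`,
  `iatpower_degenerate_error`, `iatpower_validation_error`) naming the
  offending block or parameter; a constant vector passed to the one-sample
  test returns t = 0, p = 1 when its mean equals the null value.
* The test suite uses 200 random inputs for D-score oracle equivalence
  (tolerance 1e−12), 120 simulated participants per point on the latency
  calibration curve, 1000 replicates for the power-reproduction and
  test-size checks, and n = 10 000 for parameter recovery — sizes chosen
  to keep each stochastic assertion several Monte-Carlo standard errors
  away from its bound while the whole suite stays quick.

## Known limitations

* The pilot-derived coefficient vector is a *reconstruction* from printed
  simple effects; it matches all printed values to rounding but is not the
  archived estimate itself.
* The calibrated residual SD inherits any approximation error in the
  printed standard errors (two decimal places).
* Explicit-measure generation targets plausible marginal structure only;
  it does not model the item-randomization design of the original pool or
  correlations between measures beyond what the shared participant offsets
  induce.
* The power engine covers OLS with this specific 8-term design; it is not
  a general-purpose power library.
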