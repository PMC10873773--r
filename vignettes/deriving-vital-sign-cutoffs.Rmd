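---
title: "Deriving age-based vital-sign cutoffs for pediatric major trauma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving age-based vital-sign cutoffs for pediatric major trauma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`pedvitals` operates on flat encounter tables: one row per pediatric
(< 18 years) trauma encounter carrying age, the initial post-arrival heart
rate, respiratory rate and systolic blood pressure, the Glasgow Coma Scale
score, the Injury Severity Score (ISS), exclusion flags, and the outcome
components that feed the composite major-trauma definitions. National
trauma registries distribute such tables only under data-use agreements,
so the package pairs the analysis pipeline with a synthetic generator
whose ground truth is known exactly; everything the pipeline estimates on
synthetic data can be checked against what the generator put in.

Eligibility mirrors standard registry practice: encounters with
out-of-hospital cardiac arrest, mechanical ventilation at presentation,
interfacility transfer, or no calculable ISS are excluded, in that order.
The order matters only for bookkeeping — each encounter is attributed to
the *first* rule it trips, so the exclusion ledger's counts add up and a
flow diagram can be reproduced deterministically. Missing vitals do not
exclude an encounter; missingness is handled per analysis
(available-case for single-vital accuracy, complete-vitals for the
any-abnormal and multivariable analyses).

Registries report infant age only as "< 1 year". A fractional age is
recovered from documented weight by inverting the infant arm of the
best-guess weight formula, weight = (months + 9) / 2, clamped into
[0, 11.99] months. The inversion is crude — weight-for-age spread is wide
in infancy — but it is monotone, bounded, and only ever used to place an
infant inside the first year's age bands.

## Vital-sign rule sets

A rule set is a per-vital table of half-open age bands `[age_lo, age_hi)`
with a lower and/or upper limit. Published tables print age *labels*
("1–3 years" followed by "4–6 years") that do not literally partition the
age axis, so the package canonicalizes each table into a contiguous
half-open partition of [0, 18): every boundary age belongs to the band
whose label starts there, and a label gap is closed by extending the
younger band up to the next band's start (a 3.5-year-old resolves to the
"1–3 years" PALS heart-rate band). Limits are inclusive — "100 to 125"
means 100 and 125 are normal — and abnormality is a strict inequality,
matching the "greater than / lower than" phrasing of the one-sided tables.
Values are compared as reals with no pre-rounding. One-sided rules carry
`NA` on the unused side, which can never fire, so an ATLS rule cannot
classify a heart rate as `low` no matter the value.

Three rule sets ship built in: the 2020 PALS normal ranges, the
10th-edition ATLS thresholds, and the empirically derived simplified
table from the 2021 national-registry derivation, each transcribed
verbatim and locked by fixture tests. The printed PALS neonatal
heart-rate band (100–125 below 28 days) is unusually narrow; it is encoded
as printed.

## Age-adjusted z-scores

The z-score model is deliberately a *pluggable parameter table*, not a
fit: per vital, an ordered set of age knots with location, scale and
optional Box–Cox skew, interpolated linearly in age and held constant
beyond the outermost knots (constant extrapolation avoids negative scales
at extreme ages). With zero skew the transform is location–scale; with
skew L it follows the LMS convention `z = ((v/M)^L − 1)/(L·S)`, whose
inverse is exact wherever `1 + L·S·z > 0` (outside that region the inverse
is undefined and the package raises a domain error rather than
extrapolating). Round-trips are exact to 1e-9 relative tolerance by
construction. The published reference distributions behind the original
derivation are not printed anywhere public, so they are not guessed at;
users supply their own table, and the synthetic generator supplies one
with plausible pediatric anchors (heart-rate location falling from ~140
beats/min at birth to ~75 at 17 years, and so on) purely as a coordinate
system.

## Two-sided cutpoint derivation

Because risk is U-shaped in z, the derivation splits observations at the
sample median of z (pooled across ages — the z transform is what makes
pooling meaningful) and runs one one-sided ROC optimization per side:
below the median, flag `z < z_low`; above it, flag `z > z_high`. The
optimality metric is Youden's J, the common default of cutpoint software.
Candidate cutpoints are midpoints between adjacent distinct observed
values plus infinite sentinels, so the optimum is invariant to monotone
relabeling of the gaps; exact ties in J break toward the candidate closest
to the sample median — the least aggressive rule — with the smaller
candidate preferred if still tied. The scan is O(n log n) via cumulative
counts and is tested against an O(n²) brute-force oracle, including tied
data. Degenerate inputs (a side of the median with fewer than two
observations of either outcome class) raise an error naming the side
rather than returning a meaningless cutoff.

Simplification back to practice takes each age band's midpoint as its
representative age, inverts the z transform there, and rounds to the
nearest integer, half away from zero (published tables print integers).
The representative-age and rounding rules are design choices: published
tables do not state how a single number per age group was obtained, and
band-midpoint evaluation is the least surprising option under a
piecewise-linear location curve.

## Composite outcomes

STAT major trauma is the conjunction of two arms: the Cribari matrix
severity criterion, ISS > 15 (the conventional major-trauma threshold,
configurable), and NFTI, an any-of composite whose default criterion set
follows the original NFTI publication — blood product within 4 h, ED to
operating room within 90 min, discharge from ED to interventional
radiology, ≥ 3 ventilator days, ≥ 3 ICU days, or death within 60 h. The
criterion set is configuration, not code, because registry supplements
vary in exactly which components they include; the default is flagged as
provisional. NEI-6 (need for emergent intervention within 6 h) is carried
as an ingested flag — the procedure-code logic that defines it belongs to
the registry, not this package. Missing components conservatively count as
"criterion not met". `stat = cm AND nfti` is enforced structurally and
tested across the full component lattice.

## Accuracy machinery

Confidence intervals use the Wilson score method for proportions
(sensitivity, specificity, predictive values) and the log method for
likelihood ratios; both are stated choices rather than claims about what
any particular publication used. A metric with a zero denominator is
reported `NA` without poisoning the rest of the report. AUROC uses the
rank (Mann–Whitney) formulation with midrank tie correction; paired AUROC
comparison uses DeLong's test (via pROC), with the convention that two
identical predictors compare at p = 1. The three-criteria logistic model
is an ordinary maximum-likelihood GLM on the three abnormality indicators;
with three binary predictors it can produce at most eight distinct risks,
and separation is detected from fitted probabilities numerically at 0 or 1
and surfaced as a warning plus a flag, not an error.

Spline risk curves regress the outcome on a restricted (natural) cubic
spline of z with 4 knots at the 5th/35th/65th/95th percentiles, evaluated
on a grid clipped to the 1st–99th percentile of z — the clipping trades a
little tail coverage for stability where data are sparse. Calibration uses
equal-frequency bins of predicted probability (duplicate quantile breaks
collapse, so a constant predictor yields a single bin equal to prevalence).

## The synthetic registry

The generator emulates the *structure* of a national pediatric trauma
registry sample, not trauma physiology:

* ages piecewise-uniform over [0,5), [5,11), [11,15), [15,18) with equal
  quartile mass, giving median 11 and IQR 5–15 years;
* documentation rates 99.7% (heart rate), 100% (respiratory rate), 91.1%
  (SBP), missing completely at random;
* a latent major-trauma label at 4.6% prevalence;
* per-vital z-scores whose conditional risk follows the configured link.

The default `jump` link makes P(major trauma | z) piecewise constant: a
low interior risk between the jump points (−1.3, +0.85) and a risk
`risk_ratio_at_tail` = 4 times higher outside. This link is the default
because its population Youden optimum provably sits exactly at the jump
points, giving parameter-recovery tests an analytic oracle
(`true_optimal_cutpoints()`). The z draws are implemented as truncated
normal mixtures conditional on the label, calibrated so both the marginal
prevalence and the piecewise-constant conditional risk hold exactly. A
`quadratic` link (logit risk quadratic in z) exists for U-shape and
spline tests, with its intercept calibrated on the realized draw; a
`null` link severs the vitals–outcome dependence entirely.

Outcome components are reverse-engineered from the latent label — STAT
encounters get ISS 16–75 and at least one NFTI component, and
Cribari-only / NFTI-only fringe encounters are added among non-STAT rows
so the composite prevalences land at 9.5% (CM), 14.5% (NFTI) and 17.6%
(NEI-6), preserving the ordering STAT < CM < NFTI < NEI-6. Exclusion-flag
fractions (0.5% cardiac arrest, 1% ventilated, 2% transfers, 1% missing
ISS) are not published quantities; they are plausible round numbers whose
only job is to exercise the exclusion cascade.

What the generator does *not* emulate — correlated missingness,
age-dependent outcome rates, measurement rounding, inter-hospital
variation in interventions, mechanism-of-injury structure — bounds what
passing tests show: the pipeline recovers known structure from data shaped
like a registry; it says nothing about how well any particular cutoff set
triages real children.

## Problem sizes and tolerances

The test suite checks marginal generator targets at n = 200 000 (binomial
3-sigma tolerances: prevalence ±0.002, documentation ±0.005, age median
±0.5), cutpoint recovery at n = 100 000 over 10 seeds (±0.1 on both
cutoffs, ≥ 8/10 seeds, all three vitals), oracle equivalence on 100 random
instances up to n = 500, and U-shape/null spline behavior at n = 80 000.
These sizes put simulation noise well below the assertion tolerances while
keeping the full suite under a minute. The acceptance script runs the
end-to-end pipeline at n = 200 000 plus an independent validation draw of
the same size.

## Known limitations

* The z-score reference table is an input; results are only as meaningful
  as the reference distribution supplied.
* The median split assumes the z distribution is roughly centered; with a
  heavily skewed exposure the two sides can be unbalanced (counts are
  reported so this is visible).
* In-sample AUROC of the fitted three-criteria model carries the usual
  small optimism; validation on an independent sample is the supported
  workflow.
* The NFTI default component set is provisional; match it to your
  registry's supplement via the `criteria` argument before comparing
  prevalences across sources.
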