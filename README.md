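# pedvitals

Age-based vital-sign cutoffs for identifying major trauma in children.

## The problem

Trauma triage in children leans heavily on physiologic criteria, but there
is no consensus on which vital-sign ranges should define "abnormal" for an
injured child. The two guideline systems in wide use pull in opposite
directions: PALS (Pediatric Advanced Life Support) publishes two-sided
normal ranges that flag a large share of injured children, while ATLS
(Advanced Trauma Life Support) publishes single-sided thresholds
(tachycardia, tachypnea, hypotension) that miss bradycardia, bradypnea and
hypertension entirely. An alternative is to *derive* cutoffs empirically:
anchor each vital sign to an age-adjusted z-score, and choose the z
cutoffs that best discriminate a clinically meaningful composite outcome
of major trauma.

`pedvitals` implements that derivation pipeline end to end for
registry-style encounter tables (one row per pediatric trauma encounter),
and ships a synthetic registry generator with known ground truth so the
whole pipeline is testable without access-restricted registry data.

## The method

For an encounter of age `a` with vital value `v`, the age-adjusted z-score
under a reference distribution with location `M(a)`, scale `S(a)` and
optional Box–Cox skew `L(a)` is

```
z = (v − M(a)) / S(a)                      (L = 0, location–scale)
z = ((v / M(a))^L − 1) / (L · S(a))        (L ≠ 0, LMS convention)
```

Because the relation between vital-sign z-scores and major trauma is
U-shaped, a single ROC cutoff cannot capture it. The derivation therefore
splits encounters at the median z and fits one ROC curve per side:

* below the median, find the cutoff `z_low` maximizing Youden's
  J = sensitivity + specificity − 1 for flagging `z < z_low`;
* above the median, find `z_high` for flagging `z > z_high`.

Candidate cutoffs are midpoints between adjacent distinct values; ties
break toward the least extreme candidate. The z cutoffs are then converted
back to integer vital-sign limits within nine practical age groups
(0–3 mo, …, 12–18 y) by inverting the z transform at each band midpoint.

The outcome is STAT (Standard Triage Assessment Tool) major trauma: the
conjunction of the Cribari matrix severity criterion (Injury Severity
Score > 15) and the Need for Trauma Intervention (NFTI) any-of composite
(early transfusion, rapid transfer to the operating room, interventional
radiology, ≥ 3 ICU or ventilator days, death within 60 h). CM, NFTI and
NEI-6 are also available as alternative outcomes.

Rule sets — the built-in PALS/ATLS tables or a derived one — are compared
by sensitivity/specificity/predictive values/likelihood ratios with 95%
confidence intervals, and by the AUROC of a three-criteria logistic model
with DeLong's paired test.

## Worked example

```r
library(pedvitals)

# a synthetic registry at the default study conditions (4.6% major trauma,
# U-shaped risk with jumps at z = -1.3 and +0.85)
reg  <- generate_registry(sim_config(n = 50000), seed = 2024)
kept <- apply_exclusions(reg)
kept$ledger
#>   n_input n_excluded_ohca n_excluded_vent n_excluded_transfer n_excluded_no_iss
#> 1   50000             260             501                 967               466

enc <- add_outcomes(kept$encounters)
rs  <- derive_ruleset(enc, sim_dist_table())
tidy(rs)
#>   vital      z_low z_high median_z n_below n_above youden_low youden_high
#> 1 heart_rate -1.30  0.850 -0.00225   23831   23830      0.288       0.362
#> 2 resp_rate  -1.30  0.851  0.00289   23903   23903      0.287       0.376
#> 3 sbp        -1.30  0.850 -0.00108   21841   21840      0.326       0.330
```

The derived z cutoffs sit on the generator's true jump points (−1.3,
+0.85) to within ±0.01. `rs` is itself a rule set, directly usable for
classification, with integer limits per age band (e.g. heart rate 96–132
beats/min at 1 to <3 years under the generator's reference table):

```r
evaluate_ruleset(enc, rs)[, c("criterion", "sens", "spec", "plr", "nlr")]
#>   criterion     sens  spec   plr   nlr
#> 1 heart_rate   0.585 0.705  1.99 0.589
#> 2 resp_rate    0.563 0.721  2.02 0.606
#> 3 sbp          0.577 0.716  2.03 0.590
#> 4 any_abnormal 0.923 0.366  1.46 0.210
```

Each row is an available-case analysis for that vital; `any_abnormal`
(at least one abnormal vital) is computed on the complete-vitals subset.
The high negative predictive value and the sensitivity/specificity trade
mirror what such criteria show on real registry data. `autoplot()` methods
exist for rule sets, spline risk curves (`spline_risk_curve()`) and
calibration tables (`calibration_bins()`).

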