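# grsrecal

Does adding a polygenic risk score to an already-validated absolute risk
model actually help? `grsrecal` implements the full evaluation pipeline for
that question in the setting of colorectal-cancer (CRC) risk prediction: it
builds a weighted genetic risk score (GRS) from published SNP weights,
applies two shapes of validated base model (an age-rate x family-history
relative-risk model, and a published Cox model), recalibrates the combined
models with flexible parametric survival models, and measures what the GRS
changes — discrimination, calibration, and each participant's predicted
5-year risk.

The package is aimed at biostatisticians and genetic epidemiologists
evaluating risk-stratified screening. Because cohort data of the required
scale are access-controlled, `grsrecal` ships a first-class synthetic-cohort
generator with the statistical structure the analysis assumes (Hardy-
Weinberg genotypes at 41 SNPs, lifestyle covariates, family history weakly
and positively linked to the GRS, Weibull proportional-hazards event times,
independent censoring, sibling pairs, and optional winner's-curse inflation
of the "published" SNP weights), so every stage is testable end to end.

## The models

**GRS.** For participant *i* with allele dosages *g<sub>ij</sub>* and
published per-SNP log odds ratios *w<sub>j</sub>*,

&nbsp;&nbsp;GRS<sub>i</sub> = Σ<sub>j</sub> w<sub>j</sub> g<sub>ij</sub>,

mean-centred and kept on the natural log scale.

**Base models.** The family-history model combines age-specific incidence
rates λ₀(a) with relative risks RR<sub>fh</sub>:
risk = 1 − exp(−RR<sub>fh</sub> ∫ λ₀(a) da) over the horizon. The Cox-style
model is risk = 1 − S₀(5)<sup>exp(η)</sup> with η = Σ β<sub>k</sub>
x<sub>k</sub> from a published coefficient table (sex-masked terms, e.g.
oestrogen use, contribute 0 where not applicable).

**Recalibration.** A flexible parametric (Royston–Parmar) survival model on
the log cumulative hazard scale,

&nbsp;&nbsp;log H(t | x) = s(log t; γ) + x′β,

with *s* a restricted cubic spline (2 df by default). Initial calibration
enters the base model's log hazard ratio as an offset (calibration-in-the-
large); recalibration estimates free slopes on the base log HR and the GRS
as separate covariates. A slope of 1 means the predictor's relative risks
hold in this cohort; a slope near 1/κ is the signature of weights inflated
κ-fold by the winner's curse.

**Evaluation.** Harrell's C for censored data, decile calibration against
Kaplan–Meier observed probabilities, relative-risk calibration curves
(estimated vs model-predicted hazard ratio), and the proportion of
participants whose predicted 5-year risk changes by ±0.3 percentage points
or more — overall and among those starting at ≥1% risk. A KING-style robust
kinship estimator and greedy relatedness filter (threshold 0.08) support
the related-participants sensitivity analysis.

## Worked example

Simulate a cohort of 20,000 participants whose published SNP weights are
inflated 1.6-fold relative to the data-generating weights, then run the
whole pipeline:

```r
library(grsrecal)
cfg <- pipeline_config(
  simulate = simulation_config(20000, seed = 42, inflation_factor = 1.6),
  seed = 42
)
report <- run_pipeline(cfg)
report
#> Concordance:
#> # A tibble: 4 × 4
#>   model            c_statistic conf_low conf_high
#> 1 base                   0.665    0.627     0.703
#> 2 grs_alone              0.648    0.610     0.687
#> 3 augmented              0.721    0.688     0.755
#> 4 base_age_removed       0.611    0.573     0.648
#>
#> Calibration slopes:
#>   model     term        estimate std_error conf_low conf_high
#> 1 base      base_log_hr    1.05     0.132     0.790     1.31
#> 2 augmented base_log_hr    1.02     0.130     0.768     1.28
#> 3 augmented grs            0.645    0.0913    0.466     0.824
#>
#> Change in predicted risk:
#>       n threshold prop_exceeding n_high_risk high_risk_cutoff
#> 1 20000     0.003          0.264        2912             0.01
```

Reading the output: the base model's own slope is compatible with 1 (it is
well calibrated here by construction), while the GRS slope of 0.645
(CI 0.47–0.82) recovers 1/κ = 0.625 — the inflated weights imply relative
risks about 1.6× too extreme on the log scale, exactly what free-slope
recalibration corrects. Plots come from `autoplot()` on
`report$calibration$augmented`, `report$rr_curve_grs` and `report$delta`;
`tidy()`/`glance()` work on the fitted models.

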