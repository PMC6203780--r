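---
title: "Adding a genetic risk score to validated absolute risk models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adding a genetic risk score to validated absolute risk models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`grsrecal` evaluates whether a weighted genetic risk score (GRS) adds
predictive value to validated absolute-risk models for colorectal cancer.
This vignette is the package's own account of the statistical machinery:
the models, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-cohort generator does and does not emulate,
and the numerical and design choices made where the methodology left them
open.

## The question and the procedure

A validated risk model produces, for each participant, a log relative
hazard $\eta_i$ and an absolute risk over a horizon (here 5 years). A GRS
$G_i = \sum_j w_j g_{ij}$ — allele dosages weighted by published per-SNP
log odds ratios, then mean-centred — is a candidate additional predictor.
The pipeline asks three things:

1. **Discrimination**: does the GRS, alone or added to the base model,
   raise Harrell's C?
2. **Calibration**: are the predicted probabilities and predicted relative
   risks observed at face value, before and after adding the GRS?
3. **Individual impact**: for how many participants does the predicted
   5-year risk change by a clinically visible margin (default 0.3
   percentage points), overall and among those starting at or above 1%?

Because SNP weights are selected for genome-wide significance, they tend
to overestimate the underlying effects (the winner's curse / significance
filter). A GRS built from such weights implies relative risks that are too
extreme, which surfaces as a calibration slope below 1 and an inflated top
decile of predicted risk. Recalibration is therefore central, not optional.

## The flexible parametric survival engine

Both recalibration and relative-risk calibration use a Royston–Parmar
flexible parametric survival model:

$$\log H(t \mid x) = s(\log t;\ \gamma) + x'\beta,$$

where $s$ is a restricted cubic spline (Durrleman–Simon basis: first
column $\log t$ itself, each interior knot contributing one cubic term,
the function constrained linear beyond the boundary knots and $C^2$
everywhere). With `df = 1` the family is exactly Weibull, with
$\gamma_0 = -k \log \lambda$ and $\gamma_1 = k$ for shape $k$ and scale
$\lambda$ — a closed-form anchor the test suite exploits.

The log likelihood for right-censored data,
$$\ell = \sum_i \delta_i\!\left[\log s'(\log t_i) - \log t_i + u_i\right] - e^{u_i},
\qquad u_i = s(\log t_i) + \eta_i,$$
is maximised by BFGS with the analytic gradient, started from a Weibull
(`survreg`) fit zero-padded to the spline dimension, then polished with
damped Newton steps until the gradient norm is below $10^{-6}$. Standard
errors come from the inverse observed information (numeric Hessian at the
optimum).

Choices the methodology leaves open, and what this package does:

* **Knots.** Boundary knots at the extremes of the uncensored log event
  times, interior knots at their quantiles (the median for `df = 2`). This
  is the standard Royston–Parmar convention; only the degrees of freedom
  (default 2) are treated as the user-facing parameter.
* **Monotonicity of $s$.** Not enforced during optimisation. After
  fitting, $s'$ is checked on a 200-point grid over the observed log-time
  range; a violation triggers a warning and a penalised refit. At `df = 2`
  with event counts in the hundreds the unconstrained fit is essentially
  always monotone.
* **Time scale.** Analyses run on follow-up time with baseline age as a
  covariate, not on attained age with delayed entry. This is simpler, is
  sufficient to exercise every operation, and matches the synthetic
  generator; it is a documented limitation, not a claim about how any
  particular cohort analysis handled entry times.
* **Degenerate inputs.** No events, fewer than `df + p + 2` events,
  non-positive times, or identical event times (no room for knots) are
  errors with named messages, not silent coercions.

## Initial calibration and recalibration

Two modes, used in sequence:

* `initial_calibration()` — *calibration-in-the-large*: the base model's
  log relative hazard enters as an **offset** (coefficient fixed at 1) and
  only the baseline spline is re-estimated. The participant ordering is
  untouched; the cohort's incidence level is absorbed. The exact recipe a
  published analysis used for this step is typically unavailable, so
  offset mode is the documented default and free-slope mode is available
  through `fit_fpsm()` directly.
* `recalibrate_with_grs()` — free slopes on the base log hazard ratio and
  the mean-centred GRS as **separate covariates**, sharing one knot
  specification so the base-only and augmented fits are comparable. The
  slope on a predictor is its calibration slope: 1 is ideal; under
  $\kappa$-fold multiplicative weight inflation the GRS slope converges to
  $1/\kappa$. Five-year risks are predicted from both fits, and
  `delta_risk_summary()` reports $\Pr(|\Delta| \ge 0.003)$ with ties
  counting as exceeding, overall and in the initial-risk $\ge 0.01$
  subgroup.

A GRS column with zero variance is dropped from the augmented fit (slope
reported `NA`, augmented risks equal base risks); two non-constant
covariates with $|r| > 0.999$ are a collinearity error.

## Evaluation components

* **Harrell's C** via `survival::concordance` (comparable pairs require
  the earlier, distinct time to be an event; score ties credit 0.5;
  asymptotic variance for the interval). The test suite checks it against
  an $O(n^2)$ brute-force pair enumeration.
* **Decile calibration**: participants ranked by predicted risk, ties
  broken by stable input order, ten equal-count groups; observed
  probability is the Kaplan–Meier estimate at the horizon with a
  Greenwood-based interval on the $\log(-\log)$ scale.
* **Relative-risk calibration**: an FPSM with a restricted cubic spline
  (default 2 df) of the predicted log hazard ratio as covariates; the
  fitted hazard ratio is evaluated on a grid **relative to the cohort-mean
  predicted log HR**, so the curve passes through HR = 1 at the cohort
  average by construction. Pointwise intervals use the delta method on the
  covariate block of the covariance. A constant predictor is rejected.
* **Relatedness**: a robust between-family kinship estimator based on
  heterozygote concordance and opposite-homozygote counts,
  $\hat\varphi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa}^{(i)} + N_{Aa}^{(j)})$,
  expected 0.5 / 0.25 / 0.125 / 0 for duplicates, full siblings,
  second-degree relatives and unrelated pairs. Filtering is greedy and
  randomized — pairs above the 0.08 threshold are visited in random order
  and one member dropped at random — matching a "randomly drop one member"
  sensitivity analysis rather than any maximum-independent-set
  optimisation. The 41 GRS SNPs are far too few for kinship; an auxiliary
  panel of several thousand SNPs is used.

## The synthetic cohort: what it emulates, and what it does not

`simulation_config()` / `generate_cohort()` produce cohorts with the
structure the analysis assumes:

| Parameter | Default | Why |
|---|---|---|
| `n_snps` | 41 | the published GRS panel size |
| `allele_freqs` | seeded draws on (0.1, 0.9) | common variants, no rare-variant tail |
| `true_log_ors` | scaled so theoretical GRS SD = 0.495 | matches the reported mean-centred GRS spread |
| `inflation_factor` $\kappa$ | 1 | published weight = $\kappa \times$ true weight; 1.6 in winner's-curse experiments |
| `grs_hazard_scale` | 1 | coefficient on the true-weight GRS in the hazard; 0 gives a truly null GRS with nonzero published weights |
| `baseline_shape`, `baseline_scale` | 1.2, 500 years | Weibull baseline giving roughly a 0.4% five-year event probability at the reference profile, a realistic CRC incidence for ages 40–69 |
| `covariate_effects` | modest log HRs (age 0.06/yr, family history 0.55/0.90, ...) | effect sizes of the order reported for CRC risk factors |
| `fh_grs_association` | 0.3 | weak positive ordinal-logit link between GRS and family-history category |
| `censor_horizon`, `dropout_rate` | 7 years, 0.005/yr | administrative censoring after ~7 years of follow-up with light dropout |
| `n_sibling_pairs` | 0 | sibling pairs by Mendelian transmission from simulated parents (expected kinship 0.25) |

Event times invert the Weibull cumulative hazard in closed form,
$T = \lambda (E / e^{\mathrm{lp}})^{1/k}$ with $E \sim \mathrm{Exp}(1)$;
the observed time is the minimum of event, dropout and horizon. A single
seed drives every draw through derived sub-seeds, so cohorts are
bit-reproducible.

What the generator deliberately does **not** emulate: linkage
disequilibrium between SNPs, genotyping or imputation error, population
structure, attained-age hazard scales with delayed entry, non-proportional
hazards, and competing mortality. Passing tests therefore demonstrate that
the pipeline's estimators recover what they should under the assumed
structure — slope $1/\kappa$ under inflation, coverage of well-specified
decile calibration, kinship expectations — not that any real cohort
satisfies that structure.

The family-history link deserves one note: the link is ordinal-logit in
the GRS. At the default weak association (0.3) the top family-history
category (~1% prevalence) is too small for its mean GRS to clear sampling
noise even at $n = 50{,}000$, so the monotonicity property is exercised in
tests at a stronger coefficient (1.5); the default stays weak because that
is the realistic regime.

## Base models and their file formats

The two base-model shapes are declared, not re-estimated:

* the family-history absolute-risk model as an age-rate table (half-open
  bands $[a_\ell, a_u)$, exact piecewise integration over the horizon —
  no midpoint approximation) times a family-history relative risk, with no
  competing-mortality adjustment;
* the Cox-style model as a YAML term table (linear terms with reference
  values, indicator terms, per-term sex masks) plus the baseline survival
  $S_0(5)$.

The coefficient values of any real published model live in supplementary
material not reproduced here; the shipped files under `inst/extdata/` are
clearly-labelled synthetic fixtures with plausible magnitudes, and users
supply their own tables for a real analysis. `remove_covariate_effect()`
supports the age-removed discrimination analysis: for the Cox shape it
zeroes the named coefficients; for the family-history shape it freezes the
baseline at a reference age so only the family-history relative risk
separates participants.

Missing dosages are an error by default; the optional policy imputes twice
the effect-allele frequency and records which SNPs were touched. Allele
alignment flips dosages ($g \mapsto 2-g$) where the cohort counts the
other allele and flags strand-ambiguous (A/T, C/G) SNPs for the user
instead of auto-resolving them, because a silent strand error flips the
sign of a SNP's contribution.

## Problem sizes and tolerances

The test suite and the acceptance script run on simulated cohorts sized so
each check is informative but quick: $n = 2{,}000$ for the Weibull
equivalence of the `df = 1` model (log-likelihood within $10^{-4}$
relative of an independent closed-form Weibull MLE), $n = 50{,}000$ with
roughly 500 events for slope recovery (assertions at 3 standard errors),
$n = 100{,}000$ for decile-calibration coverage, 500 sibling pairs at
5,000 auxiliary SNPs for kinship (tolerance 0.02), and 20 datasets of
$n = 500$ for the brute-force concordance comparison at $10^{-12}$.
Exact worked examples (the Kaplan–Meier product-limit table, the GRS hand
arithmetic, the closed-form absolute-risk values) are asserted at machine
precision.

## Known limitations

* Follow-up-time scale with baseline age as covariate; no delayed entry.
* No time-varying effects, frailty, interval censoring, or competing
  risks in the survival engine.
* No LD-aware PRS methods — the GRS is the fixed published-weight linear
  score by design.
* Greedy relatedness filtering does not maximise the retained sample.
* The synthetic generator's independence assumptions (SNPs, censoring)
  are idealisations; see above for what passing tests do and do not show.
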