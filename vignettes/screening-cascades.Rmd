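---
title: "Simulating and costing diabetes screening cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and costing diabetes screening cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

`dmscreen` evaluates risk-based diabetes screening strategies end to end:
who gets flagged, who gets a confirmatory test, what it costs, and what the
missed cases may later cost. This vignette is the package's account of the
models and the design choices behind them.

## The synthetic cohort model

Real screening cohorts with paired fasting (FPG) and post-load (2hPG)
glucose are rarely shareable, so the package ships a generator whose
defaults encode the population facts the analysis depends on: diabetes
prevalence near 12.4%, and a diabetic stratum splitting roughly 41% / 28% /
31% into isolated post-load, isolated fasting, and combined hyperglycemia.
That discordance between the two analytes — not any single marginal — is
what makes the screening problem interesting, because FPG-only screening
structurally misses the isolated post-load group.

One standard-normal latent risk $z$ per person drives everything:

* **Non-laboratory features** are linear in $z$: $x_f = m_f + \lambda_f z +
  \varepsilon_f$, with $m_f$ the published non-diabetic median,
  $\varepsilon_f$ Gaussian with SD = IQR/1.349, and the loading $\lambda_f$
  chosen as (diabetic median − non-diabetic median) divided by the model's
  latent gap $E[z\,|\,\text{DM}] - E[z\,|\,\text{non-DM}] \approx 0.90$.
  Units are natural (years, mmHg, bpm, kg, cm). BMI, waist-to-hip and
  waist-to-height ratios are derived row-wise from weight, height, waist
  and hip, so the anthropometric identities hold exactly. A handful of
  weakly- or non-informative pseudo-features (work status, education,
  sleep duration, cellphone years) keep feature ranking honest: top-k
  selection has something real to discard.
* **Glucose** is bivariate log-normal conditional on $z$:
  $\log \text{FPG} = \mu_F + b_F z + s_F e_1$, $\log \text{2hPG} = \mu_P +
  b_P z + s_P e_2$ with $\operatorname{cor}(e_1, e_2) = \rho$. Diabetes
  status and subtype then *emerge* from the diagnostic thresholds rather
  than being sampled directly, which keeps labs, labels and subtypes
  mutually consistent by construction.
* **HbA1c** is linear in FPG and 2hPG plus Gaussian noise, truncated at
  3.5%. It is only ever a screening lab here, never an outcome, so a
  regression model is sufficient.

**Calibration is analytic.** Marginally, $\log \text{FPG}$ is normal with
total SD $\sigma_F = \sqrt{b_F^2 + s_F^2}$ (similarly $\sigma_P$), and the
total correlation is $(b_F b_P + \rho s_F s_P)/(\sigma_F \sigma_P)$. Given
a target prevalence $p$ and subtype fractions $(f_{pl}, f_{fa}, f_{co})$,
the marginal exceedances are forced: $P(\text{FPG} \ge 7) = p(f_{fa} +
f_{co})$ and $P(\text{2hPG} \ge 11.1) = p(f_{pl} + f_{co})$, which fix
$\mu_F$ and $\mu_P$ in closed form; the joint exceedance $p f_{co}$ then
determines the total correlation by a one-dimensional root-find on the
bivariate-normal upper tail (computed by quadrature). The solution is
verified on a seeded 50,000-person sample with tolerances ±0.01 on
prevalence and ±0.03 on each subtype fraction; infeasible targets (e.g. a
combined fraction requiring a residual correlation outside (−1, 1)) fail
loudly with the achieved-versus-target numbers. The shipped defaults are
the calibrated solution for the targets above.

**What the generator does not emulate.** Missingness is MCAR only (the
generator's job is to exercise the imputation plumbing, not to model survey
nonresponse); features are conditionally independent given one latent
factor, so real multi-factor correlation structure (age–blood-pressure
beyond risk, sex-specific anthropometry) is absent; there is no
measurement-repeat variability in the labs. Consequently, passing tests
show the *machinery* is correct under realistic prevalence and discordance
— they do not certify classifier AUCs or cost savings on any real
population, and the headline real-cohort metrics of screening studies are
out of reach by design.

## Diagnosis, subtypes, cascades

Diabetes is FPG ≥ 7.0 mmol/L or 2hPG ≥ 11.1 mmol/L. One threshold per
analyte governs both the diagnostic and the "seemingly normal" role;
sources differ on whether the post-load boundary for seemingly normal is
11.0 or 11.1, and using a single 11.1 threshold avoids an undefined
11.0–11.1 gap. Both thresholds (and the 6.5% HbA1c screen boundary, which
is not diagnostic here) are configurable.

A cascade walks each person through (a) the screening lab, if any — a
diagnostic result ends the trail as a detection; (b) the risk model —
screen-negatives stop; (c) the confirmatory test for screen-positives. The
confirmatory test never repeats the already-measured analyte: the
model-only and HbA1c cascades confirm with a full OGTT, the FPG cascade
with 2hPG alone, the 2hPG cascade with FPG alone. This is a design choice
(flow diagrams in the literature leave the content of "confirmatory test"
graphical), and it is the cheaper reading; users who prefer a full OGTT
after an FPG screen can price it via the cost schedule.

Confusion outcomes are *prediction versus truth*: flagged (screen-lab
diagnostic or model-positive) non-diabetics are false positives — they pay
for a confirmatory test that finds nothing. Flagged diabetics are always
confirmed, because the confirmatory test measures exactly the analyte(s)
their diagnosis rests on; false negatives are therefore the unflagged
diabetics under every cascade, which is what the complication-cost
calculation needs. A separate `detected` field records whether a
diagnostic-range result actually appeared in the person's trail.

## Risk models

Questionnaire scores are binned-points tables (`score_table`): half-open
numeric intervals or category sets mapping to non-negative integer points,
summed and compared to a cutoff. The published NCDRS/ADART point values are
not reproduced here; the shipped JSON files carry placeholder points with
the published cutoffs (25 and 5) and exist to define the schema.

Trainable models share one surface across seven learner kinds. Fixed,
deliberately unexciting hyperparameters (overridable via `params`) replace
any automated search: boosted trees use 150 rounds at depth 4, learning
rate 0.1, no subsampling (keeping fits bit-deterministic); the SVM uses a
radial kernel with Platt probabilities; kNN uses k = 25 (odd, to avoid vote
ties); the neural net one hidden layer of 8 units with weight decay 0.01.
The centroid-displacement kNN variant classifies by how little a class
centroid moves when the query joins it — displacement
$\lVert x - \mu_c\rVert/(n_c + 1)$ — with a logistic link fitted on the
displacement difference to produce probabilities. Inputs are standardized
on development-set statistics for the distance- and gradient-based
learners; trees see raw features.

Cross-validation partitions the development set into 5 near-equal seeded
folds; pooled AUC/auPR are computed on out-of-fold predictions, CIs by
stratified bootstrap. Streamlining ranks features by mean absolute additive
contribution (boosted trees: the backend's own per-prediction
contributions; logistic: the exact linear decomposition; other learners:
label-free permutation reliance), then picks the smallest k ∈ {5, 10, 15,
20, 25} whose cross-validated AUC is within 0.005 of the best — studies
that pick "best power with fewest features" rarely state a rule, and an
explicit tolerance makes the choice testable.

Per-feature contributions $\phi_f$ live on the log-odds scale with
$\text{base} + \sum_f \phi_f$ equal to the model's log-odds output —
exactly for the logistic decomposition, and to about $10^{-5}$ for the
tree backend, which computes contributions in single precision. The
relative risk of a feature's observed value is
$\operatorname{sigmoid}(\text{base} + \phi_f) /
\operatorname{sigmoid}(\text{base})$: above 1 exactly when the
contribution is positive. The conversion is a declared definition (the
literature converts Shapley values to relative risks without printing a
formula); any monotone alternative would preserve the sign property that
the tests pin down.

Imputation is iterative regression (initialized at development-set medians
or modes, refined by per-column linear models over three sweeps), fitted on
the development set only and applied frozen to the testing set — testing
values can never influence an imputed cell. Columns with ≥ 20% missing
development cells are dropped with a warning rather than imputed.
Integer-coded categoricals stay at their development mode: regressing them
would produce fractional categories that break downstream binning.

## Economics

Defaults are published Chinese prices (CNY): medical 9.89 / 23.56 / 33.45 /
84.16 and non-medical 8.3 / 27.5 / 27.5 / 8.3 for FPG / 2hPG / OGTT /
HbA1c, and per-diabetic-per-year complication bounds 341–567 (5 y) up to
5258–9132 (25 y). Detection cost sums every test actually performed on a
trail; screening-lab-diagnosed persons incur no confirmatory cost. No
discounting is applied to future complication costs — the source prints
per-year ranges without a discount rate, and adding one would be a modeling
claim the data cannot support. One residual worth knowing: the same
source's printed cost-per-proportion pairs imply an OGTT unit price about
1% below its own price list (likely independent rounding); this package
follows the price list. Costs are kept at full precision internally and
only rounded (to centi-CNY) in printed reports.

## Metrics and matched comparison

AUC is the Mann–Whitney pair statistic with ties counted one half. auPR is
the step-wise (non-interpolated) summation over tied-score blocks — linear
PR interpolation is known to flatter classifiers, and the step-wise form
makes a constant classifier score exactly the prevalence. Confidence
intervals are stratified percentile bootstrap with B = 2000 by default (the
method behind published interval forms is typically unstated;
bootstrapping is assumption-light and seeded here). The DeLong test uses
the placement-value covariance estimator; identical or rank-identical score
pairs short-circuit to z = 0, p = 1 rather than dividing zero by zero.

Matched comparison sweeps both strategies over *all observed score
cutpoints* — the cost-versus-threshold curve is a step function, so grid
search over cutpoints is exact where root-finding would interpolate. At
matched sensitivity the smallest qualifying positive set is chosen (largest
threshold, hence best specificity); at matched cost, the most sensitive
affordable operating point. Relative reductions $(a - b)/a$ are computed
from unrounded values. The default grid is 21 evenly spaced matched values
over the strategies' common attainable range.

## Problem sizes and numerical choices

The test suite runs cohorts of 2,000–50,000 (50,000 where subtype
fractions are asserted, mirroring the calibration contract), 500 small
datasets for the exhaustive AUC oracle, 500 + 100 replicates at n = 200
for DeLong null uniformity and power, and a 20,000-person cohort for the
cost-dominance property; these sizes put Monte-Carlo error well inside the
asserted tolerances. All randomness flows through explicit integer seeds
(`withr::with_seed`), so every table in `results/` is byte-reproducible.
Degenerate inputs are contracts, not afterthoughts: empty populations,
single-class outcomes, zero-denominator metrics, unpriced tests and unknown
horizons all raise named errors rather than returning silent zeros.

## Known limitations

The generator's single-factor structure caps how interestingly nonlinear
the learning problem can be — on such data logistic regression is often the
bake-off winner, which is itself a useful reminder that boosted trees earn
their keep only on richer feature interactions. Placeholder questionnaire
points mean score-table operating characteristics on synthetic cohorts do
not transfer to the published instruments. And all cost conclusions inherit
the price schedule: different test prices or complication estimates can
reorder strategies, which is why every price is configuration, not code.
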