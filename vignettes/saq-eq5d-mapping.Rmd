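---
title: "Mapping the SAQ to EQ-5D-5L utilities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the SAQ to EQ-5D-5L utilities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saqmap)
```

## The mapping problem

Cost-utility analysis needs health utilities, but trials in coronary
heart disease typically administer only the Seattle Angina
Questionnaire (SAQ), a 19-item disease-specific instrument with five
subscales — physical limitation (PL), anginal stability (AS), anginal
frequency (AF), treatment satisfaction (TS) and disease perception
(DP) — each scored 0–100 (higher = better). A *mapping* (crosswalk)
model converts those subscale scores into EQ-5D-5L utilities, i.e.
values on the scale of a country-specific tariff applied to the five
EQ-5D dimensions (mobility, self-care, usual activities,
pain/discomfort, anxiety/depression; five ordinal levels each).

`saqmap` implements both families of mapping models:

* **direct**: regress the utility on the subscale scores;
* **indirect (response mapping)**: model each EQ-5D dimension's level
  probabilities from the subscales, then convert predicted
  probabilities to a utility through the tariff.

Throughout, the design matrix holds the five subscales divided by 100
(so each covariate spans [0, 1] and a coefficient is the utility change
over the subscale's full range), in the fixed order PL, AS, AF, TS, DP.
This 0–1 scaling reproduces exactly the arithmetic identities linking
the bundled published coefficient tables, the cohort's mean subscale
profile and the printed mean predictions (checked in the test suite),
which is why we adopted it over the alternative reading of the
tables' "score multiplied by 100" footnote.

## Value-set scoring

An EQ-5D-5L value set is additive:
$$U(s) = 1 - \sum_{d} \delta_d(\mathrm{level}_d), \qquad \delta_d(1)=0 .$$
The bundled `"china-5L"` tariff spans −0.391 to 1; both endpoints are
enforced as load-time integrity checks, along with non-negativity and
monotonicity of the decrements. The mid-level decrements are bundled
from the Chinese valuation study and can be replaced by any constants
file (`dimension, level, decrement`) — all code paths take the value
set as an argument. Utilities are kept at full floating precision and
rounded only in printed reports.

## Direct estimators

Utilities pile up at 1 (here roughly 31% of records), are left-skewed,
and are bounded — the motivation for estimators beyond OLS:

* **OLS** — closed-form least squares; its in-sample mean prediction
  equals the observed mean.
* **Log-link Gaussian GLM** — handles skewness;
  $\hat y = \exp(x'\beta)$. Note the Jensen gap: the prediction at the
  covariate means is below the mean of predictions.
* **Tobit** — right-censored Gaussian MLE: observations at 1 contribute
  $1-\Phi((1-x'\beta)/\sigma)$. Fitted through the censored Gaussian
  AFT machinery of `survival::survreg`. Predictions are reported as the
  latent index $x'\beta$, the convention that matches published mapping
  tables whose Tobit maxima exceed 1.
* **CLAD** — Powell's censored least absolute deviations
  $\min_\beta \sum_i |y_i - \min(x_i'\beta, 1)|$, by alternating median
  regression on the active subsample (fitted index < 1) with active-set
  recomputation, keeping the best objective if the active set cycles.
  The inner L1 fit uses IRLS with a Nelder–Mead polish on the exact
  objective. Standard errors via nonparametric bootstrap (199
  resamples by default; disable with `se = "none"` inside
  cross-validation loops).
* **RMM** — MM robust regression: high-breakdown S-estimate of scale
  followed by a Tukey-bisquare M-step at 95% Gaussian efficiency
  (`MASS::rlm(method = "MM")`, tuning constant 4.685), with the S-step
  subsampling seeded for reproducibility.

## Boundary-aware mixture estimators

**ALDVMM.** Utilities live in $[\mathrm{floor}, \Psi] \cup \{1\}$,
where $\Psi$ is the largest feasible utility below 1 — there is a gap
between 1 and the next attainable value. Within component $k$ (mean
$x'\beta_k$, scale $\sigma_k$), mass above $\Psi$ maps to 1, mass below
the floor maps to the floor, and the interior keeps the normal density.
Membership is multinomial-logit (intercept-only by default; the
published tables show no membership coefficients, so covariates in the
membership model are not defaulted). The likelihood is maximised by
BFGS from multiple random starts (20 by default, seeds derived from one
master seed), components relabelled by increasing intercept. The
default $\Psi$ is computed from the active value set as 1 minus the
smallest single-level decrement (0.954 for the bundled tariff), since
published analyses rarely state their $\Psi$; it is configurable. The
floor mass is retained for generality but is inert on cohorts whose
minimum utility is far above the floor. Expected-value predictions
combine the boundary masses with truncated-normal interior means and
therefore always lie in $[\mathrm{floor}, 1]$.

**One-inflated beta mixture.** A two-part model: a logistic regression
for $P(y = 1)$, and, conditional on $y < 1$, a C-component beta mixture
on $y^* = (y - L)/(U - L)$ with logit-linked means and constant
precisions. The two parts are estimated separately (their likelihoods
are additively separable), the ceiling part by exact logistic MLE and
the beta part by multi-start BFGS. Defaults: $C = 1$ with an inflation
part (matching the single published mean-link column), bounds equal to
the tariff range — the rescaling bounds actually used in published runs
are typically unstated, so they are arguments. Rescaled zeros are
nudged to $0.5/n$ (standard beta-regression practice); $y = 1$ is never
nudged — it belongs to the logistic part.

Numerical choices shared by both: log-scale parameters for
$\sigma_k, \phi_c$, reference-coded softmax for weights, log-sum-exp
for mixture likelihoods, non-finite likelihoods rejected with a large
penalty, observed-information vcov when the Hessian inverts.

## Indirect response mapping

For each dimension a proportional-odds model
$P(Y \le j \mid x) = \mathrm{logistic}(c_j - x'\beta)$ is fitted
(`MASS::polr`; plain logistic regression when only two categories are
observed — the same model with a single cut). Categories are the
levels observed in training; unobserved levels carry probability zero
at prediction. The sign convention means protective subscales get
negative $\beta$. A multinomial-logit variant is available
(`type = "multinomial"`) for sensitivity analysis, since either label
appears in the applied literature; the ordered model is primary
because published tables report cut points.

Predicted probabilities convert to utility by **expected decrement**,
$EU = 1 - \sum_d \sum_l p_d(l)\, \delta_d(l)$, which is exact for an
additive tariff when dimensions are drawn independently — so it equals
the Monte-Carlo average over sampled states (a tested identity) while
being deterministic. Monte-Carlo and modal-state computations are
provided as alternatives.

The bundled published indirect tables have three cuts per dimension
(four categories), without stating which EQ-5D levels were merged.
`map_indirect` therefore takes an explicit category-to-level map,
defaulting to levels {1, 2, 3, 4}; predictions made under the default
carry that documented assumption.

## Goodness of fit and cross-validation

`compute_metrics` reports MAE, RMSE, Pearson $\rho$ and Lin's
concordance correlation coefficient
$$CCC = \frac{2\,\mathrm{cov}(o, p)}
{\mathrm{var}(o) + \mathrm{var}(p) + (\bar o - \bar p)^2},$$
with population (1/n) moments by default, the convention of Lin's
original estimator; a sample-moment variant is a flag. MAE ≤ RMSE and
$|CCC| \le |\rho|$ hold by construction and are asserted
property-style in the tests.

`crossvalidate` partitions records into k random folds (sizes within
one of each other), trains every requested model on k−1 folds and
predicts the held-out fold. Metrics are reported both pooled over all
held-out predictions (primary) and per fold, since either convention
appears in published tables. Rows of one patient may land in different
folds by default, mirroring a row-level split of pooled
baseline/follow-up data; `group_by_pid = TRUE` keeps a patient's waves
together and is recommended when within-patient correlation matters.

## The synthetic-cohort generator

No patient-level data are distributed, so the generator emulates the
joint structure the analysis needs from published marginals alone. One
latent severity $\theta_i \sim N(0,1)$ per patient drives everything:

* subscale $j$: $s_{ij} = \mathrm{clip}_{[0,100]}\big(m_j + s_j(\lambda_j
  \theta_i + \sqrt{1-\lambda_j^2}\,\varepsilon_{ij})\big)$ with the
  published means/SDs as $(m_j, s_j)$ — including AS's near-uniform
  spread (mean 36.18, SD 34.07), which is handled by the same
  truncation mechanism rather than a separate family;
* dimension $d$: level $= 1 + \#\{k : z_{id} > \tau_{dk}\}$ with
  $z_{id} = a(-\theta_i) + \sqrt{1-a^2}\,\nu_{id}$ and ordered cuts
  $\tau_d$;
* utility is always the tariff of the generated state — never a
  free-floating column;
* covariates (age 63.04 ± 9.68, 53.72% male, disease-type shares,
  gamma-distributed illness duration 2.50 ± 5.54) are drawn
  independently of $\theta$, as they were non-significant predictors in
  the source analyses.

**Calibration.** Four structural parameters — the dimension loading
$a$, a global shift of the first cuts, a scale on the cut spacing, and
the DP loading $\lambda_{dp}$ — are found by Nelder–Mead on a fixed
common-random-numbers batch of 50,000 draws, minimising squared
deviation from the utility targets (mean 0.87, SD 0.14, ceiling share
0.311) and the Spearman(DP, utility) target 0.7093. The remaining free
loadings are then solved one-dimensionally (bisection; Spearman is
monotone in the loading) against their per-subscale correlation
targets (0.6416, 0.6502, 0.6676, 0.6184). Per-dimension base cuts are
fixed structural constants chosen once to give plausible dimension
marginals (self-care mostly at level 1, pain/discomfort the most
affected). The follow-up latent shift $\delta$ is solved so the
expected paired utility improvement equals 0.1256; follow-up levels are
redrawn from the shifted latent (no transition matrices — no published
transition data exist). Calibration results are cached in-session and
on disk keyed by a hash of the config targets and tariff; infeasible
targets (e.g. a degenerate ceiling share, or a correlation target
unreachable at loading 0.995) raise a calibration error with
diagnostics rather than silently drifting.

**What the generator does not emulate.** The exact empirical joint
distribution of any real cohort: item-level response patterns,
covariate–severity dependence, within-patient clustering of pooled
rows (rows are treated as independent, matching how pooled
baseline/follow-up analyses are usually run), floor observations, and
real missingness. Passing tests on synthetic cohorts therefore
demonstrate correctness of the estimators and machinery, not clinical
validity of any particular coefficient set on real patients.

## Problem sizes and test design

Parameter-recovery tests simulate from each estimator's own model at
n = 5,000 and check coefficient-level 2-standard-error coverage across
replicates for the likelihood-based estimators (OLS, Tobit, GLM,
ordered logit) and fixed tolerances for the robust/censored/mixture
ones. Mixture expected values are verified against 10^6-draw
Monte-Carlo oracles within three Monte-Carlo standard errors; metric
formulas against scalar hand arithmetic; generator descriptives on ten
cohorts of n = 380. Calibration uses batches of 50,000 — large enough
that batch noise is negligible against the loosest target tolerance.

## Known limitations

* Missing SAQ items are mean-imputed within subscale when at least
  half the items are answered (switchable to strict-complete); source
  analyses rarely state their rule, so scored values under imputation
  are a documented choice.
* The published ALDVMM/beta-mixture columns omit mixture weights,
  component scales, precision and the gap boundary, so
  `map_direct_mixture` requires explicit assumptions for the ALDVMM
  and cannot exactly reproduce published mixture prediction summaries.
* No heteroskedasticity- or cluster-robust standard errors; no
  uncertainty propagation through the published coefficient tables.
* The bundled Chinese tariff is verified at its endpoints; users with
  access to the original valuation tables can supply them as a
  constants file.
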