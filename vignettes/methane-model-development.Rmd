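---
title: "Developing and evaluating enteric methane prediction equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and evaluating enteric methane prediction equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entericCH4)
```

## The problem and the model

Enteric methane from lactating dairy cows is measured in expensive,
small experiments — respiration chambers, GreenFeed units, SF6 tracers —
so prediction equations are developed by pooling many studies run by
many research groups across regions. Pooled data of this kind is
clustered twice over: cows share a study (same diet, season, protocol)
and studies share a research group (same equipment, same habits). The
package's central model makes that structure explicit:

$$
y_{ijk} = \beta_0 + \beta_1 x_{1,ijk} + \dots + \beta_n x_{n,ijk}
        + S_{i}(R_j) + R_j + \epsilon_{ijk},
$$

with $S_i(R_j)$ a random study intercept nested in research group,
$R_j$ a random group intercept, and $\epsilon$ the within-study error.
The response can be CH4 production (g/day), yield (g/kg DMI) or
intensity (g/kg energy-corrected milk). `methane_lmm()` fits this by
REML through `lme4::lmer`; REML is the standard estimator when variance
components matter, and the fit is deterministic given data and formula.
The model assumes random intercepts only (no random slopes, no crossed
effects, homoscedastic residuals); those restrictions match how
multi-study CH4 equations are normally developed and keep the variance
decomposition interpretable as group / study / cow.

Predictions for new herds use fixed effects only: a new farm belongs to
no training study, so its best prediction is the marginal regression
line. `predict(fit, newdata, re = "group")` optionally adds the fitted
group intercept for research groups seen in training, but the default —
and everything downstream, including cross-validation — is fixed-only.
This mimics deployment and avoids granting the evaluation information a
user would not have.

## Derived quantities and their constants

* Energy-corrected milk (3.5% fat):
  `ECM = 12.95 · (MY · MF/100) + 7.65 · (MY · MP/100 · 0.93) + 0.327 · MY`
  (kg/day). The 0.93 converts crude protein to true protein and is part
  of the formula, not a record field.
* Methane conversion factor: `Ym = 100 · (CH4 · 0.05565)/GEI` (% of
  gross energy). 0.05565 MJ/g is the energy density of methane; it is a
  physical constant, fixed in the package and not silently editable.
* CH4 yield = CH4/DMI; CH4 intensity = CH4/ECM. Missing inputs
  propagate to missing outputs — missingness is a first-class state, and
  the complete-case filter (`complete_records()`) is the only place
  records are dropped for it.

Percentages are stored in percent units (4.1 means 4.1%), matching how
diet and milk composition are reported and how every published
coefficient is scaled.

## Outlier screening

Records are screened on CH4 yield and intensity, separately within each
region, with Tukey-style fences `Q1 − 1.5·IQR` and `Q3 + 1.5·IQR`.
Numerical choices a user should know:

* Quartiles interpolate order statistics at position $p(n-1)$
  (`stats::quantile` type 7). On small samples the fence values depend
  on this convention, so the tests pin it: the toy vector
  `c(18, 19, 20, 21, 22, 60)` gives Q1 = 19.25, Q3 = 21.75 and fences
  (15.5, 25.5), flagging exactly the 60.
* A record is flagged when yield **or** intensity falls strictly outside
  its fences (`rule = "union"`), the conservative reading; a sequential
  variant (intensity fences recomputed on the yield-screened survivors)
  is available behind the `rule` argument.
* The screen is single-pass: fences are not recomputed after removal.
* Regions with fewer than 4 records are left unscreened with a warning —
  quartiles of three points are not worth acting on.
* `k = 1.5` flags "extremes"; it is an argument, not a constant, but the
  default is the conventional one.

## Variable selection

All $2^k - 1$ non-empty subsets of the candidate predictors are scored
with `BIC = n·log(SSE/n) + log(n)·p`, natural logs, `p` counting the
intercept. Collinearity is handled first: VIFs (`1/(1 − R²)` from
auxiliary regressions) are computed iteratively and the largest VIF
above 5 is removed one predictor at a time, ties broken by keeping the
earlier-listed candidate. Exact collinearity reports `Inf` rather than
erroring, so a duplicated column is handled gracefully.

The SSE entering BIC was a genuinely open design choice. Scoring each
subset by its own ordinary-least-squares fit is cheap and matches the
printed formula most literally, but on strongly clustered data the
within-study error correlation lets chance study-level alignments buy a
spurious predictor past the `log(n)` penalty: in the package's own
selection-consistency simulations the OLS engine recovers a sparse
two-variable truth among six candidates in only about three quarters of
replicates. Scoring each subset by its mixed-model fit (conditional
residual SSE) absorbs study and group noise into the random intercepts
and recovers the sparse truth essentially always, and it is also how the
equations are actually fitted. The mixed-model engine is therefore the
default (`engine = "lmm"`), with `engine = "ols"` retained as the fast
path for large candidate sets. VIF pruning precedes the subset search by
default; the order is exposed through `vif_prune`.

## Cross-validation and evaluation

Folds are studies (`study_folds()`): leaving out single cows would let a
model be evaluated on the very study it learned, and study is the unit
at which new data arrives. For each fold the model is refitted on the
remaining studies and the held-out study is predicted with fixed effects
only. Predictions are pooled across folds **before** computing metrics
(not per-fold metrics averaged), so every record contributes once and
small studies are not over-weighted. A fold whose REML fit fails is
refitted by OLS and counted in `n_fallback` rather than aborting the
whole cross-validation.

The metric suite reports MSPE, RMSPE (absolute and as % of the observed
mean), MAE, RSR = RMSPE/So, the decomposition

$$
\mathrm{MSPE} = (\bar P - \bar O)^2 + (S_p - r S_o)^2 + (1 - r^2) S_o^2
$$

(mean bias, slope bias, random error), and Lin's concordance
$CCC = r \cdot C_b$ with $C_b = \big((v + 1/v + u^2)/2\big)^{-1}$,
$v = S_o/S_p$, $u = (\bar P - \bar O)/\sqrt{S_o S_p}$. All standard
deviations are population form (denominator $n$); with sample SDs the
decomposition identity would not close exactly, and the identity is the
suite's internal oracle (asserted to 1e-10 in the tests). Tables of
published equations report MB and SB as % of MSPE; both absolute and
percentage forms are in every report. When a vector is constant the
correlation-based statistics are a typed "undefined" state (`NA` plus a
listing in `report$undefined`), never a silent zero; the decomposition
is then closed at the $r = 0$ convention.

## The equation registry

Fifty-one published equations (production, yield and intensity;
intercontinental, EU and US scopes) are bundled with coefficients and
standard errors at printed precision — the registry is a transcription
layer and re-derives nothing. Standard errors are stored for reference
only; no prediction intervals are propagated from them. Two quirks are
preserved deliberately: one US production row duplicates another
verbatim (both ids point at the same coefficients, keeping the published
numbering traceable), and one intensity category label
(`DMI+Com_Comp_C`) is kept exactly as printed. Gross-energy-scale
equations and the IPCC Tier 2 rows divide by 0.05565 after the linear
combination. `best_available()` picks, among equations whose predictors
are all on hand, the one with most predictors; ties fall to a documented
category preference (animal-level first, then intake-, milk-,
diet-based). `ecm` counts as available only when listed explicitly —
it is computable from `my`, `mf`, `mp`, but the choice to use it is the
caller's. Regional yield/intensity equations not printed in the main
tables are not bundled; the JSON registry schema
(`load_registry()`/`write_registry()`) accepts user-supplied sets.

## The synthetic herd generator

`generate_herd()` emulates the statistical shape of a multi-study cow
database: a balanced hierarchy of groups, studies and cows; covariates
drawn from truncated normals matching published per-region means, SDs
and ranges; milk yield linked to intake by a configurable correlation
(default 0.6 — high-intake cows milk more); `GEI = DMI × GE density`;
and CH4 from a configurable true equation plus group, study and residual
noise, floored at 1 g/day. Defaults are the published all-variable
production equation for the betas, and SDs of 20 (group), 25 (study) and
40 g/day (residual), chosen once so that region-level CH4 coefficients
of variation land in the 23–33% band seen in real multi-study data.
Each study draws from its own counter-derived substream, so growing one
study never perturbs another study's records, and everything is
reproducible from a single integer seed.

What the generator does **not** emulate — and therefore what passing
recovery tests cannot show about real data: covariate correlations
beyond the intake–milk link (real diets correlate NDF, EE and CP),
measurement-method biases (chamber vs SF6), lactation-stage and breed
effects, unbalanced study sizes, and non-Gaussian tails. The generator
validates the machinery, not the biology.

## Validation problem sizes

The package's own validation runs at sizes chosen to make the
statistical claims meaningful while keeping the suite quick to run:
parameter recovery uses 50 seeded replicates of 6 groups × 10 studies ×
20 cows (n = 1200), asserting each true coefficient inside two estimated
standard errors in at least 90% of replicates; selection consistency
uses 50 replicates at n = 2000 (5 groups × 10 studies × 40 cows) with a
sparse two-variable truth among six candidates, asserting exact recovery
in at least 80%; the metric identities are asserted on 1000 random
vector pairs at 1e-10.

## Known limitations

* Variance components at a true zero are estimated slightly positive
  (REML boundary behaviour), so degenerate-noise fits agree with OLS to
  a fraction of a standard error, not to machine precision.
* With exactly one record per study, the study and residual variances
  are not separately identifiable; the fit is flagged
  (`identifiable = FALSE`) rather than silently split.
* The selection search is capped at 12 candidates (4,095 subsets);
  beyond that, prune first.
* No imputation, no model-based outlier detection, no uncertainty
  propagation from registry standard errors, and no support for
  non-lactating animals or unit systems other than kg/MJ/g.
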