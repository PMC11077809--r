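---
title: "Modelling healthcare costs and allocating capitated budgets with capamg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling healthcare costs and allocating capitated budgets with capamg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capamg)
```

## The model

`capamg` estimates expected annual healthcare cost per insured person from
three objective need variables: sex, 5-year age band (0, 5, ..., 85, the top
band open-ended), and Adjusted Morbidity Group (AMG). The AMG stratifier
assigns each person to one of 31 mutually exclusive groups — the healthy
population plus six morbidity types (acute, pregnancy/childbirth, chronic in
one organ system, in 2–3 systems, in 4 or more systems, neoplasms), each cut
into five complexity levels. The grouping itself is taken as given input:
this package starts from coded AMG labels, not diagnoses.

Costs in the analytic table are strictly positive (only persons who actually
incurred expenses appear) and heavily right-skewed, so the workhorse is a
generalized linear model

$$ g\!\left(\mathrm{E}[Y_i]\right) = \mathbf{x}_i'\boldsymbol\beta, \qquad
   \mathrm{Var}(Y_i) = \varphi\,\mathrm{E}[Y_i]^p, $$

with treatment coding (references: age band 0, AMG 1, sex = 0; the female
indicator is 1 — the coding direction is a convention of this package, the
motivating analysis never states one). The family/link menu is the standard
healthcare-cost one: links identity, square root ("power 0.5"), log;
families gaussian ($p=0$), poisson ($p=1$), gamma ($p=2$), inverse gaussian
($p=3$). Fitting is IRLS (relative deviance change below $10^{-8}$, at most
100 iterations); the gaussian/identity corner reduces exactly to OLS.

Two fitting choices deserve a note. First, AIC/BIC must be comparable across
families, so the log-likelihood is evaluated at the maximum-likelihood
dispersion: for the gamma family the shape is profiled out by 1-D
optimisation, for the inverse gaussian the ML dispersion has the closed form
$\hat\varphi = n^{-1}\sum (y_i-\hat\mu_i)^2/(\hat\mu_i^2 y_i)$; the Pearson
dispersion is kept for standard errors. Second, Poisson-family fits on
continuous costs use the quasipoisson IRLS (identical coefficients) with the
Poisson quasi log-likelihood evaluated directly, since the response is not a
count.

## Selecting the link and the family

Selection is deliberately dual:

* **Information criteria.** All 12 link/family combinations are fit and
  tabulated (`selection_grid()`); failures are recorded per row, never
  dropped. Both total and per-observation AIC/BIC are reported.
* **Box-Cox λ for the link** (`box_cox_lambda()`). The profile
  log-likelihood of the transformed-response regression *on the full
  covariate design* (not the marginal distribution — the λ is used to choose
  the link of a regression) is evaluated on a λ grid over $[-2, 2]$ with
  step $10^{-3}$, then refined locally; the 95% interval is the
  profile-likelihood $\chi^2_1$ cut. The design is QR-factorised once, so
  each λ costs a single cross-product. The recommended link is the nearest
  of $\{0 \to \log,\ 0.5 \to \text{power},\ 1 \to \text{identity}\}$.
* **Modified Park test for the family** (`modified_park_test()`). A gamma/log
  GLM is fit first; the OLS slope of $\log (y_i - \hat\mu_i)^2$ on the
  linear prediction $\hat\eta_i$ estimates the variance power $p$, with an
  HC1 robust 95% CI. Zero residuals are dropped with a logged count. The
  slope is invariant to currency rescaling.

On data generated by the package's own defaults the battery reproduces the
expected conclusion — gamma family (slope ≈ 2), log link. One nuance: with
gamma shape 0.5 the Box-Cox *point estimate* converges to λ ≈ 0.12–0.15, not
to 0. The log-gamma(0.5) distribution is left-skewed, and the Box-Cox
likelihood trades symmetry against mean fit, so its pseudo-true λ sits above
zero; with 50,000 observations the profile CI is a few thousandths wide and
therefore excludes 0 — just as the motivating analysis reported a tight CI
around 0.042 on real data and still, correctly, chose the log link because
λ is *near* 0. The recommendation rule (nearest anchor), not the CI, carries
the decision.

## The validation battery and its calibration

The specification tests are the ones named in the health-econometrics
literature, with inference details this package had to fix (and did fix by
simulating their size under the true model; a nominal 5% test should reject
roughly 5% of correctly specified datasets):

* **Pregibon link test** (`pregibon_test()`): refit with $\hat\eta^2$ added;
  two-sided p-value of its coefficient. Size ≈ 0.05 as is.
* **Modified Hosmer–Lemeshow** (`hosmer_lemeshow_test()`): records are
  sorted by $\hat\eta$ (ties broken by stable record order) and cut into 10
  equal groups; the group means of the raw-scale residuals (equivalently,
  the coefficients of the no-intercept OLS on group indicators) are tested
  jointly for zero. A naive homoskedastic F-test is essentially blind here:
  the pooled variance is dominated by the most expensive decile and the
  in-sample fit shrinks the group means, driving the size to zero. The
  package therefore uses a Wald statistic whose covariance combines robust
  per-observation variances with the estimation correction
  $e = (I - M)\varepsilon$, where $M$ is the response-scale hat operator of
  the GLM, inverted by eigenvalue pseudo-inverse (reference: $\chi^2$ with
  the covariance rank as df). Simulated size ≈ 0.08 at $n = 5{,}000$.
* **Copas cross-validation test** (`copas_test()`): repeated random half
  splits (default 10); fit on one half, regress observed on predicted in the
  other by OLS, test slope = 1 (slope < 1 flags overfitting). Holdout-only
  standard errors over-reject badly under heavy-tailed gamma costs (size
  0.17–0.28 in our simulations, whatever the HC flavour), because the slope
  error decomposes exactly as
  $b - 1 = \sum_i c_i (y_i - \hat\mu_i)$ — a holdout noise term *plus* a
  training-estimation term. The package's variance adds both components:
  the HC holdout part $\sum c_i^2 r_i^2$ and the training part
  $\mathbf{a}'\widehat{\mathrm{Var}}(\hat\beta)\,\mathbf{a}$ with
  $\mathbf{a} = \sum_i c_i\,\mu'(\hat\eta_i)\,\mathbf{x}_i$ and a robust
  sandwich for $\hat\beta$. Simulated size ≈ 0.035. Degenerate splits
  (missing factor levels) are redrawn with a logged count, at most 10 times.
  The per-repetition p-values are reported along with their mean as the
  summary; the split ratio is 50/50.
* **Raw-scale metrics** (`fit_metrics()`): auxiliary R² (squared correlation
  of observed and predicted costs on the untransformed scale), RMSE, MAE —
  in-sample and averaged over the Copas holdouts.

Diagnostics use raw-scale residuals $y - \hat\mu$ throughout. Predictions of
a log-scale OLS would need a retransformation; this package's GLMs predict on
the natural scale directly, so no smearing estimator is involved.

## Effects, weights, and the capitation formulas

* `average_marginal_effect()` averages, over all records, the predicted cost
  with a binary indicator forced to 1 minus forced to 0; indicators in a
  mutually exclusive set (age bands, AMG) switch their siblings off, so the
  "0" state is the reference level. It equals the brute-force counterfactual
  re-prediction by construction, which a test asserts to $10^{-10}$.
* `group_predicted_means()` averages individual predictions within each AMG
  — deliberately *not* the prediction at group-mean covariates. This matches
  the published weight table: the weight of the lowest acute group (1.111)
  equals the ratio of predicted means 239.45/215.57, not
  $e^{0.095} = 1.100$, which is only possible when group compositions enter.
* `relative_weights()` divides by the healthy group's mean; reporting
  precision follows the published table (weights 3 decimals, € 2 decimals,
  coefficients 3 decimals).
* `area_cost_summary()` compares observed and predicted mean cost per area
  with cross-sectional indices (system = 100). GLM predictions do not sum to
  observed costs exactly, so predictions are rescaled multiplicatively to
  the observed system mean (factor logged as an attribute) — this is what
  makes the published Total row balance. `need_index()` is the predicted
  index on the unit scale; `adjusted_population()` multiplies covered
  population by it; `allocate_budget()` distributes the budget by population
  share, adjusted-population share, and historical share, exactly conserving
  the budget pre-rounding. Need indices are estimated from cost-incurring
  persons but applied to covered populations (which include non-users) —
  the same asymmetry the published tables combine, documented here as an
  assumption.

## The synthetic-population generator

`sim_config()` defaults *are* the study conditions: AMG shares equal to the
published group sizes over 1,251,108; per-AMG age moments and female shares
from the published table; true log-scale coefficients equal to the published
gamma/log estimates; a single common gamma shape ν = 0.5 (variance
$\mu^2/\nu$), matching the selected model's assumption of one dispersion;
nine areas with covered-population shares, historical budget shares and a
coverage-inflation factor (covered 1,511,251 / analytic 1,251,108 ≈ 1.208)
from the published financing table. Ages are drawn from per-AMG truncated
normals on [0, 105]; the location parameter is solved so the *truncated*
mean equals the published mean. For young, highly dispersed groups no
truncated normal attains both published moments (the truncation caps the
attainable CV), so the mean is matched exactly and the realised SD shrinks —
the recovery tests therefore check means and shares, not SDs.

Each area tilts the AMG mix by $w_{ag} \propto p_g \cdot \bar c_g^{\,t_a}$,
where $\bar c_g$ is the published group mean cost and the exponent $t_a$ is
root-solved at configuration time so the area's expected cost index equals
the published predicted index. Realised costs are then multiplied by the
published observed/predicted ratio of the area, which recreates the
over/under-funding pattern the allocation stage is meant to expose. What the
generator does **not** emulate: within-group dispersion heterogeneity
(one global ν), any within-area correlation beyond the case-mix tilt,
zero-cost insured persons (they enter only through the area-level covered
populations), and coding errors in AMG assignment. Passing tests on this
generator therefore demonstrate the *machinery* — estimation, selection,
calibration of the tests, allocation arithmetic — not the fit of any
particular real population.

## Numerical choices and problem sizes

Tolerances: IRLS $10^{-8}$ relative deviance, Box-Cox grid step $10^{-3}$
with local refinement, budget conservation asserted to $10^{-9}$,
rank-deficient designs are errors (never silently aliased), Hosmer–Lemeshow
eigen cut at $10^{-8}$ of the largest eigenvalue, exact fits short-circuit
the degenerate statistics (slope ≡ 1 ⇒ p = 1, zero residuals ⇒ HL stat 0).
The master seed expands into fixed per-stage seeds (MINSTD multiplier, mod
$2^{31}-1$) so stages are individually reproducible; identical configuration
and seed give byte-identical report bundles.

The test suite simulates at sizes chosen to keep the whole battery
informative yet quick on one CPU: parameter-recovery coverage with 50
replicates of $n = 20{,}000$ on a reduced design (sex, four age bands, six
AMGs spanning the morbidity range), selection calibration at
$n = 50{,}000$, test-size simulations with 100 replicates at $n = 5{,}000$,
and fuzzed 3–20-area allocation checks. The size simulations use the reduced
design deliberately: under the full 31-group design at $n = 5{,}000$ the
training halves of the Copas split fit ~50 parameters on 2,500 observations
and the slope genuinely shrinks below 1 — correct overfitting detection, not
a size distortion.

## Known limitations

* Two-part/hurdle models (for populations that include zero-cost persons),
  mixed models and regularisation are out of scope.
* The historical allocation is an exogenous input (a share vector); the
  package does not model the accounting process that produces it.
* Identity and square-root links with gamma or inverse-gaussian families can
  fail to converge on heavily skewed data; the selection grid records these
  failures per row rather than forcing convergence.
* Published-table reproductions are limited by print precision: need indices
  are published at 5 decimals (worth ±1 person in adjusted populations) and
  historical allocations as whole millions (worth ±0.5 M€ in the difference
  column).
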