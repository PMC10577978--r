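---
title: "Methods: censored imputation and mixture effects for well-water metals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored imputation and mixture effects for well-water metals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellmix)
```

`wellmix` estimates associations between census-tract private-well metal
concentrations and preterm birth. This vignette is the package's own
account of its statistical machinery: the models, the tunable parameters
and their defaults, the numerical choices, the design decisions taken
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## The exposure problem

Private-well test reports are doubly incomplete. A report either lists a
detected concentration or states that the analyte was below the
laboratory's limit of reporting (LOR) — a left-censored observation — and
many tests simply never measured a given analyte. Discarding or naively
substituting these cells (e.g. LOR/√2) biases tract summaries, especially
for trace metals like cadmium where most results are censored.

### Tobit regression

For each analyte the natural-log concentration is modelled as Gaussian
given the log concentrations of every other configured analyte and county
indicator variables (county is the smallest geography with tests in every
unit, and the county shift absorbs spatial structure). Observed cells
contribute density terms and censored cells contribute CDF terms:

$$\ell(\beta,\sigma)=\sum_{\mathrm{obs}}\left[-\log\sigma+\log\phi\!\left(\tfrac{y_i-x_i^\top\beta}{\sigma}\right)\right]+\sum_{\mathrm{cens}}\log\Phi\!\left(\tfrac{c_i-x_i^\top\beta}{\sigma}\right).$$

Two censor-bound conventions are used, matching how each kind of
incompleteness arises: a below-LOR cell is censored at $c_i=\log(\mathrm{LOR})$
(the value is known to be below it), while an unmeasured cell is censored
at the log of the analyte's maximum observed concentration (nothing is
known beyond the observed support, so the bound is the weakest defensible
one). By construction the below-LOR bound never exceeds the not-measured
bound for the same analyte.

`fit_tobit()` maximises $\ell$ over $(\beta,\log\sigma)$ —
the log parameterisation keeps $\sigma$ positive and the surface close to
quadratic — with BFGS, an analytic gradient, and a warm start at the
uncensored least-squares solution. Convergence uses a relative tolerance
of 1e-12 with at most 200 iterations. Standard errors come from the
numerically differentiated observed information at the optimum;
$\mathrm{se}(\sigma)$ is delta-method from the $\log\sigma$ scale. With no
censored rows the maximiser reduces to ordinary least squares with
$\hat\sigma^2=\mathrm{RSS}/n$, which the tests assert to 1e-6, and on
small censored fixtures the fit matches an independent grid-search
maximizer of the same likelihood at step 1e-3.

### Chained-equations imputation

`impute_chain()` embeds the Tobit model in a chained-equations loop:

1. initialise every incomplete cell uniformly over the analyte's observed
   log range;
2. per iteration, cycle analytes in the configured order: fit the Tobit
   model given the *current* log values of all other analytes plus county
   indicators; draw parameters $\beta^*_k \sim N(\hat\beta_k,
   \mathrm{se}_k^2)$ independently and $\sigma^*$ on the log scale (the
   proper-imputation step that propagates estimation uncertainty); then
   redraw each incomplete cell from $N(x_i^\top\beta^*,\sigma^{*2})$
   truncated above at its censor bound;
3. after `n_iterations` (default 30) return the complete table from the
   final iteration. Observed cells are never modified.

Two wordings were possible for step 2's imputation — plugging in expected
values versus drawing stochastically. The package draws from the
truncated predictive distribution: deterministic conditional means would
collapse within-cell variance, put every imputed value at the same point
given identical covariates, and contradict the chained-equations framing.
The truncated draw also guarantees the bound invariants (imputed
below-LOR values never exceed the LOR on the ppb scale) that the tests
assert. The draw uses the inverse-CDF method on log-CDF values so that
bounds deep in the lower tail do not underflow.

One chain is run and the final iteration kept; no pooling across multiple
imputations is performed. Counties with fewer than 5 tests are pooled
into an `"other"` level so the county indicator block cannot induce
separation. Stability is monitored by the trace of per-iteration imputed
means and SDs; `trace_diagnostics()` flags an analyte stable when the
slope of the mean trace over the last 10 iterations is below 0.01 log-ppb
per iteration. That tolerance is calibrated to database-scale inputs
(tens of thousands of cells); at the few-hundred-cell scale of the test
fixtures the Monte-Carlo noise floor of the trace exceeds it, so the test
suite checks absence of drift via the slope *t*-statistic instead.

## Exposure construction

`tract_summaries()` computes, per tract and metal, the arithmetic mean
concentration (ppb) and the exceedance fraction — the share of tests at
or above the metal's maximum contaminant level (MCL; defaults iAs 10,
Cd 5, Cr 100, Cu 1300, Pb 15, Mn 300, Zn 5000 ppb). Ties at the MCL count
as exceedances. Exceedance fractions are computed on the imputed complete
data by default (a raw-only run is possible by passing the unimputed
table); whether the original analysis used imputed or raw values for this
step is not stated, and the imputed choice keeps the denominator constant
across metals.

Two per-birth codings follow:

* **Percentile** (`code_percentile_category()`): 0 for at/below the 50th
  percentile, 1 for above-50th-to-at/below-90th, 2 above the 90th.
  Cutpoints are linear-interpolation sample quantiles (R type 7; the
  reference did not state a definition, so one is fixed and documented).
  The reference distribution is the *birth-level* distribution of tract
  means — each birth contributes its tract's mean — rather than the
  tract-level distribution; this is what makes the three categories hold
  ≈50/40/10% of births, matching the published category case counts.
  Boundaries are right-closed: a value exactly at a cutpoint takes the
  lower category.
* **Exceedance** (`code_exceedance_flag()`): 1 when the tract's
  exceedance fraction is ≥ the threshold (default 0.25), with the
  boundary inclusive.

The nitrate/nitrite co-pollutant covariate applies the same 0/1/2
percentile machinery to the tract average of nitrates and nitrites; a
degenerate or absent distribution demotes the covariate to "omitted with
a warning" rather than an error, since an adjustment set should degrade
gracefully.

## Cohort construction

`apply_inclusion_filters()` retains singleton, non-anomalous births with
gestational age in [20, 44) completed weeks whose tract has well tests,
applying rules in a fixed order (geography → plurality/anomaly →
gestational age → tract coverage) and tallying each record under the
first rule that removes it, so input n = final n + removals. Outcomes are
nested by construction: PTB (<37 weeks), very PTB (<32), extremely PTB
(<28); descriptive "28 to <32" style bands are not used for modelling.
Models of very and extremely PTB compare cases with *all* non-cases of
that outcome.

Covariates are coded per `build_design_matrix()`: maternal age with a
quadratic term; race/ethnicity as five indicators against White
non-Hispanic (the largest group); smoking binary; education (<HS, HS,
>HS), tract poverty quartile, and the nitrate category as single ordinal
numeric columns; season of conception as three indicators against
winter. Season is derived from birth date minus 7 × gestational weeks
(conception date is not a birth-certificate field) and mapped to
Dec–Feb/Mar–May/Jun–Aug/Sep–Nov. Adjusted models are complete-case —
missing-covariate handling was unstated in the reference, and
complete-case deletion with a reported model n is the transparent
default — while crude models use all records with a coded exposure.

## Logistic core and single-metal tables

`fit_logistic()` is Newton–Raphson with step-halving from a zero start,
converging when the largest score component is below 1e-8 or the
log-likelihood gain is below 1e-10. Each Newton step is solved as a
weighted least-squares problem through the QR decomposition of
$\sqrt{w}X$ rather than by forming $X^\top WX$, which matters for
conditioning when covariates are tract-level and the tract count is
small. The coefficient covariance is the inverse observed information at
the optimum; all intervals are Wald. Perfect separation (diverging
coefficients with a non-vanishing score) raises an explicit error — no
finite MLE exists and silently reporting one would be misleading.

In subsample fits (training splits, strata) a factor level can be absent,
leaving an all-zero indicator column, and tract-level covariates can be
exactly collinear when few tracts are represented; covariate columns that
are constant or aliased on the analysis rows are dropped (exposure
columns are protected and instead raise an error). `odds_ratio_2x2()`
applies no continuity correction — a zero cell is an error by design.
The crude exceedance logistic model reproduces the 2×2 odds ratio to
1e-10, which the tests assert.

## Quantile-based g-computation

Each metal's birth-level exposure is scored into quartiles (`q = 4`;
cutpoints at 1/q, …, (q−1)/q, score = number of cutpoints strictly below
the value, ties to the lower score). The joint model

$$\mathrm{logit}\,P(Y=1)=\alpha+\textstyle\sum_j\beta_j s_{ij}+\gamma^\top z_i$$

defines the mixture effect $\psi=\sum_j\beta_j$ — the log-odds change
from raising every metal one quartile simultaneously — with
$\mathrm{Var}(\hat\psi)=\mathbf 1^\top V\mathbf 1$ over the exposure
block. This is the no-bootstrap, conditional form: $\psi$ is a
conditional log-OR, which is the quantity the published usage reports; a
bootstrap marginal variant is deliberately out of scope. Weights are
$\beta_j$ normalised within sign group and reported signed, so positive
weights sum to 1 and negative weights to −1. In the identity-link
Gaussian variant (`family = "gaussian"`, used for verification) $\psi$
equals the brute-force g-computation contrast — mean prediction with all
scores incremented minus mean prediction at observed scores — exactly,
and the tests assert this equality, as well as the corresponding log-odds
identity for the covariate-free logistic model.

**Partial effects** (`partial_effects()`): per cycle, a seeded random
split into 30% training / 70% validation; the training mixture fit
partitions metals by coefficient sign (an exactly zero coefficient goes
to the negative set, a measure-zero tie-break fixed for determinism); on
validation, the positive-set mixture is estimated adjusting for the
negative-set scores as covariates and vice versa. Twelve cycles by
default. Quantile cutpoints are estimated once on the full analysis
sample and shared across splits — "one quartile" must mean the same
physical contrast in training and validation, and re-estimating cutpoints
per split would quietly change the estimand. Cycle seeds derive from the
master seed by fixed increments; a split that leaves either side without
both cases and non-cases is redrawn at most five times with a logged
note. One fixed analysis sample is used for all mixture models.

**Effect-measure modification** (`qgcomp_emm()`): a single shared model
with the scores, the modifier's main-effect indicators, and
score-by-indicator products; $\psi_g=\sum_j(\beta_j+\eta_{jg})$ with
$\eta\equiv0$ in the reference stratum and variance from the matching
covariance quadratic form. The shared-model formulation (rather than
per-stratum refits) borrows covariate information across strata and makes
the reference-stratum identity $\psi_{\mathrm{ref}}=\sum_j\beta_j$ exact,
which the tests assert.

## The synthetic-data generator

`simulate_well_tests()` draws latent log concentrations from a
multivariate normal with per-county location shifts — the same family the
imputation model assumes, which is what makes recovery tests well-posed —
then applies the observation process (not-measured with a per-analyte
probability, otherwise below-LOR exactly when the latent value is under
the LOR). `simulate_births()` assigns births to tracts, quantizes the
tract-mean exposures, draws covariates, and draws the PTB indicator from
the logistic outcome model; gestational age is then uniform within
outcome class ([20, 37) for cases, [37, 44) otherwise), since only the
binary and nested outcomes feed the models. Ground truth (latent
concentrations, true $\psi$ overall and per stratum) is stored beside the
data and never read by analysis stages — the tests assert that deleting
the truth file changes nothing.

Defaults and why:

* per-metal lognormal medians anchored to the published birth-level 50th
  percentile cutpoints (e.g. arsenic 0.220 ppb) with log-scales solved
  from the 50th/90th spread — the underlying distributional parameters
  are not published, so these are order-of-magnitude anchors, all
  config-exposed;
* cross-analyte log correlation 0.3 and county shift SD 0.5 log-ppb:
  moderate co-occurrence and spatial structure;
* LORs near each metal's median, emulating the heavy left-censoring
  typical of trace metals; 10% not-measured;
* outcome model: baseline prevalence 9.4%; per-metal per-quartile
  coefficients defaulting to the published adjusted mixture coefficients
  (sum = true $\psi$); covariate margins (race/ethnicity, education,
  smoking, 8.9% missingness in education and smoking) matching the
  published cohort description; stratum increments added equally across
  metal coefficients so a stratum's true effect is $\psi+\delta_g$;
* default simulation sizes (5,000 tests, 20 counties, 200 tracts, 10,000
  births) are scaled-down emulations of the state-wide database; the
  committed fixtures are smaller still (tiny: 200 tests / 2,000 births;
  small: 1,000 / 10,000).

What the generator does **not** emulate: real geography and the real
joint distribution of all fifteen analytes; temporal trends in testing;
informative missingness (cells go unmeasured at random, not because of
the lab's panel choices); exposure measurement error between tract mean
and personal dose; and any dependence of covariates on exposure, so
synthetic "confounders" are only precision variables. Passing recovery
tests therefore demonstrates internal statistical validity of the
machinery — not that the real data meet these assumptions.

## Verification choices and problem sizes

The recovery and calibration checks run at fixed sizes chosen so each
property is informative: mixture-effect recovery at n = 100,000 births
with a true per-quartile sum of log(1.02) over 100 replicates, the
coefficient split made cadmium-dominant a priori (mirroring the published
weights) so "largest true coefficient" is statistically identifiable;
stratified recovery at n = 150,000 with a 10% index stratum and true
stratum OR 1.19 over 50 replicates; sign-partition recovery with two
harmful and two protective metals at |OR| = 1.05 per quartile over 12
cycles; imputation-vs-LOR/√2 at 500 tests per replicate with the arsenic
LOR placed at the latent 40th percentile over 50 replicates; interval
calibration over 300 replicates at n = 50,000. In these simulations the
covariate effects and covariate missingness are switched off so the
conditional and marginal mixture effects coincide and the stated n is the
effective n; with them on, the checks would conflate calibration with
logistic non-collapsibility and complete-case attrition.

## Known limitations

* Wald inference throughout; profile-likelihood intervals are not
  implemented (at cohort-scale n the difference is negligible, and the
  committed zinc bound reproduces the published one, but small-sample
  intervals will be anti-conservative).
* Single-chain imputation with the final iteration kept: between-chain
  variability is not propagated into downstream standard errors.
* The conditional (no-bootstrap) mixture estimator only; no marginal
  bootstrap variant, no nonlinear or spline mixture terms, no
  time-to-event outcomes.
* Tract IDs are opaque strings; there is no geocoding, geometry or
  spatial smoothing, and tracts with few tests get noisy summaries with
  no neighbour borrowing.
* Gestational age enters only through the nested binary outcomes;
  spontaneous and medically indicated preterm births are not
  distinguished.
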