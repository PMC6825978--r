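---
title: "Methods: the deficit-accumulation survival index and its pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the deficit-accumulation survival index and its pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind every number the
package produces, the calibration constants of the synthetic-cohort
generator, and the deliberate numerical conventions — the details that are
too long for function documentation but load-bearing for anyone auditing
results.

## 1. The index

For patient $i$ with deficit indicators $b_{ij} \in \{0,1\}$ over $J = 23$
registered factors,

$$\mathrm{DASI}_i = \frac{1}{D_i} \sum_{j=1}^{J} b_{ij},$$

where the denominator $D_i$ is fixed at 23 by default (`"fixed23"`: an
unevaluable factor contributes nothing, so missingness can only shrink the
score) or the count of evaluable factors (`"evaluable"`, the classical
frailty-index convention, which rescales instead). Patients with fewer
than 18 evaluable factors receive `NA`. Categories partition $[0,1]$
contiguously: low $\le 0.30$, moderate $(0.30, 0.48]$, high $> 0.48$ —
every valid score maps to exactly one category.

Cutoff conventions (see `default_factor_registry()` for the full table):
all numeric cutoffs are strict (`>` or `<`; the boundary value itself is
not a deficit) with one deliberate exception, corrected calcium at
$\ge 11$ mg/dL. Platelets are a two-sided rule ($< 150$ or $> 450$).
Set-valued rules (marital status in {single, divorced, widowed}, ECOG in
{2, 3, 4}, fall risk exactly "high") score membership. A factor whose
source value is missing yields a missing deficit, never zero.

Derived indices feeding four of the factors, computed at full precision
before dichotomization:

- NLR $=$ neutrophils / lymphocytes, PLR $=$ platelets / lymphocytes,
  SII $=$ platelets $\times$ neutrophils / lymphocytes;
- PNI $=$ albumin $\times$ lymphocytes. This is a deliberate,
  non-standard product convention matched to the cutoff of 45 used by the
  registry; the classical Onodera form
  ($10 \cdot \text{albumin} + 5 \cdot \text{lymphocytes}$) is available as
  `add_indices(pni_convention = "onodera")`, but its scale does not match
  the registered cutoff;
- corrected calcium $=$ total calcium $+ 0.8 \times (4 -$ albumin$)$;
  BMI $=$ kg/m$^2$.

## 2. Survival analysis

Kaplan-Meier curves use the product-limit estimator with Greenwood
variance and log(-log) pointwise bands. The reported median is the
smallest event time with $\hat S(t) \le 0.5$ (not the
average-of-two-times convention some software applies when the curve sits
exactly at 0.5), and its 95% CI inverts the log(-log) band
(Brookmeyer-Crowley style); a bound the band never crosses is reported as
"undetermined". Group contrasts use the log-rank test.

Cox models maximize the partial likelihood with the Efron tie correction
by default — admission data are recorded in whole days, so ties are heavy
— with Breslow available for comparison against hand oracles. Confidence
intervals are Wald with the literal multiplier 1.96 (not
`qnorm(0.975)`), matching the reporting convention of the clinical
literature; at reported precision the difference is nil. Monotone partial
likelihoods (complete separation) raise a diagnostic error naming the
unbounded terms rather than returning a silently huge coefficient, and a
rank-deficient design raises an error naming the collinear columns. A
factor level absent from the complete-case subset is dropped as an empty
contrast (it is not collinearity).

Model building mirrors a conventional two-stage clinical workflow:

1. **Univariate screen** (`univariate_screen()`): one Cox fit per
   registered covariate, log-transforming skewed labs (calcium,
   creatinine, length of stay, NLR, neutrophils, PLR, platelets, SII,
   WBC), selection at Wald $p < .05$. A covariate whose fit degenerates
   (constant value, or a sparse level with no events) is flagged, not
   fatal.
2. **Multivariable model** (`build_multivariable()`): selected covariates
   minus screen-only ones (the DASI category itself — it contains
   readmission as a component — and the performance-status scores), with
   the highly correlated inflammation markers {NLR, neutrophils, PLR,
   platelets, SII} collapsed to NLR, plus forced covariates (cancer type,
   prior healthcare visits), capped at 13 covariates. Exceeding the cap
   is an explicit error by default; the pipeline uses
   `budget_policy = "trim"`, which keeps the forced set plus the
   strongest-screening covariates and, under the same policy, repairs
   separation by merging a zero-event factor level into its reference.

Power is summarized as the minimum detectable hazard ratio for a binary
exposure: $\exp\{(z_{1-\alpha/2} + z_{\text{power}}) / \sqrt{d\,p(1-p)}\}$
with $d$ events and allocation $p$ — e.g. 100 events at $p = 0.5$ give
1.75 at 80% power. (This Schoenfeld-type formula is the package's
definition of record; variants in the literature differ in rounding and
allocation conventions, so exact agreement with other tools is not
expected.)

## 3. Missing data

`impute_cohort()` is chained-equations imputation written against base R:
numeric variables by type-0 predictive mean matching (OLS predictions,
5-donor pools, so imputed values always come from the observed support —
integer columns stay integer), categoricals by draws proportional to
observed frequencies; 10 cycles; the outcome enters every imputation
model as (log survival time, event) but is never imputed; observed cells
are never modified (asserted). `sensitivity_analysis()` refits the
multivariable model on each of $m = 20$ completed datasets and reports
the focal hazard-ratio **range** as the primary, assumption-light
summary, plus the Rubin's-rules pooled estimate
($\bar q$, $T = W + (1 + 1/m)B$). Everything is deterministic given
`seed`.

## 4. The synthetic-cohort generator

The generator's design problem: the 23 deficits must (a) have specified
marginal prevalences, (b) be positively dependent (frail patients
accumulate deficits), (c) drive survival through the *score*, and (d) be
consistent with the continuous observables they are defined from (a
drawn sodium of 133 must coincide with the sodium deficit being 1).

**Latent truth.** Deficits come from a one-factor Gaussian threshold
model: with shared frailty $Z_i \sim N(0,1)$, loading $\rho = 0.3$,

$$b_{ij} = \mathbf 1\{\sqrt{\rho}\, Z_i + \sqrt{1-\rho}\,\varepsilon_{ij}
  < \Phi^{-1}(p_j)\},$$

so each deficit has exact marginal probability $p_j$ and all pairs are
positively correlated. The true score is $\sum_j b_{ij} / 23$.

**Observables.** The 19 single-variable factors are realized
consistently: labs are drawn from their marginal distribution truncated
to the deficit or non-deficit region indicated by $b_{ij}$ (normal
marginals moment-matched to typical cohort summaries, e.g. sodium
$N(136, 4.98^2)$; right-skewed labs lognormal matched by median and
mean); counts (visits, medications) and categoricals are drawn the same
way. The default $p_j$ for lab factors are computed analytically as the
marginal's deficit-region mass, so region-conditional drawing reproduces
the marginals *exactly*. Values are rounded at clinical precision with a
post-rounding clamp so rounding never moves a value across its cutoff.

The four ratio-index factors (NLR, PLR, SII, PNI) are *emergent*: their
latent indicators shape the component labs, but the measured index is
computed from the drawn labs. The measured score is therefore a close
proxy of the generating score (correlation about 0.9), which is exactly
the measurement situation the analysis faces in practice. The full truth
(per-factor deficits, true score and category, latent frailty, uncensored
event time) is attached as `attr(cohort, "truth")`.

**Survival.** Exponential (optionally Weibull) hazards
$h_i(t) = h_0 \exp(\beta_r\,\text{readmit}_i + \beta_d\,\text{score}_i)$
with defaults $\beta_r = \log 2$, $\beta_d = 4$, administrative censoring
at 450 days plus 15% uniform loss to follow-up, and day-level recording
(`ceiling`, minimum 1 day), which deliberately produces heavy ties.
$h_0 = 1.67\times 10^{-4}$ was calibrated once, by simulation at large
$n$, to give roughly 41% observed deaths under the default configuration;
with $\beta_d$ set to 0 (all covariates noise, readmission's total true
hazard ratio exactly 2.0 — the configuration used for recovery tests)
the corresponding calibration is $h_0 = 8.5\times 10^{-4}$. Missingness
masks are MCAR at per-variable rates; `missingness = numeric(0)` yields a
complete cohort.

Because the single shared factor makes most covariates genuinely
prognostic, a 270-patient default cohort routinely selects more than 13
covariates at the screen — which is why the pipeline's trim policy
exists, while the hard cap remains the API default.

## 5. Default problem sizes

The defaults — $n = 270$, a 50/50 readmission split, 23 factors, an
18-of-23 completeness floor, 13-covariate cap, $m = 20$ imputations —
are package choices tuned to a mid-sized single-center oncology cohort;
all are arguments, none are hard-coded.

## 6. Limitations

- Proportional hazards throughout; no time-dependent covariates, no
  competing risks.
- The screen-then-model workflow inherits the usual caveats of
  significance-driven selection; it is provided because it matches
  standard clinical practice, not because it is optimal.
- MCAR missingness in the generator (and PMM under MAR in the imputer)
  are simplifications; informative missingness is out of scope.
- The latent one-factor dependence structure is a modeling convenience;
  real deficit correlations are not exchangeable.
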