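---
title: "Hydration adjustment of spot-urine biomarkers: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration adjustment of spot-urine biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydradjust)
```

## The dilution model

Spot-urine analyte concentrations confound exposure with hydration: a
well-hydrated volunteer excretes the same analyte mass into more water.  The
package is built around the empirical log-linear dilution model

$$\ln C = a - b \,\ln \mathrm{UFR} + \varepsilon,$$

where $C$ is the volume-based concentration (µg/L), $\mathrm{UFR}$ the
urinary flow rate (mL/min, void volume over time since the previous void)
and $b$ a dimensionless, analyte-specific exponent.  If $b$ were 1,
concentrations would vary inversely with flow and the classical excretion
rate $ER = C \cdot V / t$ would remove dilution exactly.  Empirically $b$ is
well below 1 for most analytes, which is why ER over-compensates: it
replaces a negative correlation with flow by a positive one of similar
magnitude.  The power-law adjustment $C_{\mathrm{adj}} = C \cdot
\mathrm{UFR}^{\,b}$ standardises concentrations to a flow of 1 mL/min and
contains the unadjusted ($b=0$) and ER-like ($b=1$) behaviours as special
cases.

All logarithms in the package are natural logs.  The exponent is invariant
to the base as long as both sides of the regression share it, and every
downstream correlation is computed on ln-transformed data.

## Estimating the exponent from single voids

With one void per person, $b$ cannot be estimated within individuals.  The
package derives population-level exponents by profiling: since
$\ln(C\,\mathrm{UFR}^b) = \ln C + b \ln \mathrm{UFR}$ is linear in $b$, the
Pearson correlation of the adjusted series with a chosen target is computed
at every grid point $b \in \{0, 0.01, \dots, 1.5\}$ and optimised under

* **criterion A**: minimise $|r|$ against $\ln \mathrm{UFR}$ — the adjusted
  value should carry no dilution signal; or
* **criterion B**: maximise the signed $r$ against the ln blood
  concentration of the same analyte — blood is an independent measure of
  internal dose, so a good adjustment should agree with it more strongly.

Criterion A admits a closed form.  Writing $s_{cu} =
\operatorname{cov}(\ln C, \ln U)$ and $s_u^2 = \operatorname{var}(\ln U)$,
the correlation of the adjusted series with $\ln U$ is

$$r(b) = \frac{s_{cu} + b\,s_u^2}
  {\sqrt{(s_c^2 + 2b\,s_{cu} + b^2 s_u^2)\, s_u^2}},$$

whose numerator is linear and strictly increasing in $b$ while the
denominator is positive, so $r(b)$ is non-decreasing with a single sign
change at $b^* = -s_{cu}/s_u^2$ — the negated least-squares slope of
$\ln C$ on $\ln \mathrm{UFR}$.  The grid optimum is therefore the grid point
nearest $b^*$ (clipped to $[0, 1.5]$), which the test suite verifies on
randomised instances.  `closed_form_b()` exposes $b^*$ as an analytic
cross-check; refinement beyond the 0.01 grid is deliberately not performed,
keeping the estimator faithful to the published numeric method.

Two conventions the grid search needs are worth stating.  Ties break to the
smallest $b$, making results deterministic.  And when the adjusted series is
exactly constant (noise-free cancellation at $b = b^*$), its correlation is
undefined; the package defines it as 0, which is the value the surrounding
grid points approach.

Criterion B has no closed form and is taken directly from the grid maximum
of the signed correlation — not $|r|$, so a pathological negative optimum is
reported rather than silently flipped.

## Eligibility cascade

Kidney disease and diabetes distort both creatinine excretion and
glomerular filtration, undermining every adjustment method, so cohorts are
filtered before estimation:

1. **albuminuria**: urinary albumin-creatinine ratio strictly greater than
   30 mg/g (mg/L over g/L gives mg/g directly);
2. **diabetes**: self-report, or plasma glucose ≥ 126 mg/dL after ≥ 8 h
   fasting, or ≥ 200 mg/dL otherwise (thresholds inclusive);
3. **chronic kidney disease**: self-report or eGFR strictly below
   60 mL/min/1.73 m², using the 2009 CKD-EPI equation for adults and the
   Bedside Schwartz equation (0.413·height/Scr) below age 18;
4. **non-detects**: volunteers lacking a detected value for any of urinary
   Pb, Cd, total As or I are removed, limiting censoring artefacts in the
   correlation analyses.  Total As (rather than the AsIMM composite) gates
   this rule.

The 2009 CKD-EPI variant with the race coefficient is used deliberately: it
matches the three-ethnicity survey designs this workflow targets and is
documented as historically faithful rather than current clinical practice.
Records missing a covariate needed by a rule either raise an error naming
the record and field (strict mode, the default) or are dropped with reason
`missing:<field>` — survey codebooks differ too much for the package to
guess.  Every removal is recorded with its triggering rules, and the audit
reconciles exactly: initial count = final count + sum of removals.

## Assessment battery

Performance is always assessed on a held-out testing split (default 20%,
`round(fraction·n)` with R's round-half-even; the exact counts a different
partitioning tool would produce may differ by a record or two).  Exponents
are derived on the training split only; both `araki_b()` and
`evaluate_methods()` refuse provenance-tagged testing data to prevent
leakage.

For each method and analyte the package reports the ln-scale Pearson
correlation with UFR (criterion A) and, for blood-paired analytes, with the
blood concentration (criterion B), with two-sided p-values from the
t-approximation and 95% intervals via the Fisher z transform with the 1.96
normal quantile.  Because all series are logged, correlations are invariant
to multiplicative unit changes — blood Pb in µg/dL against urine in µg/L
needs no conversion, and ER/ERBW enter as $\ln ER = \ln C + \ln UFR +
\text{const}$ so every method is compared on the same footing.

Correlations of competing methods with a shared variable are dependent, so
pairwise comparisons use the Hotelling–Williams statistic

$$t = (r_{12} - r_{13})\sqrt{\frac{(n-1)(1+r_{23})}
 {2|R|\frac{n-1}{n-3} + \bar r^2 (1-r_{23})^3}},
 \qquad df = n - 3,$$

with $|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13} r_{23}$
and $\bar r = (r_{12}+r_{13})/2$.  The implementation is validated by
simulation (type-I error at the nominal 5% level under a trivariate normal
null) rather than by matching any particular software's internals.  The
pairwise pattern at $\alpha = 0.05$ is rendered as a compact letter display
via insert-and-absorb; no family-wise correction is applied beyond the
pairwise tests, mirroring standard practice for these tables.  Two methods
whose grids land on the same exponent produce numerically identical series;
their comparison is defined as non-significant rather than attempted.

## The synthetic cohort generator

`generate_cohort()` draws volunteers from the generative inversion of the
dilution model: $\ln \mathrm{UFR} \sim N(\mu_u, \sigma_u)$, and per analyte

$$\ln C = a + D - b_{\mathrm{true}}\,\ln \mathrm{UFR} + e,\qquad
  D \sim N(0, \sigma_{\mathrm{dose}}),\; e \sim N(0, \sigma_{\mathrm{noise}}),$$

where $D$ is a latent internal dose.  Blood concentrations are generated
from the same $D$ (correlation `blood_coupling`), which is what gives
criterion B something real to detect; creatinine and osmolality get their
own dilution blocks so they act as imperfect flow-rate surrogates exactly as
they do in real data.  Exclusion covariates are constructed to trigger each
eligibility rule at a configured marginal rate, independently of the
dilution variables (no joint structure is assumed).  Concentrations below
the detection limit are stored at the limit and flagged, never zeroed.

Default scales are chosen to resemble a US population survey: geometric
means of 0.7 mL/min (UFR), 1.1 g/L (creatinine), 635 mOsm/kg (osmolality),
0.5/0.2/6.3/149 µg/L for urinary Pb/Cd/AsIMM/I, 1.1 µg/dL and 0.3 µg/L for
blood Pb and Cd, and exponents 0.38 (Pb), 0.32 (Cd), 0.27 (AsIMM), 0.45
(I), 0.52 (creatinine).  The dose and noise dispersions
($\sigma_{\mathrm{dose}} \approx 0.7{-}0.85$,
$\sigma_{\mathrm{noise}} \approx 0.45{-}0.55$ on the ln scale) are free
parameters, not survey-derived: they were fixed once so that the ln-scale
spread matches the several-hundred-fold concentration ranges such surveys
report, with the latent dose dominating residual noise.  Arsenic species
are split from the AsIMM total in fixed proportions
(DMA 75%, MMA 14%, AsIII 8%, AsV 3%), so the composite inherits the
dilution structure exactly — in particular, noise-free parameter-recovery
tests stay exact.  Marginal ranges are not truncated to match any printed
range; only the correlation structure matters downstream.

What the generator does **not** emulate: survey weights and clustering,
multiple voids per volunteer across hydration states, dependence between
internal dose and flow rate, and demographic heterogeneity in the
exponents (all strata share $b_{\mathrm{true}}$ unless a test constructs
otherwise).  Passing tests therefore demonstrate the estimator and
assessment machinery, not the field validity of any particular exponent.
One consequence worth flagging: with dose independent of flow, the
criterion-A slope estimator stays unbiased no matter how large
$\sigma_{\mathrm{dose}}$ grows — dose dispersion only dilutes $r^2$.  In
real pooled data, where dose and hydration behaviour may covary, the
population-level exponent can be biased relative to the within-individual
one; the generator reproduces the variance-dilution mechanism but not that
bias.

## Numerical and design choices

* **Grid**: inclusive endpoints $\{0, 0.01, \dots, 1.50\}$, 151 points;
  step and range are configuration, with the published defaults surfaced in
  `pipeline_config()` rather than buried as literals.
* **Reference osmolality**: computed from the training split's median at
  run time; 734 mOsm/kg is accepted as a fixed conventional value for
  comparability with published adjustments.
* **Non-detect policy inside the AsIMM sum**: configurable as-is (default),
  LOD/√2, or zero.  Species below detection are stored at the LOD, so
  "as-is" sums the placeholder — the least-assumption default given that
  survey documentation rarely states what was summed.
* **Units**: µg/L ≡ ng/mL is made explicit; ER in ng/hr equals
  60 · C(ng/mL) · UFR(mL/min), and the 60× minute-to-hour factor is tested
  to 1e-12.
* **Age bands**: 6–11, 12–19, 20–39, 40–59, >60 years, by completed years
  (`floor(age)`), so fractional ages cannot fall between bands.
* **Subgroup derivation**: groups below 4 records are skipped with a
  warning, not an error; for criterion A the p-value of the underlying
  regression slope is reported per subgroup, because an insignificant slope
  means the subgroup optimum mostly reflects sampling noise — small-group
  exponents should be read with that column in view.
* **CKD-EPI outside its age range**: calling the adult equation below 18
  warns and directs to Schwartz rather than erroring, so that textbook
  coefficient checks at hypothetical ages remain possible; the cascade
  itself always routes by age.

## Problem sizes used in the checks

The test suite exercises the estimator at the scales the workflow is
designed for: training-split sizes near 1700, testing splits near 430,
parameter-recovery over 200 replicate cohorts, calibration of the
Williams's test over 10,000 simulated null triples at n = 428, and
grid/closed-form agreement over 1000 randomised instances.  These sizes
were chosen as the smallest at which Monte-Carlo bands are tight enough to
be informative.

## Limitations

The package derives population-level exponents; it cannot recover
within-individual dilution behaviour, for which multiple voids per person
under controlled hydration are required.  The exclusion cascade implements
one published rule set; other studies may need different covariates or
thresholds.  Specific-gravity adjustment and modified
creatinine/specific-gravity schemes are out of scope, as is any
survey-weighted inference.
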