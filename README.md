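# hydradjust

Hydration adjustment of spot-urine biomonitoring data.

## The problem

Urinary biomonitoring of metals, metalloids and nutrients (Pb, Cd, arsenic
species, iodine, ...) usually relies on spot or first-morning-void samples.
Their concentrations depend not only on exposure but on how dilute the urine
happens to be, which is driven by the urinary flow rate (UFR, mL/min) at the
time of collection.  Several correction schemes are in routine use, with no
consensus on which to prefer:

| method | transform | units |
|---|---|---|
| creatinine | `C / C_cr` | ug/g creatinine |
| osmolality (Levine–Fahy) | `C · Osm_ref / Osm_meas` | ug/L at reference osmolality |
| excretion rate (ER) | `C · V / t` | ng/hr |
| bodyweight-normalised ER | `C · V / (t · BW)` | ng/kg-hr |
| UFR power law (Araki) | `C · UFR^b` | ug/L at UFR 1 mL/min |

The power-law method rests on the empirical log-linear dilution model

```
ln C = a − b · ln UFR
```

with an analyte-specific exponent `b` ("Araki's b").  For population surveys
that collect one void per person, `b` must be derived numerically:
correlations of the adjusted series are profiled over a grid of candidate
exponents (0 to 1.5, step 0.01) and optimised under one of two criteria:

* **criterion A** — minimise `|r_p|` between the adjusted concentration and
  UFR (the adjustment should remove the dilution signal);
* **criterion B** — maximise `r_p` between the adjusted concentration and the
  blood concentration of the same analyte (the adjustment should sharpen the
  agreement with an independent measure of internal dose).

`hydradjust` implements the whole workflow: the eligibility cascade used to
assemble a clean cohort (albuminuria by ACR > 30 mg/g; diabetes by
self-report or fasting-dependent glucose thresholds; chronic kidney disease
by self-report or eGFR < 60 via CKD-EPI / Bedside Schwartz; analytical
non-detect removal), an 80/20 train/test partition, grid derivation of `b`
(globally and per demographic subgroup), every adjustment transform, and a
statistical assessment battery — geometric means, ln-scale Pearson
correlations with Fisher-z intervals, Williams's test for dependent
correlations sharing a variable, and compact letter displays.

A synthetic-cohort generator reproduces the statistical structure the
analysis assumes (log-linear dilution with analyte-specific exponents, a
latent internal dose shared between urine and blood, creatinine and
osmolality as imperfect flow-rate surrogates, demographic strata, exclusion
covariates, censoring), so the full pipeline runs and is testable with no
external data.

## Worked example

```r
library(hydradjust)

ch <- generate_cohort(synthetic_params(n = 2851, seed = 1))
res <- apply_exclusions(ch)
res$cohort
#> Cohort of 2148 volunteer records
#>   source: synthetic
#>   seed:   1
#>   audit:  2851 initial; albuminuria_diabetes_ckd -687, nondetect -16

sp <- split_cohort(res$cohort, fraction = 0.8, seed = 2)
halves <- apply_split(res$cohort, sp)

fit <- araki_b(halves$training, "pb", criterion = "A")
fit
#> Flow-rate exponent profile: analyte pb, criterion A
#>   grid [0, 1.5] step 0.01, n = 1718
#>   b_opt = 0.37  (r at optimum = -0.0018)
```

The cohort was generated with a true Pb exponent of 0.38; the criterion-A
grid search recovers 0.37 from 1718 training records and, by construction,
leaves essentially no residual correlation with flow rate (`r = -0.0018`).
Deriving exponents for all analytes and assessing every method on the
held-out testing split:

```r
bt <- rbind(derive_b(halves$training),
            derive_b(halves$training, analytes = c("pb", "cd"), criterion = "B"))
attr(bt, "split") <- "training"
osm_ref <- median(halves$training$records$osmolality)
evaluate_methods(halves$testing, bt, osm_ref, analytes = "pb")
#> Criterion A (adjusted vs UFR; |r| closer to 0 is better):
#>   pb
#>     ufra       r = -0.014 (-0.108,  0.081)  p = 0.78     a
#>     ufrb       r = -0.058 (-0.151,  0.037)  p = 0.23     b
#>     osmolality r =  0.080 (-0.014,  0.174)  p = 0.096    c
#>     creatinine r =  0.114 ( 0.020,  0.206)  p = 0.018    c
#>     unadjusted r = -0.389 (-0.466, -0.305)  p = 5.9e-17  d
#>     erbw       r =  0.528 ( 0.457,  0.593)  p = 2.8e-32  e
#>     er         r =  0.563 ( 0.495,  0.624)  p = 2.5e-37  f
#> Criterion B (adjusted vs blood; larger r is better):
#>   pb
#>     ufra       r =  0.697 ( 0.645,  0.743)  p = 8.1e-64  a
#>     ufrb       r =  0.697 ( 0.645,  0.742)  p = 1e-63    a
#>     osmolality r =  0.663 ( 0.606,  0.713)  p = 8.8e-56  b
#>     unadjusted r =  0.648 ( 0.590,  0.700)  p = 1.2e-52  bc
#>     creatinine r =  0.605 ( 0.541,  0.662)  p = 2.9e-44  cd
#>     er         r =  0.567 ( 0.499,  0.628)  p = 6.7e-38  d
#>     erbw       r =  0.521 ( 0.448,  0.587)  p = 2.8e-31  e
```

Reading the criterion-A table: unadjusted concentrations correlate
negatively with flow rate (dilution), ER flips that into an equally strong
positive correlation (over-compensation), while the optimised power-law and
osmolality adjustments leave correlations near zero.  Methods share a
letter when their correlations are not significantly different under
pairwise Williams's tests at the 5% level.  `run_pipeline()` performs all
of the above in one call and writes each intermediate artifact (filtered
cohort CSV, split manifest, exponent table, adjusted values, assessment
JSON) plus a manifest with per-file checksums.

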