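# natriuria

Spot-urine estimation of 24-hour urinary sodium excretion in chronic
kidney disease (CKD), and the statistics to validate it.

Monitoring salt intake matters in CKD — most patients are salt-sensitive,
and sodium excess drives hypertension and disease progression — but the
gold-standard 24-hour urine collection is burdensome and often performed
incorrectly. Single-void ("spot") urine samples are the pragmatic
alternative, combined with published equations that predict daily sodium
excretion from a spot concentration plus anthropometry. `natriuria`
implements that whole workflow for tabular cohort data:

* the **Kawasaki**, **Tanaka** and **INTERSALT** prediction equations,
  exactly as published (sex-specific coefficients, the Na/creatinine
  ratio raised to 0.5 / 0.392 for the power forms, the INTERSALT linear
  predictor with its quadratic age term for women, mg/d = 23 × mmol/d),
  with the Kawasaki morning-urine restriction enforced and negative
  INTERSALT estimates flagged rather than clamped;
* **protocol preprocessing** of timed collections: screening (volume
  ≥ 250 ml/d as a daily rate, duration within [20, 28] h) and linear
  correction of excretion totals to 24 h;
* **agreement and diagnostic statistics**: Spearman rank correlation
  (midranks, t-approximation p), Fisher-Z comparison of correlations
  `z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3))`, Bland–Altman
  mean bias with 1.96·SD limits of agreement, ±30% precision (P30), and
  sensitivity/specificity/PPV/NPV at the guideline sodium thresholds of
  2 and 4 g/d (≈5 and 10 g/d salt; 1 g sodium = 2.54 g salt);
* a **seedable synthetic CKD cohort generator** calibrated to the summary
  statistics of a published nephrology-care validation cohort (n = 108,
  66 men, age 62.2 ± 11.9 y,
  BMI 29.7 ± 6.2, 54.6% on diuretics, 24h sodium excretion 19–437 mmol/d),
  with a Gaussian copula controlling the Spearman correlation between
  spot concentrations and daily excretion — the patient-level data are
  access-restricted, so this is what makes the pipeline testable end to
  end;
* an **analysis pipeline** producing tidy report tables (correlations
  with CKD-stage and diuretic strata plus Fisher-Z comparisons,
  per-equation agreement, classification grids) with JSON/TSV/CSV
  writers, `tidy()`/`glance()` methods and `autoplot()` figures.

Everything is data-frame-first and pipe-friendly; results come back as
tibbles.

## Worked example

```r
library(natriuria)

cohort <- simulate_cohort(n = 108, seed = 1)   # synthetic CKD cohort
report <- run_analysis(cohort)                 # screen -> normalise -> estimate -> validate

dplyr::select(report$agreement, formula, timing, n, rho,
              mean_bias, loa_lower, loa_upper, p30)
#> # A tibble: 6 × 8
#>   formula   timing     n        rho mean_bias loa_lower loa_upper   p30
#>   <chr>     <chr>  <int>      <dbl>     <dbl>     <dbl>     <dbl> <dbl>
#> 1 kawasaki  am       108 -0.0000191    -2274.    -7978.     3430.  31.5
#> 2 kawasaki  pm        NA NA               NA        NA        NA   NA
#> 3 tanaka    am       108  0.00781       -647.    -4976.     3682.  38.9
#> 4 tanaka    pm       108  0.227         -551.    -4489.     3388.  45.4
#> 5 intersalt am       108 -0.0493         562.    -3613.     4737.  39.8
#> 6 intersalt pm       108  0.0294         589.    -3282.     4459.  44.4
```

`mean_bias` is measured − estimated in mg/d (positive = the equation
underestimates), `loa_lower`/`loa_upper` are the Bland–Altman 95% limits
of agreement, and `p30` is the percentage of participants whose estimate
falls within ±30% of their measured excretion. The Kawasaki–PM cell is
structurally present but `NA`: that equation is only applicable to
morning urine. On this synthetic cohort, Tanaka-PM shows the strongest
rank correlation with measured excretion and the smallest bias — the
qualitative pattern the equations' validation literature reports —
while the absolute agreement statistics are properties of the simulated
cohort, not reproductions of any patient data.

Comparing two correlations from independent samples (printed r and n are
the inputs; the Z statistic is computed):

```r
fisher_z_compare(0.234, 108, 0.463, 107, labels = c("AM", "PM"))
#> # A tibble: 1 × 5
#>       z p_one_sided p_two_sided label1 label2
#>   <dbl>       <dbl>       <dbl> <chr>  <chr>
#> 1 -1.90      0.0288      0.0576 AM     PM
```

Write a full report to disk (`report.json`, `tables/*.tsv`,
`blandaltman/*.csv`) with `write_report(report, "report/")`, or plot all
Bland–Altman panels with `autoplot(report)`.

A thin command-line wrapper ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/natriuria.R", package = "natriuria"))')
Rscript "$CLI" simulate --n 108 --seed 1 cohort.csv
Rscript "$CLI" analyze --input cohort.csv --out report/
```

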