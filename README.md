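# powerlda

Power-law analysis of limiting dilution assays (LDA) for clonogenic
survival, accounting for cooperative and competitive growth.

## The problem

An LDA seeds a geometric dilution series of single cells into replicate
wells and scores each well as showing clonogenic growth or not. The
classical single-hit Poisson analysis assumes each cell founds a colony
independently with probability *p*, so the expected number of active cells
per well is λ = p·S and the failure fraction is μ = e^(−pS). Real cultures
often violate this: at limiting density, colony formation depends on
neighboring cells and their secreted factors, so clonogenicity per cell
can rise (cooperation) or fall (competition) with seeding density — and
the linear analysis then returns unstable, window-dependent estimates.

powerlda generalizes the mean activity to a power law,

```
λ = p · S^b        ln(−ln μ) = α + b·ln S        α = ln p
```

and fits it as a binomial regression of well failures with a log–log
link. The coefficient *b* quantifies the nonlinearity (b > 1 cooperation,
b < 1 competition, b = 1 the classical model). From a fit it derives

* the **clonogenic activity** a = e^(−α/b), the number of cells to seed so
  that on average one clonogenic cell arises per well (≈37% negative
  wells), with Fieller-type confidence intervals from inversion of the
  link-scale confidence band (or the delta method);
* **survival fractions** SF = a₀/a_t for treated versus untreated groups,
  with 95% intervals combined from the 83.5% activity intervals of
  numerator and denominator;
* a **likelihood-ratio test and ΔAIC** against the nested linear (b = 1)
  model;
* replicate handling (pooling of well counts, or per-replicate analysis
  with t-based intervals) plus a binomial expectation-range diagnostic for
  the pooling decision;
* a seeded **simulator** of LDA count tables and a design-grid explorer
  for precision planning.

Intended users: radiobiology / cancer-biology labs quantifying clonogenic
survival from multiwell dilution assays, and methodologists studying LDA
designs.

## Worked example

A synthetic three-dose experiment (3 biological replicates × 8 dilutions ×
12 wells, generated by the package's own simulator) ships with the
package:

```r
library(powerlda)
path <- system.file("extdata", "synthetic_lda_counts.csv", package = "powerlda")
x <- read_lda_table(path, reference = "0Gy")
x
#> LDA experiment: 72 observations, 9 group(s), 3 treatment(s), reference '0Gy'

pooled <- pool_replicates(x)
f <- fit_loglog_glm(pooled$data[pooled$data$treatment == "0Gy", ])
f
#> Power-law LDA fit (free slope)
#>   alpha = -2.3948 (SE 0.4093), b = 2.3146 (SE 0.3633)
#>   logLik = -6.2620, deviance = 2.4534, AIC = 16.5240, converged = TRUE

clonogenic_activity(f)
#> Clonogenic activity a = 2.814, 95% CI [2.434, 3.254] (band_inversion)
#>   capacity = 35.54% (frequency reading valid only near b = 1; b = 2.315)

survival_table(x, mode = "pooled")
#>   treatment reference    sf ci95_lower ci95_upper   mode n_replicates sem
#> 1       0Gy       0Gy 1.000      0.818      1.222 pooled            3  NA
#> 2       2Gy       0Gy 0.501      0.405      0.616 pooled            3  NA
#> 3       4Gy       0Gy 0.148      0.117      0.186 pooled            3  NA
```

Reading the output: the untreated cells grow cooperatively (b̂ = 2.3 ≫ 1,
SE 0.36), and about 2.8 cells must be seeded per well for one clonogenic
cell on average (95% CI 2.4–3.3). Irradiation at 2 Gy retains 50% of the
clonogenic activity (CI 41–62%), 4 Gy retains 15%. The nested comparison
confirms the nonlinearity is not noise:

```r
compare_models(f, fit_loglog_glm(pooled$data[pooled$data$treatment == "0Gy", ],
                                 slope_fixed = TRUE))
#> LRT free vs fixed slope: delta deviance = 21.2382, p = 4.056e-06, delta AIC = 19.2382
```

The pooling decision can be checked against the intrinsic binomial noise
of well counts — for 12 wells at failure probability 1/3 the central 95%
range is 1–7 negative wells (−2.5 to −0.5 on the ln μ scale):

```r
unlist(binomial_expectation_range(12, 1/3))
#>           lo           hi ln_mu_range1 ln_mu_range2
#>    1.0000000    7.0000000   -2.4849066   -0.5389965
```

A full workflow (fits, activities, survival fractions, model comparison,
log) is one call — `run_analysis("counts.csv", "results/")` — or, from a
shell, the thin wrapper `inst/scripts/powerlda`:

```sh
Rscript inst/scripts/powerlda --input counts.csv --reference 0Gy --out results/
Rscript inst/scripts/powerlda --simulate --p 0.1 --b 1.5 --seed 7 --out sim/
```

See `vignettes/powerlda-methods.Rmd` for the statistical details and the
package's design choices.

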