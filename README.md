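# modalmort

Old-age mortality disparities measured at the **modal age at death**, from
P-spline smoothed mortality surfaces.

## The problem

Disparities in old-age mortality between social groups are usually tracked
with indicators anchored at a fixed "old" age — life expectancy at 65 or
75, or survival to those ages.  As mortality is postponed to higher ages,
a fixed threshold mixes premature with old-age deaths, and the survivors
reaching it become increasingly (and unequally) selected, which muddles
the interpretation of long-run trends.  The adult **modal age at death**
`M` — the age at which the life-table distribution of deaths `f(x)` peaks —
needs no threshold and responds only to mortality at older ages, making it
a cleaner yardstick for monitoring old-age disparities across decades.

`modalmort` is aimed at demographers and epidemiologists with stratified
period mortality surfaces: death counts `D(x,t)` and person-year exposures
`E(x,t)` by single year of age, calendar year, and stratum (sex ×
occupational class, or any comparable grouping).

## Method in brief

1. **Smoothing.** Deaths are Poisson, `D(x,t) ~ Poisson(μ(x,t) E(x,t))`.
   The log hazard is expanded in a tensor-product cubic B-spline basis
   (5-year knots in age and year) and fitted by penalized IRLS with
   order-2 difference penalties on adjacent coefficients — a 2D P-spline.
   The penalty weights `(λ_age, λ_year)` are chosen per stratum by
   minimizing `BIC = deviance + log(n)·ED` over a discrete grid
   (`ED` = trace of the influence matrix, `n` = positive-exposure cells).
2. **Life-table functions.** The smooth hazard is evaluated on a 0.01-year
   grid and completed into survival `S(x) = exp(−∫₃₁ˣ μ)` (radix 1 at age
   31) and the density `f(x) = μ(x)S(x)`.
3. **Indicators.** `M` = argmax of `f` with quadratic sub-grid refinement;
   `SD(M+)` = RMS deviation from `M` among deaths above `M` (old-age
   compression); `e65`, `e75` = conditional life expectancies on the
   *attained-age* scale, `e_x = x + ∫ₓ S/S(x)`; proportions of
   31-year-olds surviving to `M`, 65, and 75; ages at given survival
   probabilities.  Per-year class gaps are tabulated against a reference
   class.
4. **Sensitivity.** Left-truncation of the age domain at 31/35/40 (the
   mode must not move), and 1D-vs-2D smoothing of the `M` trend
   (year-to-year fluctuation, measured as mean squared second difference,
   must shrink under 2D smoothing without losing accuracy).

Because the register data this design targets cannot be shipped, the
package includes a first-class synthetic generator: Gompertz–Makeham
hazards `μ(x,t) = c(1−r_c)^t + a(1−r)^t e^{bx}` per stratum with known
closed-form modes, calibrated so six occupational strata show modes rising
from the mid/high 70s (1971) to the mid 80s (2017), a 4-year (men) and
2-year (women) class gap, and a survival-to-mode proportion just below
40% — with Poisson counts at register-like exposures.

## Worked example

```r
library(modalmort)

ds  <- finnish_like_scenario(seed = 1)            # 6 strata, 1971-2017
run <- run_full(ds, pipeline_config(verbose = FALSE))

print(run$fits[["male_manual"]])
#> 2D P-spline fit [male_manual]: lambda = 1e+06/1e+06, ED = 9.41,
#>   deviance = 3783.59, BIC = 3861.05

tbl <- run$indicators
tbl[tbl$stratum %in% c("male_upper_nonmanual", "male_manual") &
    tbl$year %in% c(1971, 2017), ]
#>              stratum year     M sd_above_M   e65   e75 p_surv_M p_surv_65 p_surv_75 gap_M
#> male_upper_nonmanual 1971 78.03       6.94 77.65 81.99     0.37      0.78      0.49  0.00
#> male_upper_nonmanual 2017 86.40       6.95 83.77 86.60     0.37      0.90      0.74  0.00
#>          male_manual 1971 74.01       6.95 75.14 80.29     0.37      0.69      0.33  4.02
#>          male_manual 2017 82.39       6.95 80.70 84.22     0.37      0.85      0.63  4.02

max(tbl$p_surv_M)
#> [1] 0.3718
```

Reading the numbers: each stratum's BIC-selected fit smooths heavily
(`ED ≈ 9` effective parameters for 3,760 cells) because the generating
surface is log-bilinear.  The modal age `M` rises by ~8.4 years over the
period while the class gap in `M` stays fixed at ~4 years; the proportion
surviving from 31 to `M` sits at 0.37 ("just below 40%") in **every**
stratum-year, while survival to 75 climbs from 0.33 to 0.63 (manual men) —
the contrast that makes fixed-threshold indicators hard to compare over
time and `M` easy.

## The analysis, step by step

Numbered drivers under `analysis/` run the whole study and write tables
under `results/` (created on demand):

```sh
Rscript analysis/01_simulate.R               # dataset + true modes
Rscript analysis/02_fit.R                    # per-stratum BIC fits (cached as text)
Rscript analysis/03_indicators.R             # indicator trends + class gaps
Rscript analysis/04_truncation_sensitivity.R # M under start ages 31/35/40
Rscript analysis/05_compare_smoothers.R      # 1D vs 2D M-trend roughness
```

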