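# gxepref

Gene-by-environment analysis of risk and time preferences in R.

## What this package is for

A recurring question in behavioral genetics and economics is whether genetic
variation linked to cognitive and educational success predicts economic
preferences — risk aversion and patience — the same way in every
developmental environment, or whether childhood adversity redirects or mutes
its expression. Answering it requires an unusual combination of machinery:

* **Instrument inversion.** Incentivized elicitation tasks do not observe a
  preference parameter directly. A six-lottery ordered-choice task (choose
  one of six 50/50 lotteries ordered from safe to risky) brackets a
  constant-relative-risk-aversion coefficient *r*, with utility
  u(x) = x^(1−r)/(1−r) (log x at r = 1): choosing lottery *k* implies that
  *r* lies between the expected-utility indifference points with the
  adjacent lotteries. A multiple price list (£25 sooner vs a rising future
  amount after a delay of *t* weeks) brackets a weekly exponential discount
  rate d = (FV/PV)^(1/t) − 1 at the first switching row.
* **Polygenic scores.** PGS_i = Σ_j W_j G_ij over an allele-count matrix,
  standardized within sample, with ancestry principal components as
  population-structure controls.
* **Group-varying likelihood fits.** The between-family GxE specification
  Y_ig = α(g)·PGS_ig + X_ig b(g) + ε_ig, in which *every* parameter may
  differ between the disadvantage groups, estimated by interval-censored
  Gaussian regression (interval outcomes), logistic regression (binary),
  or proportional-odds regression (ordinal), with cluster-robust sandwich
  covariance for repeated observations, implied group effects
  (β_main + β_interaction with delta-method inference), and ±2 SD
  prediction profiles.
* **Sensitivity power analysis.** The smallest Cohen's f² (≈ partial R²)
  detectable at given n, α and power, by noncentral-F inversion with
  λ = f²·n.
* **A synthetic cohort generator** that emulates this entire statistical
  structure — genotypes, weakly PGS-correlated disadvantage dimensions with
  missingness, latent preferences, and rendered instrument responses with a
  truth sidecar — so each stage is testable without restricted survey data.

All of it is exposed through one modelling interface, `gxe_fit()`, plus
instrument, scoring, simulation and pipeline functions.

## Worked example

```r
library(gxepref)

# the bundled six-lottery instrument and its CRRA partition
menu_crra_intervals(beg_menu())
#>   label        lower     upper
#> 1     A 3.459706e+00       Inf
#> 2     B 1.160648e+00 3.4597059
#> 3     C 7.055819e-01 1.1606478
#> 4     D 4.986117e-01 0.7055819
#> 5     E 2.499973e-10 0.4986117
#> 6     F         -Inf 0.0000000

# a synthetic cohort and the interval-regression GxE fit
sim <- generate(sim_config(n = 400, n_snps = 80), seed = 3)
fit <- gxe_fit(c("beg_lower", "beg_upper"), sim$data, family = "interval",
               covariates = c("age_c", "age_c2", "female"))
summary(fit)
#> Gene-by-environment interval model (n = 400, logLik = -480.65)
#>               estimate       se      z        p
#> (Intercept)    2.24610  0.15378 14.606  < 2e-16 ***
#> disadv         0.30475  0.29772  1.024 0.306028
#> pgs           -0.24418  0.09383 -2.602 0.009256 **
#> pgs:disadv     0.67152  0.18377  3.654 0.000258 ***
#> ...
#> sigma: 1.4156 1.4800
#> Implied predictor effect, moderator = 1: 0.4273 (SE 0.1580, p = 0.00684)
```

The PGS slope is negative (higher score, lower risk aversion) in the
no-disadvantage group, the interaction positive and larger in magnitude, so
the implied slope in the disadvantage group is positive — the sign-reversal
pattern the generator's defaults encode. `predict(fit)` / `plot(fit)` give
the crossing ±2 SD prediction profiles, and

```r
sensitivity_f2(624)
#> Sensitivity power analysis: n = 624, alpha = 0.05, power = 0.8
#>   detectable f2 = 0.01262 (partial R2 = 0.01246)
#>   lambda = 7.874, F crit(1, 596) = 3.857
```

is the sensitivity power calculation for the experimental-scale sample.

`run_pipeline(seed, out_dir)` chains simulate → elicit → score → fit →
report and writes every artifact (per-subject intervals, grouped
correlations, fit summaries, implied effects, prediction profiles, power
report) as CSV plus a JSON manifest; `inst/scripts/gxepref.R` is a thin
command-line wrapper over the same functions.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the two
smallest-detectable-effect-size values (experimental and survey sample
sizes) by noncentral-F inversion, after a full end-to-end pipeline smoke
run, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
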