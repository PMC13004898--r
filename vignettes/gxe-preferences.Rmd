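---
title: "Methods: gene-by-environment analysis of economic preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-by-environment analysis of economic preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxepref)
```

# The scientific setting

This package implements the computational chain needed to ask whether a
polygenic score for educational attainment (PGS EA) — a weighted sum of
allele counts capturing genetic variance related to cognitive and
non-cognitive traits — predicts risk and time preferences differently for
people who grew up in disadvantaged versus advantaged childhood
environments. The chain runs from incentivized choice data and genotype
matrices to moderated-regression estimates with implied group effects,
exercised end to end on a synthetic cohort whose statistical structure
mirrors the target design: an experimental cohort of 624 older adults with
lottery and price-list instruments, and a survey cohort of 5,881 persons
(11,521 person-wave observations) with an ordinal planning-horizon item.

# Instruments and their inversion

## The ordered-lottery risk task

Six 50/50 lotteries, A (28, 28) through F (2, 70), ordered by increasing
expected value and spread. Under expected utility with CRRA utility
$u(x) = x^{1-r}/(1-r)$ (and $u(x)=\log x$ at $r = 1$; payoffs integrated
into a background income of zero), each choice brackets $r$ between the
indifference points with the adjacent lotteries. `indifference_r()` finds
those roots by bracketed solving on the continuous-in-$r$ expected-utility
difference; for $r > 1$ both utilities are negative, and the comparison on
signed utilities means the same root applies. `menu_crra_intervals()`
returns the resulting partition of the real line, with the safe choice
unbounded above and the risky choice unbounded below.

Numerical choices: the log case is handled by a limit threshold of
$|r - 1| < 10^{-10}$; roots are solved to $10^{-9}$; a menu whose adjacent
indifference points are not strictly decreasing is rejected as an invalid
instrument. Ties at an indifference point are assigned to the safer
option's interval (intervals closed on the left), a deterministic
convention that preserves the partition.

Two printed-table conventions are worth recording. First, lottery summary
moments use the two-point $n-1$ sample convention,
$SD = |high - low|/\sqrt{2}$: this is the convention under which every
published cell of both lottery tables reproduces at printed precision (the
population convention does not). Second, the loss-aversion variant of the
menu contains negative payoffs, for which CRRA utility is undefined;
consistent with how such tasks are analyzed, that menu is treated
ordinally (choice index, and a binary loss-free-vs-loss collapse,
`la_binary()`), never through the utility function.

## The multiple price lists

Each panel offers £25 at a sooner date against a rising future amount after
a common delay, and the first switch to the future option brackets the
weekly exponential discount rate $d = (FV/PV)^{1/t} - 1$. The sooner date
is two weeks out and the future dates one and two months, but the exact day
counts behind the published bounds are not stated. We therefore treat the
delay as instrument configuration, not a code constant, and calibrated it
once by least squares of $1/t$ against the twelve published bounds: the
fitted values are 2.4305 and 6.7105 weeks, and the configured values
$t = 2.43$ and $t = 6.71$ reproduce all twelve bounds to four decimals.
They are stored in `inst/extdata/instruments.json`.

Never-switchers keep a half-infinite interval — the interval likelihood
handles one-sided censoring, so nothing is imputed. Non-monotone choice
patterns are coded by the same first-switch rule and flagged; the flag is
meant to enter downstream fits as a control covariate (the pipeline's
discount-rate models include it).

## Disadvantage index

Four binary childhood-disadvantage dimensions (parental human capital,
carer occupation, housing amenities, family instability) are combined into
a count and a binary indicator for two or more dimensions. Missingness is
resolved by policy: missing-as-zero (default, preserving sample size), a
missing-indicator variant, or complete-case flagging. Threshold and policy
are arguments, not constants.

# Genetics

`compute_pgs()` is the weighted allele-count sum, standardized within the
provided sample — the standardization population of deposited scores is
generally unstated, so within-sample is the only defensible default.
`ancestry_pcs()` takes the top-k components of the column-standardized
(mean/SD of counts) genotype matrix; allele-frequency scaling is a
documented alternative we did not adopt because the upstream procedure is
not specified. Signs are fixed by making each loading vector's
largest-magnitude entry positive, so results are deterministic.
Group descriptives use the pooled-variance two-sample t (df = n − 2, the
convention matching published df) with Cohen's d, and Pearson correlations
with t-based p and Fisher-z CIs.

# The three likelihoods

All outcomes are fit by maximum likelihood with a shared machinery:
BFGS with analytic gradients, followed by Newton polishing on a
finite-difference Hessian until the gradient's largest component is below
$10^{-6}$ (fits abort rather than return if it exceeds $10^{-4}$).
Covariance is the inverse observed information; scale parameters are
optimized on unconstrained transforms (log σ; log threshold differences)
and reported on the natural scale by the delta method.

* **Interval regression** (`fit_interval()`): Gaussian latent
  $Y^* = X\beta + \varepsilon$; point rows contribute the density,
  half-infinite rows one-sided censoring probabilities, finite intervals
  normal-CDF differences, all computed in log space with tail-stable
  differencing. Starting values are OLS on interval midpoints (the finite
  bound for half-infinite rows). Rows with both bounds infinite, or data
  censored entirely on one side, are rejected as degenerate.
* **Logistic regression** (`fit_logit()`): Newton–Raphson with step
  halving; perfect separation is detected (fitted probabilities collapsing
  onto the outcome at extreme linear predictors) and raised as an error
  rather than silently returning divergent coefficients.
* **Ordered logistic regression** (`fit_ologit()`): proportional odds with
  strictly increasing thresholds via the log-difference reparameterization;
  with two categories it reduces exactly to the binary logit (a tested
  identity).

The proportional-odds diagnostic (`prop_odds_test()`) is a likelihood-ratio
comparison of common versus category-specific slopes, both fitted on the
stacked cumulative binary splits with split-specific intercepts, df =
(J−2)·p. Because each observation is reused across splits, the chi-square
reference is approximate (typically somewhat anticonservative); the result
carries that caveat, and sparse splits skip the test with a warning.

# The gene-by-environment layer

`build_gxe_design()` constructs the fully interacted design in a fixed
order — intercept, moderator, predictor, predictor×moderator, then each
covariate with its moderator product — so that the predictor's coefficient
is its association in the no-disadvantage group and the interaction the
group difference. `gxe_fit()` is the central fitting function; for the
interval family the error SD is by default group-specific. The rationale:
"all parameters may differ across environments" is only exactly equivalent
to separate group-wise estimation if σ differs too, and that equivalence
(identical maximized likelihood and group-specific estimates) is a tested
invariant. A shared-σ option is retained since the original convention is
not stated.

`implied_effect()` returns $\beta_{main} + \beta_{interaction}$ with
delta-method variance $V_{mm} + V_{ii} + 2V_{mi}$ (identical, by
reparameterization, to refitting with the moderator baseline flipped —
also a tested identity), two-sided normal p-values, and odds ratios for
logit families. `predict()`/`plot()` produce model-scale profiles over a
±2 SD PGS grid per group with covariates at estimation-sample means; the
covariate policy is configurable because published prediction figures
rarely state it. `cluster_vcov()` is the cluster sandwich with
cluster-summed scores and small-sample factor G/(G−1); scores are obtained
by central finite differences of the per-row log-likelihood at the MLE,
which keeps one code path correct for all three families.

# Sensitivity power analysis

`sensitivity_f2()` inverts the noncentral-F power function: the smallest
f² such that a noncentral F(1, n − n_params) with λ = f²·n exceeds the α
critical value with the target probability. Two conventions needed pinning:
λ = f²·n (rather than f²·df_den), and a default parameter count of 28 (the
fully interacted design with 10 ancestry PCs). Both printed reference
values (0.013 at n = 624, 0.001 at n = 11,521, to 3 decimals) reproduce
under these choices, and the result is insensitive to the parameter count
between 5 and 30. f² and partial R² = f²/(1+f²) are both reported; at
these magnitudes they agree to the printed rounding of f².

# The synthetic world

The generator's defaults are a stated world, chosen once:

* Disadvantage prevalences 0.498/0.276/0.237/0.152 (the experimental-sample
  dimension rates) with the ≥2-of-4 binary; dimensions are generated
  individually (not the index directly) so that all three missingness
  policies are exercisable; per-dimension intercepts are root-found to hit
  the marginal prevalences at the configured PGS slope.
* The PGS→disadvantage log-odds slope is −0.10, calibrated once (n =
  400,000 draws) so the PGS × binary-index correlation is ≈ −0.07, the
  small gene–environment correlation the design must tolerate.
* Per-dimension missingness 0.09, reproducing the observed "about 29%
  missing one dimension, about 2% missing two" pattern under independence.
* Ages are truncated-normal 64.2 ± 5.6 on [50, 75]; 53.7% female.
* Outcome coefficients per group mirror the published signs and magnitudes:
  CRRA latent slopes (−0.368, +0.431) — a sign reversal; weekly discount
  slopes (−0.021, −0.027) and (−0.011, −0.004) — no reversal; horizon
  slopes (0.199, 0.068) — attenuation. Latent noise SDs (1.4 for CRRA,
  0.05 and 0.03 for the weekly rates) are not published anywhere on the
  latent scale; they were chosen once to spread choices across the
  instrument ranges the way the published response distributions suggest,
  and are documented as presets, not facts.
* Noise families follow the estimators: normal latents for the
  interval-regression outcomes, logistic for the planning-horizon
  propensity. This matters for validation: the binary collapse of a
  proportional-odds latent is exactly a logit with the same slopes, so
  coverage tests for the logit and ordered-logit families use the horizon
  outcome, where the generating interaction is the estimand. The
  loss-aversion ordinal outcome is a thresholded normal latent — fitting
  it by ordered logit is deliberate misspecification of the same kind the
  original ordinal treatment accepts, so it is not used as a coverage
  estimand.
* MPL inconsistency is injected as a single random row flip in 9.6%/7.5%
  of subjects (the observed 60/624 and 47/624 rates), after the monotone
  rule, which produces first-switch-codable patterns; the truth table keeps
  the injected flag.
* The survey preset draws 5,881 persons with a second wave at probability
  0.959 (expected 11,521 rows) and a person-level random intercept
  (SD 0.5) on the horizon propensity, making cluster-robust errors
  consequential.

What a green simulation test does **not** establish: the generator has no
linkage disequilibrium, no genotyping platform artifacts, no attrition
process, and its effect sizes on the latent scale are package presets.
Recovery and coverage results validate the estimators under the assumed
structure; they are not evidence about any real cohort.

# Validation strategy

The test suite asserts, among others: exact reproduction of every published
instrument cell (expected values, SDs, CRRA bounds, all twelve discount
bounds); per-row interval likelihood against adaptive quadrature; the
degenerate-interval = OLS, two-category-ordered = binary-logit, and
singleton-cluster = heteroskedastic-sandwich reductions; equivalence of the
interacted fit with group-wise fits; agreement of all three fitters with
independent implementations (`survival::survreg`, `stats::glm`,
`MASS::polr`) used strictly as cross-checks; round-trip containment of
latent preferences in elicited intervals; and a 200-replicate, n = 5,000
coverage battery for the interaction coefficient in all three families
(93–97% band). The coverage battery runs with a trimmed design and 100
SNPs to stay within a single-CPU test budget; the estimand and band are
unchanged by the trimming because the corresponding generating covariate
effects are set to zero.

# Limitations

Interval fits assume homoskedastic normal latent errors within group;
residual diagnostics are the user's task. The proportional-odds diagnostic
is approximate by construction. The cluster sandwich assumes many clusters
(G/(G−1) is its only small-sample correction). VCF ingestion, GWAS weight
estimation, LD-aware scoring, and within-family designs are out of scope:
genotypes enter as plain count matrices with externally supplied weights.
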