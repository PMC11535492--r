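---
title: "Comparing two binary diagnostic tests from paired data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two binary diagnostic tests from paired data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagpair)
```

## The problem

Two binary diagnostic tests are applied to the same subjects, and a gold
standard (a reference test or clinical diagnosis) defines each subject's true
disease status. Because both tests are read on the same people, their results
are correlated within subject, and naive two-sample comparisons of
sensitivity, specificity, predictive values or likelihood ratios are wrong.
`diagpair` implements the paired-design versions of these comparisons:
estimation with modern confidence intervals, and global-then-individual
hypothesis testing per metric family with multiplicity control.

Everything is computed from the eight *fundamental counts*: the joint
classification of (test 1, test 2) within the gold-positive stratum
(`s11, s10, s01, s00`) and within the gold-negative stratum
(`r11, r10, r01, r00`). With `s` and `r` the stratum totals and
`n1. = n11 + n10` etc. the per-test margins:

* `Se_i` and `Sp_i` are stratum proportions (e.g. `Se1 = (s11+s10)/s`);
* `PPV_i` and `NPV_i` are margin proportions (e.g. `PPV1 = (s11+s10)/n1.`);
* `PLR_i = Se_i/(1-Sp_i)` and `NLR_i = (1-Se_i)/Sp_i` are ratios of
  proportions estimated in independent strata.

## Confidence intervals

### Proportions: a midpoint-modified Wilson interval

All proportion-type metrics (including prevalence) use a modified Wilson
interval with nominal level `1 - alpha`:

$$\tfrac12 + \frac{m + z^2/8}{m + z^2}\Big(\hat p - \tfrac12\Big)
  \;\pm\; \frac{z}{m + z^2}\sqrt{m\,\hat p(1-\hat p) + z^2/4},$$

clamped to `[0, 1]`, where `m` is the relevant denominator and `z` the
`100(1 - alpha/2)`th standard-normal percentile. The half-width is exactly
Wilson's; the midpoint is pulled towards 1/2 slightly less strongly than
Wilson's midpoint (shrink factor `(m + z^2/8)/(m + z^2)` instead of
`m/(m + z^2)`). This midpoint modification improves small-sample coverage
near the boundaries while leaving the large-sample behaviour untouched: as
`m` grows the interval converges to the Wald interval (the test suite checks
agreement within `1e-3` of a half-width at `m = 1e6`), and empirical coverage
at the 95% level stays at or above 0.93 across `p` in {0.1, 0.5, 0.9} and
`m` in {20, 100, 500}.

Setting `conf_int = "classic"` switches every proportion to the exact
Clopper-Pearson interval. Likelihood ratios keep their score-approximation
interval under either setting, because no exact analogue exists for a ratio
of two independent proportions; this is deliberate and documented here.

### Likelihood ratios: a closed-form score approximation

`PLR` and `NLR` are ratios of two independent binomial proportions, so their
intervals come from a closed-form approximation to the score interval for
such a ratio. The computation uses *smoothed counts*: each per-test margin
gains 0.5 and each stratum total gains 1 (`s1.~ = s1. + 0.5`, `s~ = s + 1`,
`n~ = n + 2`), which keeps every quantity strictly positive even with empty
cells, so the intervals are always finite. Writing `A` and `B` for the
smoothed numerator and denominator margins (e.g. for `PLR1`, `A = s1.~` and
`B = r1.~`) and `S`, `R`, `N` for the smoothed totals, the bounds are the
two roots

$$\frac{N A B + \frac{z^2}{2}\big(S A + R B - 2 A B\big)
  \pm z\sqrt{N^2 A B\Big(A + B - \frac{N A B}{S R}\Big)
  + \frac{z^2}{4}\big(S A - R B\big)^2}}
  {B\Big(\frac{N S B}{R} - \frac{3 z^2}{2}\big(S - B\big)\Big)},$$

a second-degree equation in the ratio, which is why these intervals cost
microseconds rather than a model fit. A root can escape the admissible range
for a ratio of proportions, `[A/(N-B), (N-A)/B]`, or cross the smoothed point
estimate; in that case the offending limit is replaced by a boundary
expression that tends to the smoothed point estimate as `z -> 0`
(`lr_lower_fallback()` / `lr_upper_fallback()` in the source). Square-root
arguments in the fallbacks are clamped at zero and all bounds at zero from
below. On well-populated tables, such as the bundled CASS data, the
fallbacks never trigger.

## Hypothesis testing

Each enabled family is tested globally first; individual member comparisons
are *always computed and stored*, but they are only "evaluated" (narrated by
the interpreter, used for conclusions) when the global null is rejected.
This ordering controls the error rate of the family-level question that the
study actually asks.

* **Diagnostic accuracies.** The global null `Se1 = Se2 and Sp1 = Sp2` uses
  a Wald statistic that is the sum of the two stratum components, e.g.
  `(Se1-Se2)^2 / Var(Se1-Se2)` with the paired-multinomial variance
  `[(s10+s01) - (s10-s01)^2/s] / s^2`; the strata are independent, so the sum
  is chi-square with 2 df and the decomposition is an exact identity (tested
  on 1000 random tables). Individual comparisons follow the sample-size rule
  established in the simulation literature for this design: Wald when
  `n <= 100` or `n >= 1000`, McNemar (continuity-corrected by default) in
  between; when prevalence is below 10% *and* `n < 100`, the global step is
  skipped and the two Wald tests are reported directly. Boundary values
  (`n` exactly 100 or 1000, prevalence exactly 10%) take the first branch
  that admits them, i.e. Wald and the global-first pathway respectively.
  Individual statistics are referred to chi-square with 1 df, never to the
  normal; with the continuity-corrected McNemar statistic for the CASS
  specificities (0.0111) this gives p = 0.92, which is the behaviour we
  consider correct for these statistics.

* **Predictive values.** The global null `PPV1 = PPV2 and NPV1 = NPV2` uses
  a Wald statistic on the vector of differences with a delta-method
  covariance from the joint multinomial over the eight cells (chi-square,
  2 df). Individual comparisons use a weighted generalized score statistic:
  the two predictive values being compared are proportions over
  *overlapping* cohorts (subjects positive on both tests belong to both PPV
  cohorts), so the null variance combines the pooled proportion - weighted
  by cohort size - with an empirical covariance contributed by the shared
  subjects, each evaluated under the pooled null.

* **Likelihood ratios.** The global test works on
  `(log(PLR1/PLR2), log(NLR1/NLR2))`. Each log-ratio decomposes into
  independent diseased and non-diseased parts (e.g.
  `log PLR1 - log PLR2 = log Se1 - log Se2 - log(1-Sp1) + log(1-Sp2)`),
  and the covariance of the pair comes from the delta method on the two
  stratum multinomials; the global statistic is chi-square with 2 df and
  each log-ratio is then tested on 1 df. Raw proportions are used whenever
  they are all inside (0, 1); if any would make a logarithm infinite, the
  smoothed proportions described above are substituted. The delta-method
  variance is validated against a 10,000-replicate parametric bootstrap
  (agreement within 5%).

### Multiplicity

Two natural families exist in one call: the set of global tests that were
requested, and, within each family, the two member comparisons. Both are
adjusted with the method in `multi_corr` (default Holm, any
`stats::p.adjust` method). This matches the shape of the output - one
adjusted p per global test, one per member - while keeping each family
small and interpretable. The `equal` flag summarises the run: `TRUE` exactly
when no executed global test rejects at `alpha` after adjustment.

## Data preparation choices

Input is subject-level and tabular: one row per independent subject, columns
for test 1, test 2 and the gold standard, coded with any mix of the accepted
synonyms (case- and whitespace-insensitive; numeric `2` means negative, so
1/2 and 0/1 coding may coexist in one column - accepted deliberately, since
secondary analyses often merge sources with different conventions). When no
columns are designated, columns 1-3 are used with a warning. Missing values
are a hard error, never dropped: the choice among complete-case analysis and
imputation belongs to the analyst, not to this package. Pre-tabulated data
enter through `fundamental_counts()` and `compare_tests(counts = )`.

Internally every metric lives on the 0-1 scale at full precision;
multiplication by 100 and rounding to `dp` decimals happen only in display
methods, and the JSON rendering (`render(x, "json")`) is unrounded, so the
whole analysis can be reproduced bit-identically from it
(`parse_comparison()`).

## The simulator

`sim_scenario()` + `sample_counts()` generate fundamental counts under a
known truth for coverage, type-I-error and power studies: disease status is
`Binomial(n, prevalence)`, and each stratum's four cells are multinomial
with margins fixed by the accuracies and the within-stratum correlation
expressed as a phi coefficient, e.g.
`p11 = Se1*Se2 + rho_d*sqrt(Se1(1-Se1)Se2(1-Se2))` among the diseased.
Infeasible accuracy/correlation combinations are rejected at construction.
One integer seed fully determines a draw and the caller's RNG state is
restored afterwards.

What the generator emulates - and what it does not: it reproduces the
sampling structure of a paired accuracy study (correlated within-subject
results, binomial disease status), but not covariate-dependent accuracy,
spectrum effects, imperfect gold standards or verification bias. Passing
simulation-based tests therefore demonstrates the frequentist calibration of
the methods under the design they assume, not robustness to those
violations.

Problem sizes used by the shipped verification suite were chosen to be
informative yet quick: coverage over `p` in {0.1, 0.5, 0.9} and `m` in
{20, 100, 500} with 2,000 replicates; type-I error of the three global tests
at `n = 500`, prevalence 0.5, accuracies 0.8/0.7 and within-stratum
correlation 0.25 (a realistic paired design) with 2,000 replicates, judged
against a three-standard-error Monte-Carlo band around `alpha`; and a
10,000-replicate bootstrap for the delta-method check.

## Numerical and design notes

* Degenerate inputs: a metric with an empty denominator is reported as `NA`
  without suppressing the others; `Sp = 1` makes `PLR` infinite as a point
  estimate while its smoothed interval stays finite; zero discordant pairs
  give a degenerate McNemar statistic (0, p = 1) with a warning; an empty
  predictive-value cohort skips that family with a warning. The number of
  empty cells is reported as `other$zeros` but triggers no correction beyond
  the smoothing already built into the LR machinery.
* The accuracy decision tree's thresholds (100, 1000, 10%) are structural
  constants of the method, not tuning parameters.
* Delta-method Jacobians are computed by central differences at step `1e-7`
  on the probability scale; the functions involved are smooth rational/log
  expressions, so this is accurate to ~1e-9 and keeps the code in one
  generic path.
* The CASS benchmark (exercise stress test and chest-pain history versus
  coronary angiography, 871 subjects) ships as `cass_counts()` /
  `cass_data()` and is the fixed reference for the estimation and testing
  paths; all its published summary values are asserted in the test suite.

## Known limitations

Unpaired (two-cohort) designs, clustered or replicated observations,
covariate adjustment, ROC/threshold analysis, exact or mid-p McNemar
variants, equivalence (TOST) testing, and bootstrap or Bayesian intervals
are out of scope.
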