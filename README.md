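# diagpair

Compare two binary diagnostic tests evaluated against a gold standard on the
**same subjects** (a paired design). `diagpair` is aimed at clinicians and
applied researchers developing or evaluating diagnostic tests: it takes a
plain data frame of subject-level results, tolerates almost any sensible
coding of positive/negative ("pos"/"neg", y/n, 0/1, 1/2, TRUE/FALSE, ...),
and returns, in one call, everything a diagnostic-accuracy comparison
normally reports.

## What it computes

From the eight fundamental counts — the joint classification of
(test 1, test 2) within the gold-positive stratum (`s11, s10, s01, s00`) and
the gold-negative stratum (`r11, r10, r01, r00`) — it estimates, for each
test *i*:

- sensitivity `Se_i` and specificity `Sp_i`,
- predictive values `PPV_i`, `NPV_i`,
- likelihood ratios `PLR_i = Se_i/(1−Sp_i)`, `NLR_i = (1−Se_i)/Sp_i`,
- plus cohort prevalence and the Youden indices `J_i = Se_i + Sp_i − 1`.

Proportions get a midpoint-modified Wilson confidence interval (Wilson's
half-width with midpoint shrink `(m+z²/8)/(m+z²)` towards 1/2; Clopper–
Pearson available via `conf_int = "classic"`). Likelihood ratios get a
closed-form approximation to the score interval for a ratio of independent
binomial proportions, computed on smoothed counts (margins + 0.5, totals + 1)
so it is always finite.

Inference is *global-then-individual* per metric family, with Holm (or any
`p.adjust`) multiplicity control:

- accuracies: paired-multinomial Wald global test (2 df); individual tests
  are Wald or continuity-corrected McNemar depending on sample size;
- predictive values: delta-method Wald global test; individual comparisons
  via a weighted generalized score statistic for overlapping cohorts;
- likelihood ratios: Wald tests on `log(PLR1/PLR2)` and `log(NLR1/NLR2)`
  with delta-method covariance.

A correlated paired-multinomial simulator (`sim_scenario()`,
`sample_counts()`) supports coverage, type-I-error and power studies.

## Worked example

The bundled CASS data (871 subjects; exercise stress test and chest-pain
history versus coronary angiography) reproduce a classic benchmark:

```r
library(diagpair)
res <- compare_tests(cass_data(), test1 = 1, test2 = 2, gold = 3,
                     ppvnpv = FALSE, plrnlr = FALSE)
res
```

```
----------------------------------------------------------------------
PREVALENCE (%)
----------------------------------------------------------------------

           Estimate  SE Lower CI Upper CI
Prevalence     69.8 1.6     66.7     72.8

----------------------------------------------------------------------
DIAGNOSTIC ACCURACIES
----------------------------------------------------------------------

Test 1 (%)
            Estimate  SE Lower CI Upper CI
Sensitivity     82.6 1.5     79.4     85.4
Specificity     74.1 2.7     68.6     79.1

Test 2 (%)
            Estimate  SE Lower CI Upper CI
Sensitivity     91.1 1.2     88.6     93.2
Specificity     74.9 2.7     69.4     79.8

Global null hypothesis: Se1 = Se2 & Sp1 = Sp2
Test statistic: 25.662  Adjusted p value: 2.676497e-06 ***SIGNIFICANT***

Investigating cause(s) of significance

Null hypothesis 1: Se1 = Se2
Test statistic: 23.64545  Adjusted p value: 2.316383e-06 ***SIGNIFICANT***

Null hypothesis 2: Sp1 = Sp2
Test statistic: 0.01111111  Adjusted p value: 0.9160511

Alpha: 0.05   Tests equivalent: FALSE   Empty cells: 0
Youden index Test 1: 0.5671028   Test 2: 0.6602336
```

Reading: about 70% of the cohort is angiography-positive; the chest-pain
history (test 2) is significantly more sensitive than the stress test
(91.1% vs 82.6%, McNemar statistic 23.6), while their specificities are
indistinguishable (74.1% vs 74.9%). The global 2-df statistic 25.662
decomposes exactly into its sensitivity and specificity components.

Other entry points:

```r
interpret(res)                     # the same, with a plain-English epilogue
tidy(res); glance(res)             # broom-style tibbles
autoplot(res)                      # bar chart with CI whiskers
summarise_test(cass_data()[, c("test1", "gold")])  # one test, descriptives only
render(res, "json")                # full-fidelity serialisation
```

A thin command-line front end ships in `inst/cli/diagpair`
(`diagpair compare input.csv --interpret`, `diagpair summarise input.csv`).

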