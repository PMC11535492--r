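test_that("McNemar statistics match the published CASS values", {
  expect_equal(mcnemar_stat(29, 81, cc = TRUE)$statistic, 23.64545,
               tolerance = 1e-6)
  expect_equal(mcnemar_stat(46, 44, cc = TRUE)$statistic, 0.01111111,
               tolerance = 1e-6)
  no_cc <- mcnemar_stat(10, 10, cc = FALSE)
  expect_equal(no_cc$statistic, 0)
  expect_equal(no_cc$p.value, 1)
  expect_warning(deg <- mcnemar_stat(0, 0), class = "diagpair_degenerate_warning")
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p.value, 1)
})

test_that("McNemar without correction dominates the corrected statistic", {
  set.seed(5)
  for (rep in 1:50) {
    b <- rpois(1, 20); c <- rpois(1, 10)
    if (b + c == 0 || b == c) next
    expect_gte(mcnemar_stat(b, c, cc = FALSE)$statistic,
               mcnemar_stat(b, c, cc = TRUE)$statistic)
  }
})

test_that("paired Wald components match direct evaluation of the variance formula", {
  # independent oracle: evaluate the paired-multinomial variance directly
  s <- 608
  se_diff <- (502 - 554) / s
  v <- ((29 + 81) - (29 - 81)^2 / s) / s^2
  expect_equal(paired_diff_wald(se_diff, v)$statistic, se_diff^2 / v)
  expect_equal(se_diff^2 / v, 25.61755, tolerance = 1e-5)
  r <- 263
  sp_diff <- (195 - 197) / r
  vsp <- ((46 + 44) - (46 - 44)^2 / r) / r^2
  expect_equal(sp_diff^2 / vsp, 0.0444520, tolerance = 1e-4)
  expect_equal(paired_diff_wald(0, 0.01)$p.value, 1)
})

test_that("the global accuracy statistic matches the console and decomposes exactly", {
  blk <- test_accuracies(cass)
  expect_equal(round(blk$global$statistic, 3), 25.662)
  expect_equal(blk$global$df, 2L)
  # CASS has n = 871, so individual tests are continuity-corrected McNemar
  expect_identical(unique(blk$members$method), "mcnemar_cc")
  expect_equal(blk$members$statistic, c(23.64545, 0.01111111), tolerance = 1e-6)
  # decomposition identity on random tables
  set.seed(21)
  for (rep in 1:100) {
    fc <- random_counts()
    blk <- test_accuracies(fc)
    comp <- diagpair:::accuracy_wald_components(fc)
    expect_equal(blk$global$statistic,
                 comp$se_diff^2 / comp$se_var + comp$sp_diff^2 / comp$sp_var)
  }
})

test_that("a perfectly symmetric table gives a zero global statistic", {
  fc <- fundamental_counts(40, 10, 10, 5, 5, 12, 12, 60)
  blk <- test_accuracies(fc)
  expect_equal(blk$global$statistic, 0)
  expect_equal(blk$global$p.value, 1)
})

test_that("the decision tree picks Wald or McNemar by sample size and prevalence", {
  scale_to <- function(n) {
    # roughly CASS-shaped table scaled to n subjects
    k <- n / 871
    fundamental_counts(round(473 * k), round(29 * k) + 1, round(81 * k) + 1,
                       round(25 * k), round(22 * k), round(46 * k) + 1,
                       round(44 * k) + 1, round(151 * k))
  }
  n_of <- function(fc) fc_margins(fc)$n
  fc100 <- scale_to(96)   # n <= 100 -> Wald
  expect_identical(unique(test_accuracies(fc100)$members$method), "wald")
  fc500 <- scale_to(500)  # 100 < n < 1000 -> McNemar
  expect_identical(unique(test_accuracies(fc500)$members$method), "mcnemar_cc")
  expect_identical(unique(test_accuracies(fc500, cc = FALSE)$members$method),
                   "mcnemar")
  fc2000 <- scale_to(2000)  # n >= 1000 -> Wald
  expect_gte(n_of(fc2000), 1000)
  expect_identical(unique(test_accuracies(fc2000)$members$method), "wald")
  # boundary: exactly 100 and exactly 1000 use Wald
  fc_b <- fundamental_counts(20, 5, 5, 10, 10, 5, 5, 40)
  expect_identical(n_of(fc_b), 100L)
  expect_identical(unique(test_accuracies(fc_b)$members$method), "wald")
  fc_k <- fundamental_counts(200, 50, 50, 100, 100, 50, 50, 400)
  expect_identical(n_of(fc_k), 1000L)
  expect_identical(unique(test_accuracies(fc_k)$members$method), "wald")
  # low prevalence and n < 100 bypasses the global test
  fc_low <- fundamental_counts(3, 1, 1, 2, 20, 10, 10, 50)
  expect_lt(fc_margins(fc_low)$s / fc_margins(fc_low)$n, 0.10)
  blk <- test_accuracies(fc_low)
  expect_true(blk$bypass)
  expect_null(blk$global)
  expect_identical(unique(blk$members$method), "wald")
})

test_that("predictive-value tests reproduce the published significance pattern", {
  blk <- test_predictive_values(cass)
  expect_lt(blk$global$p.value, 0.05)
  p <- setNames(blk$members$p.value, blk$members$member)
  expect_equal(round(unname(p["PPV"]), 2), 0.37)
  expect_lt(p["NPV"], 0.0001)
  # symmetric construction: PPV1 = PPV2 and NPV1 = NPV2 -> zero statistic
  fc <- fundamental_counts(40, 10, 10, 5, 5, 12, 12, 60)
  expect_equal(test_predictive_values(fc)$global$statistic, 0, tolerance = 1e-12)
  # empty predictive-value denominator skips the family with a warning
  fc_deg <- fundamental_counts(5, 5, 0, 0, 3, 7, 0, 0)  # nobody tests negative
  expect_warning(out <- test_predictive_values(fc_deg),
                 class = "diagpair_degenerate_warning")
  expect_null(out)
})

test_that("likelihood-ratio tests reproduce the published significance pattern", {
  blk <- test_likelihood_ratios(cass)
  expect_lt(blk$global$p.value, 0.05)
  p <- setNames(blk$members$p.value, blk$members$member)
  expect_equal(round(unname(p["PLR"]), 2), 0.37)
  expect_lt(p["NLR"], 0.0001)
  # identical test columns: both log-ratios zero, global statistic zero
  fc <- fundamental_counts(50, 0, 0, 10, 8, 0, 0, 70)
  blk0 <- test_likelihood_ratios(fc)
  expect_equal(blk0$global$statistic, 0, tolerance = 1e-12)
})

test_that("delta-method variance of the log PLR ratio matches a bootstrap oracle", {
  fc <- cass
  p <- diagpair:::lr_cell_probs(fc)
  V <- diagpair:::delta_vcov_probs(p$cells, p$s, p$r,
                                   diagpair:::lr_log_ratios_prob)
  set.seed(99)
  reps <- 10000
  draws_s <- rmultinom(reps, p$s, p$cells[1:4])
  draws_r <- rmultinom(reps, p$r, p$cells[5:8])
  log_ratio <- log((draws_s[1, ] + draws_s[2, ]) / (draws_s[1, ] + draws_s[3, ])) -
    log((draws_r[1, ] + draws_r[2, ]) / (draws_r[1, ] + draws_r[3, ]))
  expect_equal(V[1, 1], var(log_ratio), tolerance = 0.05)
})

test_that("p-value adjustment behaves like the hand-stepped procedures", {
  # Holm by hand: sort 0.01, 0.03, 0.04 -> 0.03, 0.06, 0.06 in input order
  expect_equal(adjust_p(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  expect_equal(adjust_p(c(0.02, 0.02), "bonferroni"), c(0.04, 0.04))
  p <- c(0.001, 0.2, 0.8)
  expect_identical(adjust_p(p, "none"), p)
  expect_error(adjust_p(0.5, "tukey"), class = "diagpair_config_error")
  expect_error(adjust_p(c(0.5, 1.2)), class = "diagpair_config_error")
  # dominance invariants on random p-vectors
  set.seed(123)
  for (rep in 1:50) {
    p <- runif(sample(2:6, 1))
    for (mth in c("holm", "bonferroni", "hochberg", "BH", "BY")) {
      expect_true(all(adjust_p(p, mth) >= p))
    }
    expect_true(all(adjust_p(p, "holm") <= adjust_p(p, "bonferroni")))
  }
})
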