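cass_res <- compare_tests(cass_data(), test1 = 1, test2 = 2, gold = 3)

test_that("a full CASS run reproduces every published summary value at dp = 1", {
  out <- capture.output(print(cass_res))
  txt <- paste(out, collapse = "\n")
  expect_match(txt, "69.8 1.6     66.7     72.8")          # prevalence row
  expect_match(txt, "82.6 1.5     79.4     85.4")          # Se1
  expect_match(txt, "74.1 2.7     68.6     79.1")          # Sp1
  expect_match(txt, "91.1 1.2     88.6     93.[12]")       # Se2
  expect_match(txt, "74.9 2.7     69.4     79.8")          # Sp2
  expect_match(txt, "88.1 1.4     85.2     90.5")          # PPV1
  expect_match(txt, "64.8 2.8     59.3     70.0")          # NPV1
  expect_match(txt, "89.4 1.2     86.7     91.6")          # PPV2
  expect_match(txt, "78.5 2.6     73.0     83.2")          # NPV2
  expect_match(txt, "25.662")                              # global accuracy stat
  expect_match(txt, "23.64545")                            # sensitivity McNemar
  expect_match(txt, "0.01111111")                          # specificity McNemar
})

test_that("disabling families removes their sections without touching the others", {
  acc_only <- compare_tests(cass_data(), test1 = 1, test2 = 2, gold = 3,
                            ppvnpv = FALSE, plrnlr = FALSE)
  expect_true(is.null(acc_only$pv) && is.null(acc_only$lr))
  expect_false(is.null(acc_only$acc))
  expect_setequal(intersect(c("cont", "prev", "acc", "pv", "lr", "other"),
                            names(acc_only)),
                  c("cont", "prev", "acc", "other"))
  # the accuracy numbers are identical to the full run
  expect_equal(acc_only$acc$estimates, cass_res$acc$estimates)
  expect_equal(acc_only$acc$tests$global$statistic,
               cass_res$acc$tests$global$statistic)
  expect_equal(acc_only$acc$tests$members$p.value,
               cass_res$acc$tests$members$p.value)
  # but the adjusted global p differs because only one global test ran
  expect_equal(acc_only$acc$tests$global$p.adj,
               acc_only$acc$tests$global$p.value)
  expect_error(compare_tests(cass_data(), test1 = 1, test2 = 2, gold = 3,
                             sesp = FALSE, ppvnpv = FALSE, plrnlr = FALSE),
               class = "diagpair_config_error")
})

test_that("the CASS significance pattern matches the published table", {
  alpha <- cass_res$other$alpha
  acc <- cass_res$acc$tests
  expect_lt(acc$global$p.adj, alpha)
  memb <- function(blk, who) blk$members[blk$members$member == who, ]
  expect_lt(memb(acc, "Se")$p.adj, alpha)
  expect_gt(memb(acc, "Sp")$p.adj, alpha)
  pv <- cass_res$pv$tests
  expect_gt(memb(pv, "PPV")$p.adj, alpha)
  expect_lt(memb(pv, "NPV")$p.adj, alpha)
  lr <- cass_res$lr$tests
  expect_gt(memb(lr, "PLR")$p.adj, alpha)
  expect_lt(memb(lr, "NLR")$p.adj, alpha)
  expect_false(cass_res$other$equal)
  expect_identical(cass_res$other$zeros, 0L)
})

test_that("empty or degenerate input errors cleanly", {
  expect_error(compare_tests(data.frame()), class = "diagpair_config_error")
  all_pos <- tibble::tibble(test1 = c(1, 1), test2 = c(1, 0), gold = c(1, 1))
  expect_error(compare_tests(all_pos, test1 = 1, test2 = 2, gold = 3),
               class = "diagpair_degenerate_error")
})

test_that("the single-test summary agrees with the paired comparison", {
  one <- summarise_test(cass_data()[, c("test1", "gold")])
  expect_equal(round(100 * one$estimate[one$metric == "Se"], 1), 82.6)
  expect_equal(round(100 * one$estimate[one$metric == "Sp"], 1), 74.1)
  est <- cass_res$acc$estimates
  for (mtr in c("Se", "Sp")) {
    expect_equal(one$estimate[one$metric == mtr],
                 est$estimate[est$metric == mtr & est$test == "1"])
    expect_equal(one$conf.low[one$metric == mtr],
                 est$conf.low[est$metric == mtr & est$test == "1"])
  }
  perfect <- tibble::tibble(t = c(1, 1, 0, 0), g = c(1, 1, 0, 0))
  ps <- summarise_test(perfect)
  expect_true(all(ps$estimate[ps$metric %in% c("Se", "Sp", "PPV", "NPV")] == 1))
  expect_error(summarise_test(cass_data()), class = "diagpair_config_error")
})

test_that("JSON rendering is full fidelity: the analysis reproduces bit-identically", {
  js <- render(cass_res, "json")
  back <- parse_comparison(js)
  expect_identical(back$acc$tests$global$statistic,
                   cass_res$acc$tests$global$statistic)
  expect_identical(back$pv$tests$members$p.value,
                   cass_res$pv$tests$members$p.value)
  expect_identical(back$lr$tests$members$statistic,
                   cass_res$lr$tests$members$statistic)
  expect_identical(back$prev$estimate, cass_res$prev$estimate)
  expect_identical(back$other$youden1, cass_res$other$youden1)
  expect_error(render(cass_res, "yaml"), class = "diagpair_config_error")
})

test_that("display settings change the rendering but never the stored values", {
  res3 <- compare_tests(cass_data(), test1 = 1, test2 = 2, gold = 3, dp = 3,
                        margins = TRUE)
  expect_equal(res3$acc$estimates, cass_res$acc$estimates)
  out <- paste(capture.output(print(res3)), collapse = "\n")
  expect_match(out, "82.566")  # three decimals now visible
  expect_match(out, "Sum")     # contingency margins present
  out1 <- paste(capture.output(print(cass_res)), collapse = "\n")
  expect_no_match(out1, "Sum")
})

test_that("interpretation narrates causes only after a global rejection", {
  txt <- paste(capture.output(interpret(cass_res)), collapse = "\n")
  expect_match(txt, "Investigating cause\\(s\\) of significance")
  expect_match(txt, "\\*\\*\\*SIGNIFICANT\\*\\*\\*")
  # a table built to be identical on both tests: no flags anywhere
  fc <- fundamental_counts(40, 10, 10, 5, 5, 12, 12, 60)
  eq <- compare_tests(counts = fc)
  txt_eq <- paste(capture.output(interpret(eq)), collapse = "\n")
  expect_no_match(txt_eq, "SIGNIFICANT")
  expect_no_match(txt_eq, "Investigating")
  expect_true(eq$other$equal)
  # individual statistics are stored even though not evaluated
  expect_false(eq$acc$tests$evaluated)
  expect_equal(nrow(eq$acc$tests$members), 2L)
})

test_that("tidiers and the plot expose the comparison in tidy form", {
  td <- tidy(cass_res)
  expect_true(all(c("metric", "test", "estimate", "conf.low", "conf.high",
                    "p.adj") %in% names(td)))
  expect_identical(nrow(td), 13L)  # prevalence + 6 metrics x 2 tests
  gl <- glance(cass_res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$acc_global_stat, cass_res$acc$tests$global$statistic)
  expect_false(gl$equal)
  p <- autoplot(cass_res)
  expect_s3_class(p, "ggplot")
})
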