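#' Compare two binary diagnostic tests against a gold standard
#'
#' The workhorse of the package: recodes and tabulates the paired
#' observations, estimates every requested metric with its confidence
#' interval, and runs the global-then-individual hypothesis tests for each
#' enabled metric family with multiplicity control.
#'
#' @param data A data frame or matrix of subject-level results (see
#'   [paired_observations()]), or `NULL` when `test1`/`test2`/`gold` are
#'   vectors or `counts` is given.
#' @param test1,test2,gold Column designators (name or 1-based position) when
#'   `data` is supplied, otherwise raw result vectors.
#' @param counts A [fundamental_counts()] object for pre-tabulated data;
#'   overrides `data`.
#' @param alpha Significance level (default 0.05).
#' @param margins Display row/column sums on the printed contingency tables.
#' @param multi_corr Multiplicity adjustment method, one of
#'   [stats::p.adjust.methods] (default `"holm"`). Individual member
#'   p-values are adjusted within their family; global p-values are adjusted
#'   across the executed global tests.
#' @param cc Continuity correction for McNemar's test (default `TRUE`).
#' @param dp Decimal places used when printing percentages (default 1).
#' @param sesp,ppvnpv,plrnlr Enable the accuracy, predictive-value and
#'   likelihood-ratio families (all default `TRUE`). A disabled family is
#'   absent from the result, and disabling one never changes the numbers of
#'   another.
#' @param conf_int `"contemporary"` (midpoint-modified Wilson and
#'   score-approximation intervals) or `"classic"` (Clopper-Pearson for
#'   proportions; likelihood ratios keep the score-approximation interval,
#'   which has no exact analogue).
#' @param test_names Character vector of length 2 naming the tests.
#' @param recoding A [recoding_table()].
#' @return An object of class `compare_tests`: a list with components
#'   `cont` (contingency tables by true status), `prev` (prevalence row),
#'   `acc`, `pv`, `lr` (per-family estimates and test results) and `other`
#'   (alpha, `equal` flag, zero-cell count, Youden indices, test names,
#'   settings echo).
#' @examples
#' res <- compare_tests(cass_data(), ppvnpv = FALSE, plrnlr = FALSE)
#' res
#' @export
compare_tests <- function(data = NULL, test1 = NULL, test2 = NULL, gold = NULL,
                          counts = NULL, alpha = 0.05, margins = FALSE,
                          multi_corr = "holm", cc = TRUE, dp = 1,
                          sesp = TRUE, ppvnpv = TRUE, plrnlr = TRUE,
                          conf_int = c("contemporary", "classic"),
                          test_names = c("Test 1", "Test 2"),
                          recoding = recoding_table()) {
  conf_int <- match.arg(conf_int)
  check_alpha(alpha)
  if (!is.character(test_names) || length(test_names) != 2) {
    abort_config("`test_names` must be a character vector of length 2")
  }
  if (!dp %in% 0:10) abort_config("`dp` must be a whole number of decimals")
  if (!any(sesp, ppvnpv, plrnlr)) {
    abort_config("at least one metric family must be enabled")
  }
  if (is.null(counts)) {
    obs <- paired_observations(data, test1, test2, gold, recoding)
    fc <- tabulate_pairs(obs)
  } else {
    if (!inherits(counts, "fundamental_counts")) {
      abort_config("`counts` must be a fundamental_counts object")
    }
    fc <- counts
  }
  m <- fc_margins(fc)
  if (m$s < 1 || m$r < 1) {
    abort_degenerate(
      "need at least one gold-positive and one gold-negative subject")
  }

  est <- point_estimates(fc, alpha, conf_int)

  blocks <- list()
  if (sesp) blocks$acc <- test_accuracies(fc, alpha, cc)
  if (ppvnpv) blocks$pv <- test_predictive_values(fc, alpha)
  if (plrnlr) blocks$lr <- test_likelihood_ratios(fc, alpha)
  blocks <- Filter(Negate(is.null), blocks)

  # multiplicity: global p-values form one family across the executed global
  # tests; each family's two member p-values form their own family
  glob_idx <- which(vapply(blocks, function(b) !is.null(b$global), TRUE))
  glob_p <- vapply(blocks[glob_idx], function(b) b$global$p.value, 0)
  glob_adj <- if (length(glob_p)) adjust_p(glob_p, multi_corr) else numeric()
  for (k in seq_along(glob_idx)) {
    blocks[[glob_idx[k]]]$global$p.adj <- unname(glob_adj[k])
  }
  for (k in seq_along(blocks)) {
    blocks[[k]]$members$p.adj <- adjust_p(blocks[[k]]$members$p.value,
                                          multi_corr)
    rejected <- if (is.null(blocks[[k]]$global)) {
      TRUE  # low-prevalence small-n bypass: individual tests stand alone
    } else {
      blocks[[k]]$global$p.adj < alpha
    }
    blocks[[k]]$evaluated <- rejected
  }

  equal <- all(vapply(blocks, function(b) {
    is.null(b$global) || b$global$p.adj >= alpha
  }, TRUE))

  families <- list(acc = c("Se", "Sp"), pv = c("PPV", "NPV"),
                   lr = c("PLR", "NLR"))
  sections <- list()
  for (nm in names(blocks)) {
    sections[[nm]] <- list(
      estimates = dplyr::filter(est, .data$metric %in% families[[nm]]),
      tests = blocks[[nm]])
  }

  yj <- youden(fc)
  out <- list(
    cont = contingency_tables(fc),
    prev = dplyr::filter(est, .data$metric == "prevalence"),
    acc = sections$acc, pv = sections$pv, lr = sections$lr,
    other = list(alpha = alpha, equal = equal, zeros = fc_zeros(fc),
                 youden1 = unname(yj[1]), youden2 = unname(yj[2]),
                 test_names = test_names,
                 settings = list(alpha = alpha, margins = margins,
                                 multi_corr = multi_corr, cc = cc, dp = dp,
                                 sesp = sesp, ppvnpv = ppvnpv,
                                 plrnlr = plrnlr, conf_int = conf_int,
                                 test_names = test_names)),
    counts = fc)
  out[vapply(out, is.null, TRUE)] <- NULL
  structure(out, class = "compare_tests")
}

contingency_tables <- function(fc) {
  tab <- function(cells) {
    matrix(cells, 2, 2, byrow = TRUE,
           dimnames = list(`Test 1` = c("Positive", "Negative"),
                           `Test 2` = c("Positive", "Negative")))
  }
  list(pos = tab(c(fc$s11, fc$s10, fc$s01, fc$s00)),
       neg = tab(c(fc$r11, fc$r10, fc$r01, fc$r00)))
}

#' Summarise a single test against a gold standard
#'
#' Descriptive statistics only: sensitivity, specificity, predictive values
#' and likelihood ratios of one test, with the same estimators and intervals
#' as [compare_tests()] but no hypothesis tests.
#'
#' @param data A two-column data frame or matrix (test, gold standard), or
#'   `NULL` when `test` and `gold` are vectors.
#' @param test,gold Column designators or raw result vectors.
#' @param alpha Significance level.
#' @param conf_int `"contemporary"` or `"classic"`.
#' @param recoding A [recoding_table()].
#' @return A tibble with one row per metric: `metric`, `estimate`, `se`,
#'   `conf.low`, `conf.high` (proportions on the 0-1 scale).
#' @examples
#' summarise_test(cass_data()[, c("test1", "gold")])
#' @export
summarise_test <- function(data = NULL, test = NULL, gold = NULL,
                           alpha = 0.05,
                           conf_int = c("contemporary", "classic"),
                           recoding = recoding_table()) {
  conf_int <- match.arg(conf_int)
  if (!is.null(data)) {
    if (is.matrix(data)) data <- as.data.frame(data)
    if (!is.data.frame(data) || ncol(data) != 2) {
      abort_config("`data` must have exactly two columns: test, gold standard")
    }
    test <- data[[1]]; gold <- data[[2]]
  }
  if (is.null(test) || is.null(gold)) {
    abort_config("supply `data` or both `test` and `gold`")
  }
  # duplicate the single test into both slots and keep the test-1 rows
  obs <- paired_observations(test1 = test, test2 = test, gold = gold,
                             recoding = recoding)
  fc <- tabulate_pairs(obs)
  est <- point_estimates(fc, alpha, conf_int)
  out <- dplyr::filter(est, .data$test %in% c("1", "cohort"))
  dplyr::select(out, "metric", "estimate", "se", "conf.low", "conf.high")
}
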