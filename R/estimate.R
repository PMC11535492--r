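#' Wald standard error of a binomial proportion
#'
#' @param p Estimated proportion.
#' @param m Denominator count.
#' @return `sqrt(p * (1 - p) / m)`; `NA` when `m` is zero.
#' @export
wald_se <- function(p, m) {
  ifelse(m >= 1, sqrt(p * (1 - p) / m), NA_real_)
}

#' Point estimates, standard errors and confidence intervals for all metrics
#'
#' Computes, for each test, sensitivity `Se = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)`, the predictive values `PPV = TP/(TP+FP)` and
#' `NPV = TN/(TN+FN)`, the likelihood ratios `PLR = Se/(1-Sp)` and
#' `NLR = (1-Se)/Sp`, plus the cohort prevalence. Proportions carry a Wald
#' standard error and a confidence interval ([ci_modwilson()] by default,
#' Clopper-Pearson under `conf_int = "classic"`). Likelihood ratios carry no
#' standard error on the natural scale (a log-scale SE would not be
#' comparable with the proportion SEs) and use the score-approximation
#' intervals [ci_plr()] / [ci_nlr()] under either `conf_int` setting, since
#' no exact analogue exists for a ratio of proportions.
#'
#' A metric whose denominator is empty is returned as `NA` rather than
#' dropped; `PLR` is `Inf` when `Sp = 1` and `NLR` is `0` when `Se = 1`.
#'
#' @param fc A [fundamental_counts()] object.
#' @param alpha Significance level for the confidence intervals.
#' @param conf_int `"contemporary"` (default) or `"classic"`.
#' @return A tibble with columns `metric`, `test` (`"1"`, `"2"` or
#'   `"cohort"`), `estimate`, `se`, `conf.low`, `conf.high`. Proportions are
#'   on the 0-1 scale; multiply by 100 for display.
#' @examples
#' point_estimates(cass_counts())
#' @export
point_estimates <- function(fc, alpha = 0.05,
                            conf_int = c("contemporary", "classic")) {
  conf_int <- match.arg(conf_int)
  check_alpha(alpha)
  m <- fc_margins(fc)
  if (m$s < 1 || m$r < 1) {
    abort_degenerate(
      "need at least one gold-positive and one gold-negative subject")
  }

  prop_row <- function(metric, test, x, den) {
    if (den < 1) {
      return(tibble::tibble(metric = metric, test = test, estimate = NA_real_,
                            se = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_))
    }
    p <- x / den
    ci <- proportion_ci(x, den, alpha, conf_int)
    tibble::tibble(metric = metric, test = test, estimate = p,
                   se = wald_se(p, den),
                   conf.low = ci$conf.low, conf.high = ci$conf.high)
  }
  lr_row <- function(metric, test, num, den, ci) {
    est <- if (den == 0) {
      if (num == 0) NA_real_ else Inf
    } else num / den
    tibble::tibble(metric = metric, test = test, estimate = est,
                   se = NA_real_, conf.low = ci$conf.low,
                   conf.high = ci$conf.high)
  }

  se1 <- (fc$s11 + fc$s10) / m$s; se2 <- (fc$s11 + fc$s01) / m$s
  sp1 <- (fc$r01 + fc$r00) / m$r; sp2 <- (fc$r10 + fc$r00) / m$r

  dplyr::bind_rows(
    prop_row("prevalence", "cohort", m$s, m$n),
    prop_row("Se", "1", fc$s11 + fc$s10, m$s),
    prop_row("Se", "2", fc$s11 + fc$s01, m$s),
    prop_row("Sp", "1", fc$r01 + fc$r00, m$r),
    prop_row("Sp", "2", fc$r10 + fc$r00, m$r),
    prop_row("PPV", "1", fc$s11 + fc$s10, m$n1.),
    prop_row("PPV", "2", fc$s11 + fc$s01, m$n.1),
    prop_row("NPV", "1", fc$r01 + fc$r00, m$n0.),
    prop_row("NPV", "2", fc$r10 + fc$r00, m$n.0),
    lr_row("PLR", "1", se1, 1 - sp1, ci_plr(fc, 1, alpha)),
    lr_row("PLR", "2", se2, 1 - sp2, ci_plr(fc, 2, alpha)),
    lr_row("NLR", "1", 1 - se1, sp1, ci_nlr(fc, 1, alpha)),
    lr_row("NLR", "2", 1 - se2, sp2, ci_nlr(fc, 2, alpha)))
}

#' Youden indices of both tests
#'
#' The Youden index `J = Se + Sp - 1` summarises overall discriminative
#' ability: 0 for a useless test, 1 for a perfect one.
#'
#' @param fc A [fundamental_counts()] object.
#' @return Named numeric vector `c(youden1, youden2)`.
#' @export
youden <- function(fc) {
  m <- fc_margins(fc)
  if (m$s < 1 || m$r < 1) {
    abort_degenerate("Youden indices need both gold-standard strata")
  }
  se1 <- (fc$s11 + fc$s10) / m$s; se2 <- (fc$s11 + fc$s01) / m$s
  sp1 <- (fc$r01 + fc$r00) / m$r; sp2 <- (fc$r10 + fc$r00) / m$r
  c(youden1 = se1 + sp1 - 1, youden2 = se2 + sp2 - 1)
}
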