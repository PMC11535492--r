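#' Midpoint-modified Wilson confidence interval for a binomial proportion
#'
#' The "contemporary" interval used for all proportion-type metrics
#' (sensitivity, specificity, predictive values, prevalence). It keeps the
#' Wilson score half-width but pulls the midpoint towards 1/2 by a slightly
#' weaker factor than Wilson's, which improves small-sample coverage near the
#' boundaries:
#' \deqn{\frac12 + \frac{m + z^2/8}{m + z^2}\left(\hat p - \frac12\right)
#'   \pm \frac{z}{m + z^2}\sqrt{m\,\hat p(1-\hat p) + z^2/4},}
#' where \eqn{\hat p = x/m} and \eqn{z} is the \eqn{100(1-\alpha/2)}th
#' standard-normal percentile. Bounds are clamped to \eqn{[0, 1]}.
#'
#' @param x Number of successes (vectorised).
#' @param m Number of trials.
#' @param alpha Significance level; the interval has nominal coverage
#'   `1 - alpha`. Default 0.05.
#' @return A tibble with columns `conf.low`, `conf.high` (one row per input).
#' @examples
#' ci_modwilson(502, 608)  # sensitivity of an exercise stress test, 95% CI
#' @export
ci_modwilson <- function(x, m, alpha = 0.05) {
  check_alpha(alpha)
  stopifnot(length(x) == length(m) || length(x) == 1 || length(m) == 1)
  z <- stats::qnorm(1 - alpha / 2)
  p <- x / m
  shrink <- (m + z^2 / 8) / (m + z^2)
  centre <- 0.5 + shrink * (p - 0.5)
  half <- z * sqrt(m * p * (1 - p) + z^2 / 4) / (m + z^2)
  lo <- pmin(pmax(centre - half, 0), 1)
  hi <- pmin(pmax(centre + half, 0), 1)
  lo[m == 0] <- NA_real_; hi[m == 0] <- NA_real_
  tibble::tibble(conf.low = lo, conf.high = hi)
}

#' Clopper-Pearson exact confidence interval
#'
#' The "classic" option: exact binomial bounds from beta quantiles.
#'
#' @inheritParams ci_modwilson
#' @return A tibble with columns `conf.low`, `conf.high`.
#' @export
ci_clopper_pearson <- function(x, m, alpha = 0.05) {
  check_alpha(alpha)
  lo <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, m - x + 1))
  hi <- ifelse(x == m, 1, stats::qbeta(1 - alpha / 2, x + 1, m - x))
  lo[m == 0] <- NA_real_; hi[m == 0] <- NA_real_
  tibble::tibble(conf.low = lo, conf.high = hi)
}

proportion_ci <- function(x, m, alpha, method = c("contemporary", "classic")) {
  method <- match.arg(method)
  if (method == "contemporary") ci_modwilson(x, m, alpha) else ci_clopper_pearson(x, m, alpha)
}

#' Smoothed counts used by the likelihood-ratio intervals
#'
#' Likelihood-ratio intervals are built on counts smoothed by adding 0.5 to
#' each per-test margin and 1 to each stratum total, which keeps every
#' quantity strictly positive even when raw cells are empty:
#' `s1.~ = s1. + 0.5`, `s~ = s + 1`, `n~ = n + 2`, and analogously for the
#' negative margins and the gold-negative stratum.
#'
#' @param fc A [fundamental_counts()] object.
#' @return A list with the smoothed margins for both tests and both strata.
#' @export
smoothed_counts <- function(fc) {
  m <- fc_margins(fc)
  list(
    s1_1 = fc$s11 + fc$s10 + 0.5,  # positive margin, test 1, diseased
    s1_2 = fc$s11 + fc$s01 + 0.5,  # positive margin, test 2, diseased
    s0_1 = fc$s01 + fc$s00 + 0.5,
    s0_2 = fc$s10 + fc$s00 + 0.5,
    r1_1 = fc$r11 + fc$r10 + 0.5,
    r1_2 = fc$r11 + fc$r01 + 0.5,
    r0_1 = fc$r01 + fc$r00 + 0.5,
    r0_2 = fc$r10 + fc$r00 + 0.5,
    s = m$s + 1, r = m$r + 1, n = m$n + 2)
}

# Closed-form approximation to the score interval for a ratio of two
# independent binomial proportions A/S over B/R (both margins smoothed).
# A = smoothed success margin among the numerator stratum (size S),
# B = same among the denominator stratum (size R), N = S + R.
# Boundary fallbacks replace a limit that escapes the admissible range
# [A/(N - B), (N - A)/B] or crosses the smoothed point estimate.
lr_score_ci <- function(A, B, S, R, N, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  pa <- A / S                       # smoothed numerator proportion
  pb <- B / R                       # smoothed denominator proportion
  est <- pa / pb
  centre <- N * A * B + (z^2 / 2) * (S * A + R * B - 2 * A * B)
  arg <- N^2 * A * B * (A + B - N * A * B / (S * R)) +
    (z^2 / 4) * (S * A - R * B)^2
  den <- B * (N * S * B / R - 1.5 * z^2 * (S - B))
  if (den <= 0 || arg < 0) {
    # pathological smoothed table; fall back to the boundary expressions
    lo <- lr_lower_fallback(A, S, pa, pb, z)
    hi <- lr_upper_fallback(B, R, pa, pb, z)
    return(c(max(lo, 0), max(hi, lo, 0)))
  }
  lo <- (centre - z * sqrt(arg)) / den
  hi <- (centre + z * sqrt(arg)) / den
  if (lo < A / (N - B) || lo > est) lo <- lr_lower_fallback(A, S, pa, pb, z)
  if (hi > (N - A) / B || hi < est) hi <- lr_upper_fallback(B, R, pa, pb, z)
  c(max(lo, 0), max(hi, 0))
}

# boundary expression for the lower limit; reduces to pa/pb as z -> 0
lr_lower_fallback <- function(A, S, pa, pb, z) {
  arg <- max(z^2 / 4 + A * (1 - pb - pa), 0)
  (A * pb + z^2 / 2 - z * sqrt(arg)) / (S * pb^2 + z^2)
}

# boundary expression for the upper limit; reduces to pa/pb as z -> 0
lr_upper_fallback <- function(B, R, pa, pb, z) {
  arg <- max(z^2 / 4 + B * (pa + pb - 1), 0)
  (B * pa + z^2 / 2 + z * sqrt(arg)) / (R * pb^2)
}

#' Score-approximation confidence interval for a positive likelihood ratio
#'
#' The positive likelihood ratio \eqn{Se/(1-Sp)} is a ratio of two
#' independent binomial proportions (estimated in the diseased and
#' non-diseased strata respectively). The interval is a closed-form
#' approximation to the score interval for that ratio, computed on smoothed
#' counts (see [smoothed_counts()]) so it remains finite for empty cells,
#' with documented fallback expressions when a limit leaves the admissible
#' range. Bounds are clamped to \eqn{[0, \infty)}.
#'
#' @param fc A [fundamental_counts()] object.
#' @param test Which test, `1` or `2`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with columns `conf.low`, `conf.high`.
#' @export
ci_plr <- function(fc, test = 1, alpha = 0.05) {
  check_alpha(alpha)
  sc <- smoothed_counts(fc)
  A <- if (test == 1) sc$s1_1 else sc$s1_2
  B <- if (test == 1) sc$r1_1 else sc$r1_2
  b <- lr_score_ci(A, B, sc$s, sc$r, sc$n, alpha)
  tibble::tibble(conf.low = b[1], conf.high = b[2])
}

#' Score-approximation confidence interval for a negative likelihood ratio
#'
#' Mirror image of [ci_plr()] using the negative margins: the negative
#' likelihood ratio \eqn{(1-Se)/Sp} is the ratio of the smoothed negative
#' margin proportions of the diseased and non-diseased strata.
#'
#' @inheritParams ci_plr
#' @return A tibble with columns `conf.low`, `conf.high`.
#' @export
ci_nlr <- function(fc, test = 1, alpha = 0.05) {
  check_alpha(alpha)
  sc <- smoothed_counts(fc)
  A <- if (test == 1) sc$s0_1 else sc$s0_2
  B <- if (test == 1) sc$r0_1 else sc$r0_2
  b <- lr_score_ci(A, B, sc$s, sc$r, sc$n, alpha)
  tibble::tibble(conf.low = b[1], conf.high = b[2])
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_config("`alpha` must be a single number strictly between 0 and 1")
  }
  invisible(alpha)
}
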