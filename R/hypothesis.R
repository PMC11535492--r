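#' McNemar's test statistic for discordant pairs
#'
#' @param b,c The two discordant counts.
#' @param cc Apply the continuity correction (default `TRUE`).
#' @return A list with `statistic` and `p.value` (chi-square, 1 df).
#' @details With the correction the statistic is `(|b - c| - 1)^2 / (b + c)`,
#'   without it `(b - c)^2 / (b + c)`. When `b + c = 0` there is no
#'   information about a difference: the statistic is 0 and p = 1, with a
#'   warning.
#' @export
mcnemar_stat <- function(b, c, cc = TRUE) {
  if (b < 0 || c < 0) abort_config("discordant counts must be non-negative")
  if (b + c == 0) {
    rlang::warn("no discordant pairs: McNemar statistic is degenerate",
                class = "diagpair_degenerate_warning")
    return(list(statistic = 0, p.value = 1))
  }
  num <- if (cc) max(abs(b - c) - 1, 0)^2 else (b - c)^2
  stat <- num / (b + c)
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Paired-difference Wald test
#'
#' Chi-square (1 df) Wald test of a difference between two paired
#' proportions given its estimated variance.
#'
#' @param diff Estimated difference.
#' @param var Estimated variance of the difference.
#' @return A list with `statistic` and `p.value`.
#' @export
paired_diff_wald <- function(diff, var) {
  if (is.na(var) || var < 0) abort_config("`var` must be a non-negative number")
  if (var == 0) {
    rlang::warn("zero variance in paired Wald test",
                class = "diagpair_degenerate_warning")
    return(list(statistic = if (diff == 0) 0 else Inf,
                p.value = if (diff == 0) 1 else 0))
  }
  stat <- diff^2 / var
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# paired-multinomial Wald components for the accuracy comparison:
# for sensitivities, Var(Se1 - Se2) = [(s10 + s01) - (s10 - s01)^2 / s] / s^2
accuracy_wald_components <- function(fc) {
  m <- fc_margins(fc)
  se1 <- (fc$s11 + fc$s10) / m$s; se2 <- (fc$s11 + fc$s01) / m$s
  sp1 <- (fc$r01 + fc$r00) / m$r; sp2 <- (fc$r10 + fc$r00) / m$r
  vse <- ((fc$s10 + fc$s01) - (fc$s10 - fc$s01)^2 / m$s) / m$s^2
  vsp <- ((fc$r10 + fc$r01) - (fc$r10 - fc$r01)^2 / m$r) / m$r^2
  list(se_diff = se1 - se2, se_var = vse, sp_diff = sp1 - sp2, sp_var = vsp)
}

safe_wald_component <- function(diff, var) {
  if (var > 0) diff^2 / var else if (diff == 0) 0 else Inf
}

#' Global-then-individual comparison of the diagnostic accuracies
#'
#' Tests the global null `Se1 = Se2 and Sp1 = Sp2` with a Wald statistic
#' that is the sum of the paired-multinomial Wald components for the two
#' independent strata (chi-square, 2 df). Individual comparisons use the
#' method indicated by the study size: the Wald statistic when
#' `n <= 100` or `n >= 1000`, otherwise McNemar's test (with continuity
#' correction by default). When prevalence is below 10% and `n < 100` the
#' global step is skipped and the two Wald tests are run directly.
#' Individual statistics are referred to chi-square with 1 df.
#'
#' @param fc A [fundamental_counts()] object.
#' @param alpha Significance level.
#' @param cc Continuity correction for McNemar's test.
#' @return A `test_block` list: `family`, `global` (statistic, df, p.value,
#'   or `NULL` when bypassed), `members` tibble (member, statistic, df,
#'   p.value, method), `bypass` flag.
#' @export
test_accuracies <- function(fc, alpha = 0.05, cc = TRUE) {
  check_alpha(alpha)
  m <- fc_margins(fc)
  comp <- accuracy_wald_components(fc)
  prev <- m$s / m$n
  bypass <- prev < 0.10 && m$n < 100
  use_mcnemar <- m$n > 100 && m$n < 1000

  glob <- NULL
  if (!bypass) {
    gstat <- safe_wald_component(comp$se_diff, comp$se_var) +
      safe_wald_component(comp$sp_diff, comp$sp_var)
    glob <- list(statistic = gstat, df = 2L,
                 p.value = stats::pchisq(gstat, 2, lower.tail = FALSE))
  }

  if (use_mcnemar && !bypass) {
    ts <- mcnemar_stat(fc$s10, fc$s01, cc)
    tp <- mcnemar_stat(fc$r10, fc$r01, cc)
    method <- if (cc) "mcnemar_cc" else "mcnemar"
  } else {
    ts <- paired_diff_wald(comp$se_diff, comp$se_var)
    tp <- paired_diff_wald(comp$sp_diff, comp$sp_var)
    method <- "wald"
  }
  members <- tibble::tibble(
    member = c("Se", "Sp"),
    statistic = c(ts$statistic, tp$statistic),
    df = 1L,
    p.value = c(ts$p.value, tp$p.value),
    method = method)
  new_test_block("accuracies", glob, members, bypass)
}

#' Global-then-individual comparison of the predictive values
#'
#' The global null `PPV1 = PPV2 and NPV1 = NPV2` is tested with a Wald
#' statistic on the vector of differences, whose covariance comes from the
#' delta method applied to the joint multinomial over the eight fundamental
#' cells (chi-square, 2 df). Individual comparisons use a weighted
#' generalized score statistic: the pooled proportion weights the two
#' predictive values by their cohort sizes, and the covariance induced by
#' subjects positive (negative) on both tests is estimated empirically under
#' the pooled null.
#'
#' @inheritParams test_accuracies
#' @return A `test_block` list; see [test_accuracies()].
#' @export
test_predictive_values <- function(fc, alpha = 0.05) {
  check_alpha(alpha)
  m <- fc_margins(fc)
  if (min(m$n1., m$n.1, m$n0., m$n.0) < 1) {
    rlang::warn("a predictive-value denominator is empty: family skipped",
                class = "diagpair_degenerate_warning")
    return(NULL)
  }
  d <- pv_differences(fc)
  V <- delta_vcov(fc, pv_differences_prob)
  glob <- wald_global(d, V)
  members <- tibble::tibble(
    member = c("PPV", "NPV"),
    statistic = c(wgs_stat(fc$s11 + fc$s10, m$n1., fc$s11 + fc$s01, m$n.1,
                           fc$s11, m$n11),
                  wgs_stat(fc$r01 + fc$r00, m$n0., fc$r10 + fc$r00, m$n.0,
                           fc$r00, m$n00)),
    df = 1L)
  members$p.value <- stats::pchisq(members$statistic, 1, lower.tail = FALSE)
  members$method <- "wgs"
  new_test_block("predictive_values", glob, members, bypass = FALSE)
}

# weighted generalized score statistic for two overlapping cohorts:
# x1/m1 and x2/m2 are the compared proportions, the cohorts share `overlap`
# subjects of whom `x12` are successes; pooled proportion weighted by cohort
# size, covariance of the shared subjects estimated under the pooled null.
wgs_stat <- function(x1, m1, x2, m2, x12, overlap) {
  p1 <- x1 / m1; p2 <- x2 / m2
  pt <- (x1 + x2) / (m1 + m2)
  v <- pt * (1 - pt) * (1 / m1 + 1 / m2) -
    2 * (x12 * (1 - pt)^2 + (overlap - x12) * pt^2) / (m1 * m2)
  if (v <= 0) return(if (p1 == p2) 0 else Inf)
  (p1 - p2)^2 / v
}

pv_differences <- function(fc) {
  m <- fc_margins(fc)
  c((fc$s11 + fc$s10) / m$n1. - (fc$s11 + fc$s01) / m$n.1,
    (fc$r01 + fc$r00) / m$n0. - (fc$r10 + fc$r00) / m$n.0)
}

# same differences as a function of the 8 cell probabilities (delta method)
pv_differences_prob <- function(p) {
  c((p[1] + p[2]) / (p[1] + p[2] + p[5] + p[6]) -
      (p[1] + p[3]) / (p[1] + p[3] + p[5] + p[7]),
    (p[7] + p[8]) / (p[3] + p[4] + p[7] + p[8]) -
      (p[6] + p[8]) / (p[2] + p[4] + p[6] + p[8]))
}

#' Global-then-individual comparison of the likelihood ratios
#'
#' Works on the natural logarithms of the ratios `PLR1/PLR2` and
#' `NLR1/NLR2`. Both log-ratios are smooth functions of the stratum
#' multinomials, so their joint covariance comes from the delta method
#' (the diseased and non-diseased strata contribute independent
#' paired-multinomial pieces). The global Wald statistic is chi-square with
#' 2 df; each log-ratio is then tested individually with the same machinery
#' on 1 df. Raw proportions are used whenever all of them are inside (0, 1);
#' when any is degenerate the smoothed proportions of [smoothed_counts()]
#' are substituted so every logarithm stays finite.
#'
#' @inheritParams test_accuracies
#' @return A `test_block` list; see [test_accuracies()].
#' @export
test_likelihood_ratios <- function(fc, alpha = 0.05) {
  check_alpha(alpha)
  p <- lr_cell_probs(fc)
  d <- lr_log_ratios(p)
  V <- delta_vcov_probs(p$cells, p$s, p$r, lr_log_ratios_prob)
  glob <- wald_global(d, V)
  members <- tibble::tibble(
    member = c("PLR", "NLR"),
    statistic = c(if (V[1, 1] > 0) d[1]^2 / V[1, 1] else if (d[1] == 0) 0 else Inf,
                  if (V[2, 2] > 0) d[2]^2 / V[2, 2] else if (d[2] == 0) 0 else Inf),
    df = 1L)
  members$p.value <- stats::pchisq(members$statistic, 1, lower.tail = FALSE)
  members$method <- "log_ratio_wald"
  new_test_block("likelihood_ratios", glob, members, bypass = FALSE)
}

# cell probabilities for the LR tests; falls back to smoothed counts when a
# required proportion would be 0 or 1 (logs must stay finite)
lr_cell_probs <- function(fc) {
  m <- fc_margins(fc)
  cells <- fc_cells(fc)
  pr <- c(cells[1:4] / m$s, cells[5:8] / m$r)
  degen <- function(p) {
    se1 <- p[1] + p[2]; se2 <- p[1] + p[3]
    sp1 <- p[7] + p[8]; sp2 <- p[6] + p[8]
    any(c(se1, se2, sp1, sp2) <= 0) || any(c(se1, se2, sp1, sp2) >= 1)
  }
  if (degen(pr)) {
    # add 0.25 per cell: margins gain 0.5 and stratum totals gain 1,
    # matching the smoothing used by the likelihood-ratio intervals
    scells <- c(fc$s11, fc$s10, fc$s01, fc$s00) + 0.25
    rcells <- c(fc$r11, fc$r10, fc$r01, fc$r00) + 0.25
    pr <- c(scells / sum(scells), rcells / sum(rcells))
    return(list(cells = pr, s = sum(c(fc$s11, fc$s10, fc$s01, fc$s00)) + 1,
                r = sum(c(fc$r11, fc$r10, fc$r01, fc$r00)) + 1))
  }
  list(cells = pr, s = m$s, r = m$r)
}

lr_log_ratios <- function(p) lr_log_ratios_prob(p$cells)

# (log PLR1/PLR2, log NLR1/NLR2) as a function of the stacked cell
# probabilities (first 4 diseased, last 4 non-diseased, each summing to 1)
lr_log_ratios_prob <- function(p) {
  se1 <- p[1] + p[2]; se2 <- p[1] + p[3]
  sp1 <- p[7] + p[8]; sp2 <- p[6] + p[8]
  c(log(se1) - log(se2) - log(1 - sp1) + log(1 - sp2),
    log(1 - se1) - log(1 - se2) - log(sp1) + log(sp2))
}

# delta-method covariance for a function of the joint 8-cell multinomial
delta_vcov <- function(fc, g) {
  m <- fc_margins(fc)
  p <- fc_cells(fc) / m$n
  J <- num_jacobian(g, p)
  Sig <- (diag(p) - outer(p, p)) / m$n
  J %*% Sig %*% t(J)
}

# delta-method covariance for functions of two independent stratum
# multinomials with sizes s and r (cells stacked 4 + 4)
delta_vcov_probs <- function(p, s, r, g) {
  J <- num_jacobian(g, p)
  Sig <- matrix(0, 8, 8)
  Sig[1:4, 1:4] <- (diag(p[1:4]) - outer(p[1:4], p[1:4])) / s
  Sig[5:8, 5:8] <- (diag(p[5:8]) - outer(p[5:8], p[5:8])) / r
  J %*% Sig %*% t(J)
}

num_jacobian <- function(g, p, h = 1e-7) {
  k <- length(g(p))
  J <- matrix(0, k, length(p))
  for (j in seq_along(p)) {
    e <- rep(0, length(p)); e[j] <- h
    J[, j] <- (g(p + e) - g(p - e)) / (2 * h)
  }
  J
}

wald_global <- function(d, V) {
  qr_ok <- is.finite(sum(V)) && qr(V)$rank == length(d)
  if (!qr_ok) {
    if (all(d == 0)) {
      return(list(statistic = 0, df = 2L, p.value = 1))
    }
    rlang::warn("singular covariance in global Wald test",
                class = "diagpair_degenerate_warning")
    return(list(statistic = Inf, df = 2L, p.value = 0))
  }
  stat <- drop(t(d) %*% solve(V, d))
  list(statistic = stat, df = 2L,
       p.value = stats::pchisq(stat, 2, lower.tail = FALSE))
}

new_test_block <- function(family, global, members, bypass) {
  structure(list(family = family, global = global, members = members,
                 bypass = bypass),
            class = "test_block")
}

#' Adjust p-values for multiple comparisons
#'
#' Thin validated wrapper around [stats::p.adjust()] offering the same
#' methods (`holm`, `hochberg`, `hommel`, `bonferroni`, `BH`, `BY`, `fdr`,
#' `none`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method (default `"holm"`).
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_p <- function(p, method = "holm") {
  if (!is.character(method) || length(method) != 1 ||
      !method %in% stats::p.adjust.methods) {
    abort_config(sprintf("unknown adjustment method '%s'; use one of %s",
                         paste(method, collapse = ","),
                         paste(stats::p.adjust.methods, collapse = ", ")))
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_config("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}
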