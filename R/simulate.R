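#' Define a simulation scenario for paired diagnostic testing
#'
#' Specifies the data-generating mechanism used for coverage, type-I-error
#' and power studies: disease status is Bernoulli with the given prevalence,
#' and within each gold-standard stratum the two test results are correlated
#' Bernoulli variables with the stated accuracies and a phi-coefficient
#' correlation (`rho_d` among diseased, `rho_nd` among non-diseased). The
#' induced four-cell probabilities, e.g.
#' `p11 = Se1*Se2 + rho_d*sqrt(Se1(1-Se1)Se2(1-Se2))` among the diseased,
#' must all lie in `[0, 1]`; invalid accuracy/correlation combinations are
#' rejected.
#'
#' @param prevalence Disease prevalence in (0, 1).
#' @param se1,se2 Sensitivities of tests 1 and 2.
#' @param sp1,sp2 Specificities of tests 1 and 2.
#' @param rho_d,rho_nd Within-stratum correlations between the two tests
#'   (default 0; paired designs typically induce positive correlation).
#' @param n Number of subjects.
#' @return An object of class `sim_scenario`.
#' @examples
#' sc <- sim_scenario(0.3, 0.85, 0.85, 0.75, 0.75, rho_d = 0.3, rho_nd = 0.3,
#'                    n = 500)
#' sample_counts(sc, seed = 1)
#' @export
sim_scenario <- function(prevalence, se1, se2, sp1, sp2,
                         rho_d = 0, rho_nd = 0, n) {
  probs <- c(prevalence = prevalence, se1 = se1, se2 = se2,
             sp1 = sp1, sp2 = sp2)
  if (any(probs <= 0) || any(probs >= 1)) {
    abort_config("prevalence, sensitivities and specificities must be in (0, 1)")
  }
  if (n < 1 || n != round(n)) abort_config("`n` must be a positive integer")
  pd <- correlated_cell_probs(se1, se2, rho_d)
  pn <- correlated_cell_probs(1 - sp1, 1 - sp2, rho_nd)
  structure(list(prevalence = prevalence, se1 = se1, se2 = se2,
                 sp1 = sp1, sp2 = sp2, rho_d = rho_d, rho_nd = rho_nd,
                 n = as.integer(n), p_diseased = pd, p_non_diseased = pn),
            class = "sim_scenario")
}

# joint cell probabilities (11, 10, 01, 00) for two Bernoulli margins with a
# phi-coefficient correlation; errors if the combination is infeasible
correlated_cell_probs <- function(p1, p2, rho) {
  if (abs(rho) > 1) abort_config("correlations must lie in [-1, 1]")
  p11 <- p1 * p2 + rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  cells <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  if (any(cells < -1e-12) || any(cells > 1 + 1e-12)) {
    abort_config(sprintf(
      "correlation %.3f is infeasible for margins %.3f and %.3f", rho, p1, p2))
  }
  pmin(pmax(cells, 0), 1)
}

#' Draw fundamental counts from a simulation scenario
#'
#' The number of diseased subjects is Binomial(n, prevalence); each
#' stratum's four-cell vector is then multinomial with the scenario's joint
#' probabilities. A given `seed` fully determines the draw without
#' disturbing the caller's random-number state.
#'
#' @param scenario A [sim_scenario()] object.
#' @param seed Optional integer seed; `NULL` uses (and advances) the current
#'   RNG state.
#' @return A [fundamental_counts()] object.
#' @export
sample_counts <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  draw <- function() {
    s <- stats::rbinom(1, scenario$n, scenario$prevalence)
    d <- if (s > 0) stats::rmultinom(1, s, scenario$p_diseased) else rep(0, 4)
    h <- if (s < scenario$n) {
      stats::rmultinom(1, scenario$n - s, scenario$p_non_diseased)
    } else rep(0, 4)
    fundamental_counts(d[1], d[2], d[3], d[4], h[1], h[2], h[3], h[4])
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# evaluate `code` under set.seed(seed) and restore the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The CASS paired-testing contingency data
#'
#' Fundamental counts for 871 subjects from the Coronary Artery Surgery
#' Study: an exercise stress test (test 1) and a history of chest pain
#' (test 2) evaluated against coronary angiography as the gold standard.
#' Among the 608 angiography-positive subjects the cross-classification of
#' (test 1, test 2) is 473/29/81/25 (++/+-/-+/--); among the 263 negatives
#' it is 22/46/44/151.
#'
#' @return `cass_counts()`: a [fundamental_counts()] object.
#' @export
cass_counts <- function() {
  fundamental_counts(473, 29, 81, 25, 22, 46, 44, 151)
}

#' @rdname cass_counts
#' @return `cass_data()`: the row-level expansion, a tibble of 871 subjects
#'   with 0/1 columns `test1`, `test2`, `gold`.
#' @export
cass_data <- function() {
  fc_expand(cass_counts())
}

#' @rdname cass_counts
#' @param path File path for the CSV copy of the row-level data.
#' @return `cass_csv()`: `path`, invisibly, after writing the 3-column CSV.
#' @export
cass_csv <- function(path = tempfile(fileext = ".csv")) {
  utils::write.csv(cass_data(), path, row.names = FALSE)
  invisible(path)
}
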