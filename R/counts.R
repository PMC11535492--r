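#' Fundamental counts: the 2x4 cross-classification of two paired tests
#'
#' All statistics in the package are computed from the eight fundamental
#' counts: the joint classification of both tests within the gold-positive
#' stratum (`s11`, `s10`, `s01`, `s00`, first index test 1, second test 2) and
#' within the gold-negative stratum (`r11`, `r10`, `r01`, `r00`). For example
#' `s10` is the number of diseased subjects positive on test 1 and negative on
#' test 2.
#'
#' @param s11,s10,s01,s00 Non-negative integer counts among gold-positive
#'   subjects.
#' @param r11,r10,r01,r00 Non-negative integer counts among gold-negative
#'   subjects.
#' @return An object of class `fundamental_counts`.
#' @examples
#' fundamental_counts(473, 29, 81, 25, 22, 46, 44, 151)
#' @export
fundamental_counts <- function(s11, s10, s01, s00, r11, r10, r01, r00) {
  cells <- c(s11 = s11, s10 = s10, s01 = s01, s00 = s00,
             r11 = r11, r10 = r10, r01 = r01, r00 = r00)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort_config("all eight cell counts must be non-negative numbers")
  }
  if (any(cells != round(cells))) {
    abort_config("cell counts must be whole numbers")
  }
  cells <- as.integer(round(cells))
  names(cells) <- c("s11", "s10", "s01", "s00", "r11", "r10", "r01", "r00")
  if (sum(cells) == 0) {
    abort_degenerate("all eight cells are zero: no subjects to analyse")
  }
  structure(as.list(cells), class = "fundamental_counts")
}

#' @export
print.fundamental_counts <- function(x, ...) {
  m <- fc_margins(x)
  cat("Fundamental counts (", m$n, " subjects; ", m$s, " gold-positive, ",
      m$r, " gold-negative)\n\n", sep = "")
  show <- function(cells, label) {
    tab <- matrix(cells, 2, 2, byrow = TRUE,
                  dimnames = list(`Test 1` = c("Positive", "Negative"),
                                  `Test 2` = c("Positive", "Negative")))
    cat(label, "\n"); print(tab); cat("\n")
  }
  show(c(x$s11, x$s10, x$s01, x$s00), "True status: positive")
  show(c(x$r11, x$r10, x$r01, x$r00), "True status: negative")
  invisible(x)
}

#' Margins and totals derived from fundamental counts
#'
#' @param fc A [fundamental_counts()] object.
#' @return A list with stratum totals `s`, `r`, `n`, the cross-test cell
#'   totals `n11`, `n10`, `n01`, `n00`, and the per-test margins `n1.` / `n.1`
#'   (positives on test 1 / test 2) and `n0.` / `n.0` (negatives).
#' @export
fc_margins <- function(fc) {
  s <- fc$s11 + fc$s10 + fc$s01 + fc$s00
  r <- fc$r11 + fc$r10 + fc$r01 + fc$r00
  n11 <- fc$s11 + fc$r11; n10 <- fc$s10 + fc$r10
  n01 <- fc$s01 + fc$r01; n00 <- fc$s00 + fc$r00
  list(s = s, r = r, n = s + r,
       n11 = n11, n10 = n10, n01 = n01, n00 = n00,
       n1. = n11 + n10, n.1 = n11 + n01,
       n0. = n00 + n01, n.0 = n00 + n10)
}

fc_cells <- function(fc) {
  c(s11 = fc$s11, s10 = fc$s10, s01 = fc$s01, s00 = fc$s00,
    r11 = fc$r11, r10 = fc$r10, r01 = fc$r01, r00 = fc$r00)
}

# number of empty cells among the eight fundamental counts
fc_zeros <- function(fc) sum(fc_cells(fc) == 0)

#' Tabulate paired observations into fundamental counts
#'
#' @param obs A [paired_observations()] tibble (or any data frame with 0/1
#'   columns `test1`, `test2`, `gold`).
#' @return A [fundamental_counts()] object; each subject increments exactly
#'   one of the eight cells.
#' @export
tabulate_pairs <- function(obs) {
  stopifnot(all(c("test1", "test2", "gold") %in% names(obs)))
  t1 <- obs$test1; t2 <- obs$test2; g <- obs$gold
  if (any(!t1 %in% 0:1) || any(!t2 %in% 0:1) || any(!g %in% 0:1)) {
    abort_config("observations must be recoded to 0/1 before tabulation")
  }
  cnt <- function(gs, a, b) sum(g == gs & t1 == a & t2 == b)
  fundamental_counts(
    s11 = cnt(1, 1, 1), s10 = cnt(1, 1, 0), s01 = cnt(1, 0, 1), s00 = cnt(1, 0, 0),
    r11 = cnt(0, 1, 1), r10 = cnt(0, 1, 0), r01 = cnt(0, 0, 1), r00 = cnt(0, 0, 0))
}

#' @export
as.data.frame.fundamental_counts <- function(x, ...) {
  as.data.frame(as.list(fc_cells(x)))
}

# expand counts back to one row per subject (inverse of tabulate_pairs)
fc_expand <- function(fc) {
  key <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(1, 0, 0),
               c(0, 1, 1), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  # rows of key are (gold, test1, test2) for s11..r00
  reps <- unname(fc_cells(fc))
  idx <- rep(seq_len(8), reps)
  tibble::tibble(test1 = key[idx, 2], test2 = key[idx, 3], gold = key[idx, 1])
}
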