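#' Recoding table for flexibly coded binary test results
#'
#' Diagnostic test results arrive coded in many dialects ("pos"/"neg", "y"/"n",
#' 0/1, 1/2, TRUE/FALSE, "+"/"-"). A recoding table maps every accepted synonym
#' onto a positive or negative indicator. Matching is case-insensitive and
#' ignores surrounding whitespace; there is no requirement for consistent
#' coding within a column, so `1` and `"yes"` may coexist.
#'
#' The default synonym sets are: positive `"positive"`, `"pos"`, `"p"`,
#' `"yes"`, `"y"`, `"+"`, `"1"`, `"true"`, `"t"` (and numeric `1`); negative
#' `"negative"`, `"neg"`, `"no"`, `"n"`, `"-"`, `"0"`, `"2"`, `"false"`, `"f"`
#' (and numerics `0` and `2`). Note that numeric `2` codes a *negative* result,
#' following the common 1 = positive / 2 = negative convention.
#'
#' @param positive Character vector of tokens recoded to 1.
#' @param negative Character vector of tokens recoded to 0.
#' @return An object of class `recoding_table`: a list with normalised
#'   `positive` and `negative` synonym sets.
#' @examples
#' rt <- recoding_table()
#' recode_binary(c(" POS ", "no", 2, TRUE), rt)
#' @export
recoding_table <- function(positive = c("positive", "pos", "p", "yes", "y",
                                        "+", "1", "true", "t"),
                           negative = c("negative", "neg", "no", "n", "-",
                                        "0", "2", "false", "f")) {
  pos <- unique(normalise_token(positive))
  neg <- unique(normalise_token(negative))
  clash <- intersect(pos, neg)
  if (length(clash) > 0) {
    abort_config(sprintf(
      "positive and negative synonym sets overlap after normalisation: %s",
      paste(clash, collapse = ", ")))
  }
  structure(list(positive = pos, negative = neg), class = "recoding_table")
}

# lower-case, trim whitespace; numbers pass through as their decimal strings
normalise_token <- function(x) tolower(trimws(as.character(x)))

#' Recode a vector of test results to 0/1 indicators
#'
#' @param x Vector of raw results (character, numeric, logical or factor).
#' @param table A [recoding_table()].
#' @param column Label used in error messages to locate offending values.
#' @return Integer vector of 0/1 indicators.
#' @details Missing values (`NA` or empty strings) are a hard error: complete
#'   data are expected, and any missing-data strategy (complete-case analysis,
#'   imputation) must be applied by the analyst before recoding. Unrecognised
#'   tokens raise a coding error naming the value and its row.
#' @export
recode_binary <- function(x, table = recoding_table(), column = "column") {
  if (is.factor(x)) x <- as.character(x)
  miss <- is.na(x) | normalise_token(x) == ""
  if (any(miss)) {
    abort_missing(sprintf(
      paste0("missing value in %s (first at row %d); complete data are ",
             "required - resolve missingness (e.g. complete-case analysis ",
             "or imputation) before running the comparison"),
      column, which(miss)[1]))
  }
  tok <- normalise_token(x)
  out <- rep(NA_integer_, length(tok))
  out[tok %in% table$positive] <- 1L
  out[tok %in% table$negative] <- 0L
  bad <- is.na(out)
  if (any(bad)) {
    i <- which(bad)[1]
    abort_coding(sprintf(
      "unrecognised result '%s' in %s at row %d; accepted values are %s (positive) and %s (negative)",
      x[i], column, i,
      paste(table$positive, collapse = "/"),
      paste(table$negative, collapse = "/")))
  }
  out
}

#' Assemble validated paired observations
#'
#' Builds the subject-level table of paired results: one row per independent
#' subject, with both candidate tests and the gold standard recoded to 0/1.
#' Rows must be paired (all three results belong to the same subject) and
#' independent (no technical or biological replicates).
#'
#' @param data A data frame or matrix with at least three columns, or `NULL`
#'   when `test1`, `test2` and `gold` are given as result vectors.
#' @param test1,test2,gold When `data` is supplied: a column name or 1-based
#'   column position. When `data` is `NULL`: vectors of raw results. If all
#'   three are `NULL`, columns 1, 2 and 3 of `data` are used and a warning is
#'   issued.
#' @param recoding A [recoding_table()].
#' @return A tibble of class `paired_observations` with integer columns
#'   `test1`, `test2`, `gold`.
#' @examples
#' df <- data.frame(a = c("pos", "neg"), b = c(1, 2), c = c("y", "n"))
#' paired_observations(df, "a", "b", "c")
#' @export
paired_observations <- function(data = NULL, test1 = NULL, test2 = NULL,
                                gold = NULL, recoding = recoding_table()) {
  if (is.null(data)) {
    if (is.null(test1) || is.null(test2) || is.null(gold)) {
      abort_config("supply either `data` or all three of `test1`, `test2`, `gold`")
    }
    cols <- list(test1 = test1, test2 = test2, gold = gold)
  } else {
    if (is.matrix(data)) data <- as.data.frame(data)
    if (!is.data.frame(data)) abort_config("`data` must be a data frame or matrix")
    if (nrow(data) < 1) abort_config("`data` has no rows")
    if (is.null(test1) && is.null(test2) && is.null(gold)) {
      if (ncol(data) < 3) abort_config("`data` needs at least 3 columns")
      rlang::warn(paste("no columns designated: using columns 1, 2 and 3 as",
                        "test 1, test 2 and gold standard - check that this is correct"),
                  class = "diagpair_default_columns")
      test1 <- 1L; test2 <- 2L; gold <- 3L
    }
    cols <- lapply(list(test1 = test1, test2 = test2, gold = gold),
                   function(j) pick_column(data, j))
  }
  lens <- lengths(cols)
  if (length(unique(lens)) != 1) {
    abort_config(sprintf("test1, test2 and gold differ in length (%s)",
                         paste(lens, collapse = ", ")))
  }
  out <- tibble::tibble(
    test1 = recode_binary(cols$test1, recoding, "test 1"),
    test2 = recode_binary(cols$test2, recoding, "test 2"),
    gold  = recode_binary(cols$gold,  recoding, "gold standard"))
  class(out) <- c("paired_observations", class(out))
  out
}

pick_column <- function(data, j) {
  if (is.null(j)) abort_config("designate all of test1, test2 and gold, or none")
  if (length(j) == 1 && (is.character(j) || is.numeric(j))) {
    if (is.character(j) && !j %in% names(data)) {
      abort_config(sprintf("column '%s' not found in `data`", j))
    }
    if (is.numeric(j) && (j < 1 || j > ncol(data))) {
      abort_config(sprintf("column index %s outside 1..%d", j, ncol(data)))
    }
    return(data[[j]])
  }
  abort_config("column designators must be a single name or 1-based position")
}

# condition helpers -----------------------------------------------------

abort_coding <- function(msg) {
  rlang::abort(msg, class = c("diagpair_coding_error", "diagpair_error"))
}
abort_missing <- function(msg) {
  rlang::abort(msg, class = c("diagpair_missing_error", "diagpair_error"))
}
abort_config <- function(msg) {
  rlang::abort(msg, class = c("diagpair_config_error", "diagpair_error"))
}
abort_degenerate <- function(msg) {
  rlang::abort(msg, class = c("diagpair_degenerate_error", "diagpair_error"))
}
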