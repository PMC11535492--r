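#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy the metric estimates of a test comparison
#'
#' @param x A `compare_tests` object.
#' @param ... Unused.
#' @return A tibble with one row per metric and test: `metric`, `test`,
#'   `estimate`, `se`, `conf.low`, `conf.high`, plus the member test
#'   statistic and raw/adjusted p-values where an individual comparison
#'   exists for that metric.
#' @method tidy compare_tests
#' @export
tidy.compare_tests <- function(x, ...) {
  est <- dplyr::bind_rows(
    x$prev,
    purrr::map_dfr(intersect(c("acc", "pv", "lr"), names(x)),
                   function(nm) x[[nm]]$estimates))
  tests <- purrr::map_dfr(intersect(c("acc", "pv", "lr"), names(x)),
                          function(nm) x[[nm]]$tests$members)
  tests <- dplyr::rename(tests, metric = "member", statistic = "statistic")
  dplyr::left_join(est, tests, by = "metric")
}

#' One-row summary of a test comparison
#'
#' @param x A `compare_tests` object.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, prevalence, global statistics and
#'   adjusted p-values per executed family, the `equal` flag, zero-cell
#'   count and Youden indices.
#' @method glance compare_tests
#' @export
glance.compare_tests <- function(x, ...) {
  m <- fc_margins(x$counts)
  row <- tibble::tibble(
    n = m$n, n_diseased = m$s, n_non_diseased = m$r,
    prevalence = x$prev$estimate,
    equal = x$other$equal, zeros = x$other$zeros,
    youden1 = x$other$youden1, youden2 = x$other$youden2,
    alpha = x$other$alpha)
  for (nm in intersect(c("acc", "pv", "lr"), names(x))) {
    g <- x[[nm]]$tests$global
    row[[paste0(nm, "_global_stat")]] <- if (is.null(g)) NA_real_ else g$statistic
    row[[paste0(nm, "_global_p_adj")]] <- if (is.null(g)) NA_real_ else g$p.adj
  }
  row
}

family_title <- c(acc = "DIAGNOSTIC ACCURACIES",
                  pv = "PREDICTIVE VALUES",
                  lr = "LIKELIHOOD RATIOS")
member_label <- c(Se = "Sensitivity", Sp = "Specificity",
                  PPV = "Pos. predictive value", NPV = "Neg. predictive value",
                  PLR = "Pos. likelihood ratio", NLR = "Neg. likelihood ratio")
global_null <- c(acc = "Se1 = Se2 & Sp1 = Sp2",
                 pv = "PPV1 = PPV2 & NPV1 = NPV2",
                 lr = "PLR1 = PLR2 & NLR1 = NLR2")

# format an estimates tibble for one test as a percent (or ratio) matrix
estimate_matrix <- function(est, test_id, dp) {
  rows <- dplyr::filter(est, .data$test == test_id)
  is_lr <- rows$metric %in% c("PLR", "NLR")
  scale <- ifelse(is_lr, 1, 100)
  digits <- ifelse(is_lr, dp + 1, dp)
  m <- cbind(Estimate = round(rows$estimate * scale, digits),
             SE = round(rows$se * scale, digits),
             `Lower CI` = round(rows$conf.low * scale, digits),
             `Upper CI` = round(rows$conf.high * scale, digits))
  rownames(m) <- member_label[rows$metric]
  m
}

print_family <- function(x, nm, dp) {
  sec <- x[[nm]]
  cat(strrep("-", 70), "\n", family_title[nm], "\n", strrep("-", 70), "\n",
      sep = "")
  for (i in 1:2) {
    cat("\n", x$other$test_names[i],
        if (nm != "lr") " (%)" else "", "\n", sep = "")
    print(estimate_matrix(sec$estimates, as.character(i), dp))
  }
  blk <- sec$tests
  if (!is.null(blk$global)) {
    cat("\nGlobal null hypothesis: ", global_null[nm], "\n", sep = "")
    cat("Test statistic: ", format_stat(blk$global$statistic),
        "  Adjusted p value: ", format_stat(blk$global$p.adj),
        significance_flag(blk$global$p.adj, x$other$alpha), "\n", sep = "")
  } else {
    cat("\nGlobal test bypassed (low prevalence, small sample):",
        "individual Wald tests reported directly.\n")
  }
  if (blk$evaluated) {
    if (!is.null(blk$global)) cat("\nInvestigating cause(s) of significance\n")
    for (i in seq_len(nrow(blk$members))) {
      mb <- blk$members[i, ]
      cat("\nNull hypothesis ", i, ": ", mb$member, "1 = ", mb$member, "2\n",
          sep = "")
      cat("Test statistic: ", format_stat(mb$statistic),
          "  Adjusted p value: ", format_stat(mb$p.adj),
          significance_flag(mb$p.adj, x$other$alpha), "\n", sep = "")
    }
  } else {
    cat("\nGlobal null not rejected: individual comparisons not evaluated.\n")
  }
  cat("\n")
}

format_stat <- function(v) format(signif(v, 7), trim = TRUE)
significance_flag <- function(p, alpha) {
  if (!is.na(p) && p < alpha) " ***SIGNIFICANT***" else ""
}

print_contingency <- function(x, dp) {
  set <- x$other$settings
  add_margins <- isTRUE(set$margins)
  show <- function(tab, label) {
    if (add_margins) tab <- stats::addmargins(tab)
    cat("\n", label, "\n", sep = "")
    print(tab)
  }
  show(x$cont$pos, "True status: POSITIVE")
  show(x$cont$neg, "True status: NEGATIVE")
}

#' @export
print.compare_tests <- function(x, ...) {
  dp <- x$other$settings$dp
  cat(strrep("-", 70), "\nCONTINGENCY TABLES\n", strrep("-", 70), "\n",
      sep = "")
  print_contingency(x, dp)
  cat("\n", strrep("-", 70), "\nPREVALENCE (%)\n", strrep("-", 70), "\n\n",
      sep = "")
  pm <- cbind(Estimate = round(x$prev$estimate * 100, dp),
              SE = round(x$prev$se * 100, dp),
              `Lower CI` = round(x$prev$conf.low * 100, dp),
              `Upper CI` = round(x$prev$conf.high * 100, dp))
  rownames(pm) <- "Prevalence"
  print(pm)
  cat("\n")
  for (nm in intersect(c("acc", "pv", "lr"), names(x))) print_family(x, nm, dp)
  cat("Alpha: ", x$other$alpha,
      "   Tests equivalent: ", x$other$equal,
      "   Empty cells: ", x$other$zeros, "\n", sep = "")
  cat("Youden index ", x$other$test_names[1], ": ",
      format_stat(x$other$youden1), "   ",
      x$other$test_names[2], ": ", format_stat(x$other$youden2), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.compare_tests <- function(object, ...) {
  print(glance(object))
  invisible(object)
}

#' Plain-language interpretation of a comparison
#'
#' Renders the result of [compare_tests()] as a sectioned plain-English
#' report, flagging significant results and narrating the cause of a global
#' rejection only when one occurred.
#'
#' @param x A `compare_tests` object.
#' @return Invisibly, the report as a character vector of lines; also
#'   printed to the console.
#' @export
interpret <- function(x) {
  stopifnot(inherits(x, "compare_tests"))
  txt <- utils::capture.output(print(x))
  alpha <- x$other$alpha
  concl <- character()
  for (nm in intersect(c("acc", "pv", "lr"), names(x))) {
    blk <- x[[nm]]$tests
    if (!is.null(blk$global) && blk$global$p.adj < alpha) {
      sig <- blk$members$member[blk$members$p.adj < alpha]
      concl <- c(concl, sprintf(
        "The %s differ overall (adjusted p = %s).%s",
        tolower(family_title[nm]), format_stat(blk$global$p.adj),
        if (length(sig)) paste0(" Driven by: ", paste(sig, collapse = ", "), ".")
        else " No single member comparison reaches significance after adjustment."))
    } else if (!is.null(blk$global)) {
      concl <- c(concl, sprintf(
        "No evidence that the %s differ (adjusted p = %s).",
        tolower(family_title[nm]), format_stat(blk$global$p.adj)))
    }
  }
  out <- c(txt, "", strrep("-", 70), "IN PLAIN ENGLISH", strrep("-", 70),
           concl)
  cat(out, sep = "\n")
  invisible(out)
}

#' Render a comparison as text or JSON
#'
#' `"text"` is the console report. `"json"` is a full-fidelity, unrounded
#' serialisation carrying the fundamental counts and settings, so the whole
#' analysis can be reproduced bit-identically from the JSON alone.
#'
#' @param x A `compare_tests` object.
#' @param format `"text"` or `"json"`.
#' @return A character scalar.
#' @export
render <- function(x, format = c("text", "json")) {
  stopifnot(inherits(x, "compare_tests"))
  if (!is.character(format)) abort_config("`format` must be a string")
  format <- tryCatch(match.arg(format),
                     error = function(e) abort_config(
                       sprintf("unknown format '%s'", format[1])))
  if (format == "text") {
    return(paste(utils::capture.output(print(x)), collapse = "\n"))
  }
  payload <- list(
    counts = as.list(fc_cells(x$counts)),
    settings = x$other$settings,
    prevalence = as.list(x$prev),
    other = x$other[c("alpha", "equal", "zeros", "youden1", "youden2",
                      "test_names")])
  for (nm in intersect(c("acc", "pv", "lr"), names(x))) {
    blk <- x[[nm]]$tests
    payload[[nm]] <- list(
      estimates = x[[nm]]$estimates,
      global = blk$global,
      members = blk$members,
      evaluated = blk$evaluated)
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Rebuild a comparison from its JSON rendering
#'
#' @param json JSON produced by `render(x, "json")`.
#' @return A `compare_tests` object recomputed from the embedded counts and
#'   settings.
#' @export
parse_comparison <- function(json) {
  p <- jsonlite::fromJSON(json)
  cells <- p$counts
  set <- p$settings
  compare_tests(counts = do.call(fundamental_counts, cells),
                alpha = set$alpha, margins = set$margins,
                multi_corr = set$multi_corr, cc = set$cc, dp = set$dp,
                sesp = set$sesp, ppvnpv = set$ppvnpv, plrnlr = set$plrnlr,
                conf_int = set$conf_int, test_names = set$test_names)
}

#' Bar chart of accuracies and predictive values with CI whiskers
#'
#' @param object A `compare_tests` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot compare_tests
#' @export
autoplot.compare_tests <- function(object, ...) {
  est <- purrr::map_dfr(intersect(c("acc", "pv"), names(object)),
                        function(nm) object[[nm]]$estimates)
  if (nrow(est) == 0) {
    abort_config("nothing to plot: enable the accuracy or predictive-value family")
  }
  est$metric <- factor(est$metric, levels = c("Se", "Sp", "PPV", "NPV"))
  est$test <- factor(object$other$test_names[as.integer(est$test)],
                     levels = object$other$test_names)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$metric, y = 100 * .data$estimate,
                                    fill = .data$test)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$conf.low, ymax = 100 * .data$conf.high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Estimate (%)", fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' @export
plot.compare_tests <- function(x, ...) print(autoplot(x, ...))
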