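#' One-vs-rest diagnostic validity of a method for one cause
#'
#' Dichotomizes both the method's and the gold standard's assignments into
#' "this cause" vs "anything else" and tabulates the 2x2 counts. Metrics:
#' sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`,
#' PPV `100*TP/(TP+FP)`, NPV `100*TN/(TN+FN)`, each with an exact binomial
#' (Clopper-Pearson) 95% confidence interval. A metric with a zero
#' denominator is undefined and reported as `NA`, not 0.
#'
#' An indeterminate call is never "this cause", so it counts as a negative
#' prediction.
#'
#' @param data Data frame, one row per death.
#' @param pred Column with the method's condensed cause, tidy-eval.
#' @param gold Column with the gold-standard condensed cause, tidy-eval.
#' @param cause The cause (or causes) to dichotomize on.
#' @param conf_level Confidence level for the binomial intervals.
#' @return A tibble of class `va_validity`, one row per cause: `cause`,
#'   `tp`, `fp`, `tn`, `fn`, then `sensitivity`, `specificity`, `ppv`,
#'   `npv`, each with `_low`/`_high` bounds; all metrics in percent.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   gold = rep(c("TB", "other"), c(7, 138)),
#'   pred = c(rep("TB", 5), "other", "other", rep("TB", 3), rep("other", 135))
#' )
#' two_by_two(d, pred, gold, "TB")
two_by_two <- function(data, pred, gold, cause, conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  p <- dplyr::pull(data, {{ pred }})
  g <- dplyr::pull(data, {{ gold }})
  stopifnot(length(p) == length(g))
  rows <- purrr::map(cause, function(cs) {
    pp <- p == cs
    gg <- g == cs
    tp <- sum(pp & gg); fp <- sum(pp & !gg)
    fn <- sum(!pp & gg); tn <- sum(!pp & !gg)
    sens <- prop_ci(tp, tp + fn, conf_level)
    spec <- prop_ci(tn, tn + fp, conf_level)
    ppv <- prop_ci(tp, tp + fp, conf_level)
    npv <- prop_ci(tn, tn + fn, conf_level)
    tibble::tibble(
      cause = cs, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sens[1], sensitivity_low = sens[2], sensitivity_high = sens[3],
      specificity = spec[1], specificity_low = spec[2], specificity_high = spec[3],
      ppv = ppv[1], ppv_low = ppv[2], ppv_high = ppv[3],
      npv = npv[1], npv_low = npv[2], npv_high = npv[3]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("va_validity", class(out))
  out
}

# percentage + exact binomial CI; zero denominator -> NA triple
prop_ci <- function(x, n, conf_level) {
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  c(100 * x / n, 100 * ci[1], 100 * ci[2])
}

#' Validity table for the most common causes
#'
#' Convenience wrapper running [two_by_two()] for each of the top `n_causes`
#' causes by gold-standard frequency (ties broken by cause-list order),
#' mirroring the usual layout of VA validation reports.
#'
#' @inheritParams two_by_two
#' @param categories Cause list used for ranking order.
#' @param n_causes Number of top causes to report (default 5).
#' @return A `va_validity` tibble, one row per selected cause.
#' @export
validity_table <- function(data, pred, gold, categories = NULL, n_causes = 5,
                           conf_level = 0.95) {
  g <- dplyr::pull(data, {{ gold }})
  categories <- categories %||% setdiff(sort(unique(g)), va_indeterminate())
  counts <- table(factor(g, levels = categories))
  # order() is stable, so ties keep cause-list order
  top <- categories[order(-as.integer(counts))][
    seq_len(min(n_causes, length(categories)))
  ]
  two_by_two(data, {{ pred }}, {{ gold }}, top, conf_level = conf_level)
}
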