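#' ROC curve for a hard categorical classifier
#'
#' A method that outputs a single cause per death (a physician coder, or the
#' engine's final assignment) has no score to threshold, so the curve is
#' built from per-cause operating points: each cause contributes the
#' (false positive rate, true positive rate) = (1 - specificity,
#' sensitivity) of its one-vs-rest 2x2 against the gold standard. The points
#' are anchored at (0,0) and (1,1), sorted by FPR (ties by TPR), and the
#' area under the resulting empirical curve is the trapezoidal integral. A
#' cause never observed in the gold standard has undefined sensitivity; its
#' point is skipped with a warning.
#'
#' Overall performance is conventionally called adequate when the AUC
#' exceeds 0.75.
#'
#' @param data Data frame, one row per death.
#' @param pred,gold Columns with the method's and the gold standard's
#'   condensed causes, tidy-eval.
#' @param categories Cause list contributing operating points.
#' @return An object of class `va_roc`: list with `points` (tibble
#'   `fpr`, `tpr`, `cause`), `auc`, `adequate`, `type = "categorical"`.
#' @export
roc_categorical <- function(data, pred, gold, categories = NULL) {
  p <- dplyr::pull(data, {{ pred }})
  g <- dplyr::pull(data, {{ gold }})
  categories <- categories %||% setdiff(sort(unique(g)), va_indeterminate())
  pts <- purrr::map(categories, function(cs) {
    gg <- g == cs; pp <- p == cs
    if (!any(gg)) {
      warning("Cause \"", cs, "\" absent from the gold standard; ",
              "operating point skipped.", call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      fpr = sum(pp & !gg) / sum(!gg),
      tpr = sum(pp & gg) / sum(gg),
      cause = cs
    )
  })
  pts <- dplyr::bind_rows(pts)
  anchored <- dplyr::bind_rows(
    tibble::tibble(fpr = 0, tpr = 0, cause = NA_character_),
    pts,
    tibble::tibble(fpr = 1, tpr = 1, cause = NA_character_)
  )
  anchored <- dplyr::arrange(anchored, .data$fpr, .data$tpr)
  auc <- trapezoid_auc(anchored$fpr, anchored$tpr)
  new_va_roc(anchored, auc, "categorical")
}

#' ROC curve from per-cause scores
#'
#' For the Bayes engine the posterior probabilities themselves can be
#' thresholded: every (death, cause) pair is pooled as a one-vs-rest case
#' with label "gold standard assigned this cause" and score equal to the
#' posterior. Sweeping the threshold yields the empirical curve, whose
#' trapezoidal area equals the Mann-Whitney concordance probability
#' P(score of a positive pair > score of a negative pair), ties counting
#' one half.
#'
#' @param scores Numeric matrix of scores, deaths in rows, one column per
#'   cause in `categories` (e.g. the `"posterior"` attribute of
#'   [batch_assign()]).
#' @param gold Character vector of gold-standard causes, one per row.
#' @param categories Cause list (defaults to `colnames(scores)`).
#' @return A `va_roc` with `type = "scores"`; `points` holds the full
#'   empirical curve. Constant scores give AUC 0.5 with a warning.
#' @export
roc_scores <- function(scores, gold, categories = NULL) {
  scores <- as.matrix(scores)
  categories <- categories %||% colnames(scores)
  if (is.null(categories)) {
    stop("`categories` required when `scores` has no column names.",
         call. = FALSE)
  }
  stopifnot(nrow(scores) == length(gold), ncol(scores) == length(categories))
  lab <- as.vector(outer(gold, categories, `==`))
  sc <- as.vector(scores)
  keep <- !is.na(sc)
  lab <- lab[keep]; sc <- sc[keep]
  if (!any(lab) || all(lab)) {
    stop("Pooled pairs must include both positives and negatives.",
         call. = FALSE)
  }
  if (length(unique(sc)) == 1) {
    warning("Scores are constant; AUC is 0.5 by convention.", call. = FALSE)
    pts <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1), cause = NA_character_)
    return(new_va_roc(pts, 0.5, "scores"))
  }
  ord <- order(-sc)
  tp <- cumsum(lab[ord]); fp <- cumsum(!lab[ord])
  # one curve point per distinct threshold
  last <- c(sc[ord][-1] != sc[ord][-length(sc)], TRUE)
  pts <- tibble::tibble(
    fpr = c(0, fp[last] / sum(!lab), 1),
    tpr = c(0, tp[last] / sum(lab), 1),
    cause = NA_character_
  )
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  new_va_roc(pts, auc, "scores")
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

new_va_roc <- function(points, auc, type) {
  structure(
    list(points = points, auc = auc, adequate = roc_adequate(auc),
         type = type),
    class = "va_roc"
  )
}

#' Is an AUC adequate?
#'
#' The adequacy rule for overall diagnostic performance: the area under the
#' ROC curve must exceed 0.75 (strictly).
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return Logical vector.
#' @export
#' @examples
#' roc_adequate(c(0.82, 0.88, 0.75))
roc_adequate <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1)) {
    stop("AUC must lie in [0, 1].", call. = FALSE)
  }
  auc > 0.75
}

#' @export
print.va_roc <- function(x, ...) {
  cat("<va_roc> ", x$type, " curve, ", nrow(x$points), " points, AUC = ",
      sprintf("%.3f", x$auc), if (x$adequate) " (adequate)" else
        " (not adequate)", "\n", sep = "")
  invisible(x)
}
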