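#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kappa result
#'
#' @param x A `va_kappa` from [cohen_kappa()] or [multirater_kappa()].
#' @param ... Unused.
#' @return A one-row tibble: `method`, `kappa`, `p_a`, `p_e`, `ci_low`,
#'   `ci_high`, `strength`, `n`.
#' @method tidy va_kappa
#' @export
tidy.va_kappa <- function(x, ...) {
  tibble::tibble(
    method = x$method, kappa = x$kappa, p_a = x$p_a, p_e = x$p_e,
    ci_low = x$ci_low, ci_high = x$ci_high,
    strength = x$strength, n = x$n
  )
}

#' @rdname tidy.va_kappa
#' @method glance va_kappa
#' @export
glance.va_kappa <- function(x, ...) tidy.va_kappa(x)

#' Tidy an ROC result
#'
#' `tidy()` returns the curve's points; `glance()` the one-row AUC summary.
#'
#' @param x A `va_roc`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy va_roc
#' @export
tidy.va_roc <- function(x, ...) x$points

#' @rdname tidy.va_roc
#' @method glance va_roc
#' @export
glance.va_roc <- function(x, ...) {
  tibble::tibble(type = x$type, auc = x$auc, adequate = x$adequate,
                 n_points = nrow(x$points))
}

#' Tidy a probability matrix into long format
#'
#' @param x A `va_matrix`.
#' @param ... Unused.
#' @return A tibble `indicator`, `cause`, `emit`, `prior`.
#' @method tidy va_matrix
#' @export
tidy.va_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(indicator = x$indicators),
                     tibble::as_tibble(x$emit)),
    -"indicator", names_to = "cause", values_to = "emit"
  )
  long$prior <- x$priors[long$cause]
  long
}

#' Tidy a contingency table into long counts
#'
#' @param x A `va_contingency`.
#' @param ... Unused.
#' @return A tibble `a`, `b`, `n`.
#' @method tidy va_contingency
#' @export
tidy.va_contingency <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame.table(m, responseName = "n",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("a", "b", "n"))
}
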