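#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; mortality tables conventionally
#' round half up. `round_half_up(0.5) == 1`, `round_half_up(1.45, 1) == 1.5`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The label used for an indeterminate assignment
#'
#' A death for which no cause reaches the reporting threshold is recorded as
#' indeterminate. The label is an assignment outcome only: it is never a valid
#' true cause, and in agreement statistics it matches nothing, including
#' itself.
#'
#' @return The string `"indeterminate"`.
#' @export
va_indeterminate <- function() "indeterminate"

# Split one user-facing seed into independent per-stage substreams so that
# e.g. the cohort draw is unchanged when the rater stage is re-run. Offsets
# are fixed; results stay below 2^31 - 1.
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offsets <- c(
    cohort = 101L, indicators = 211L, hcod = 307L, pcva = 401L,
    matrix = 503L, bootstrap = 601L, generic = 701L
  )
  if (!stage %in% names(offsets)) stage <- "generic"
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

# Validate a cause list: unique non-empty labels, no reserved label.
check_cause_list <- function(categories, allow_indeterminate = FALSE) {
  if (!is.character(categories) || length(categories) == 0) {
    stop("`categories` must be a non-empty character vector of cause labels.",
         call. = FALSE)
  }
  if (anyDuplicated(categories)) {
    stop("Cause labels must be unique; duplicated: ",
         paste(unique(categories[duplicated(categories)]), collapse = ", "),
         call. = FALSE)
  }
  if (!allow_indeterminate && va_indeterminate() %in% categories) {
    stop("\"", va_indeterminate(), "\" is an assignment outcome, ",
         "not a cause; it cannot appear in a cause list.", call. = FALSE)
  }
  invisible(categories)
}

# categories + the indeterminate outcome, for reporting/cross-tabulation
with_indeterminate <- function(categories) {
  c(categories, va_indeterminate())
}

`%||%` <- function(x, y) if (is.null(x)) y else x
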