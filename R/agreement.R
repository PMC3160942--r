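#' Cause-specific mortality fractions
#'
#' The CSMF for a cause is the proportion of all deaths attributable to it.
#' Indeterminate assignments form their own category so the fractions always
#' sum to 1.
#'
#' @param data Data frame with one row per death.
#' @param cause Column of assigned (condensed) causes, tidy-eval.
#' @param categories Cause list; defaults to the causes observed. The
#'   indeterminate label is appended automatically.
#' @return A tibble `cause`, `n`, `fraction`, `percent` (round-half-up to
#'   1 decimal place), ordered by `categories`, plus attribute `n_total`.
#' @export
#' @examples
#' d <- tibble::tibble(cod = c(rep("HIV", 38), rep("TB", 107)))
#' csmf(d, cod)
csmf <- function(data, cause, categories = NULL) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ cause }})
  n <- length(x)
  if (n == 0) stop("Cannot compute a CSMF over zero deaths.", call. = FALSE)
  categories <- categories %||% setdiff(sort(unique(x)), va_indeterminate())
  lev <- with_indeterminate(categories)
  bad <- setdiff(unique(x), lev)
  if (length(bad) > 0) {
    stop("Assigned cause(s) outside the cause list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- as.integer(table(factor(x, levels = lev)))
  frac <- counts / n
  out <- tibble::tibble(
    cause = lev,
    n = counts,
    fraction = frac,
    percent = round_half_up(100 * frac, 1)
  )
  attr(out, "n_total") <- n
  out
}

#' Check population-level agreement of two CSMF tables
#'
#' Flags, cause by cause, whether a method's CSMF lies within `tolerance`
#' percentage points of the gold standard's.
#'
#' @param csmf_method,csmf_gold CSMF tibbles from [csmf()] over the same
#'   cause list.
#' @param tolerance Allowed absolute difference in percentage points
#'   (default 5).
#' @return A tibble `cause`, `percent_method`, `percent_gold`, `diff_pp`
#'   (absolute difference in percentage points), `pass`.
#' @export
csmf_tolerance_check <- function(csmf_method, csmf_gold, tolerance = 5) {
  if (!setequal(csmf_method$cause, csmf_gold$cause)) {
    stop("CSMF tables cover different cause lists.", call. = FALSE)
  }
  g <- csmf_gold[match(csmf_method$cause, csmf_gold$cause), ]
  diff_pp <- abs(100 * csmf_method$fraction - 100 * g$fraction)
  tibble::tibble(
    cause = csmf_method$cause,
    percent_method = csmf_method$percent,
    percent_gold = g$percent,
    diff_pp = diff_pp,
    pass = diff_pp <= tolerance
  )
}

#' Cross-classification of two methods' assigned causes
#'
#' @param data Data frame, one row per death.
#' @param a,b Columns holding the two methods' condensed causes, tidy-eval.
#' @param categories Shared cause list (indeterminate appended
#'   automatically).
#' @return A K x K integer matrix of class `va_contingency`; method A in
#'   rows, method B in columns.
#' @export
contingency <- function(data, a, b, categories = NULL) {
  stopifnot(is.data.frame(data))
  xa <- dplyr::pull(data, {{ a }})
  xb <- dplyr::pull(data, {{ b }})
  categories <- categories %||%
    setdiff(sort(unique(c(xa, xb))), va_indeterminate())
  lev <- with_indeterminate(categories)
  bad <- setdiff(unique(c(xa, xb)), lev)
  if (length(bad) > 0) {
    stop("Assignment(s) outside the shared cause list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(xa, levels = lev), factor(xb, levels = lev))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  class(m) <- c("va_contingency", class(m))
  m
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement between two categorical raters:
#' `kappa = (P_A - P_E) / (1 - P_E)` with `P_A` the observed agreement
#' proportion and `P_E` the agreement expected from the marginals alone.
#' The confidence interval uses the Fleiss–Cohen–Everitt large-sample
#' standard error, truncated to `[-1, 1]`.
#'
#' Indeterminate calls never count as agreement, not even with each other
#' (`indeterminate = "mismatch"`, the default); alternatively drop every
#' death either rater left indeterminate (`"drop"`), or score them like any
#' other category (`"agree"`).
#'
#' @param x A `va_contingency` (or square matrix/table) from
#'   [contingency()], or a data frame of per-death assignments.
#' @param ... Passed between methods.
#' @param conf_level Confidence level (default 0.95).
#' @param indeterminate Handling of the indeterminate category; see above.
#' @return An object of class `va_kappa` with fields `kappa`, `p_a`, `p_e`,
#'   `se`, `ci_low`, `ci_high`, `strength`, `n`, `method`. Both raters
#'   constant and identical (`P_E = 1`) leaves `kappa` undefined (`NA`) with
#'   a warning.
#' @export
#' @examples
#' tab <- matrix(c(10, 1, 0, 2, 12, 2, 0, 3, 10), 3, 3)
#' cohen_kappa(tab)
cohen_kappa <- function(x, ...) UseMethod("cohen_kappa")

#' @rdname cohen_kappa
#' @export
cohen_kappa.default <- function(x, ..., conf_level = 0.95,
                                indeterminate = c("mismatch", "drop", "agree")) {
  indeterminate <- match.arg(indeterminate)
  tab <- unclass(as.matrix(x))
  if (nrow(tab) != ncol(tab)) stop("Table must be square.", call. = FALSE)
  ind <- va_indeterminate()
  has_ind <- !is.null(rownames(tab)) && ind %in% rownames(tab)
  if (has_ind && indeterminate == "drop") {
    keep <- rownames(tab) != ind
    tab <- tab[keep, keep, drop = FALSE]
  } else if (has_ind && indeterminate == "mismatch") {
    # split indeterminate into rater-specific categories so two
    # indeterminates never land on the diagonal; marginals unchanged
    causes <- setdiff(rownames(tab), ind)
    lev <- c(causes, ".ind_a", ".ind_b")
    big <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
    big[causes, causes] <- tab[causes, causes]
    big[".ind_a", causes] <- tab[ind, causes]
    big[causes, ".ind_b"] <- tab[causes, ind]
    big[".ind_a", ".ind_b"] <- tab[ind, ind]
    tab <- big
  }
  kappa_from_table(tab, conf_level = conf_level, method = "cohen")
}

#' @param rater1,rater2 Columns of `x` with the two methods' causes,
#'   tidy-eval.
#' @param categories Shared cause list.
#' @rdname cohen_kappa
#' @export
cohen_kappa.data.frame <- function(x, rater1, rater2, categories = NULL, ...,
                                   conf_level = 0.95,
                                   indeterminate = c("mismatch", "drop", "agree")) {
  tab <- contingency(x, {{ rater1 }}, {{ rater2 }}, categories = categories)
  cohen_kappa(tab, conf_level = conf_level,
              indeterminate = match.arg(indeterminate))
}

# core computation + Fleiss-Cohen-Everitt large-sample SE
kappa_from_table <- function(tab, conf_level, method) {
  n <- sum(tab)
  if (n < 1) stop("Empty table.", call. = FALSE)
  p <- tab / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (abs(1 - pe) < 1e-12) {
    warning("Both raters are constant and identical; kappa is undefined.",
            call. = FALSE)
    kap <- NA_real_; se <- NA_real_
  } else {
    kap <- (po - pe) / (1 - pe)
    k <- nrow(p)
    a <- sum(diag(p) * ((1 - pe) - (pr + pc) * (1 - po))^2)
    b <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) b <- b + p[i, j] * (pc[i] + pr[j])^2
    }
    b <- (1 - po)^2 * b
    cterm <- (po * pe - 2 * pe + po)^2
    se <- sqrt(max(0, a + b - cterm)) / ((1 - pe)^2 * sqrt(n))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      kappa = kap, p_a = po, p_e = pe, se = se,
      ci_low = if (is.na(kap)) NA_real_ else max(-1, kap - z * se),
      ci_high = if (is.na(kap)) NA_real_ else min(1, kap + z * se),
      strength = if (is.na(kap)) NA_character_ else kappa_strength(kap),
      n = n, conf_level = conf_level, method = method
    ),
    class = "va_kappa"
  )
}

#' @export
print.va_kappa <- function(x, ...) {
  cat("<va_kappa> ", x$method, " kappa = ",
      ifelse(is.na(x$kappa), "NA", sprintf("%.2f", x$kappa)),
      " (", x$conf_level * 100, "% CI ",
      sprintf("%.2f", x$ci_low), "-", sprintf("%.2f", x$ci_high),
      "), strength: ", x$strength %||% "NA", ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Fleiss' kappa across three (or more) raters
#'
#' Multirater chance-corrected agreement over `n` subjects rated by `m`
#' raters into `K` categories. The confidence interval is a subject-level
#' bootstrap (percentile, seeded). Indeterminate handling matches
#' [cohen_kappa()]: by default each rater's indeterminate is a
#' rater-specific category, so indeterminates never agree.
#'
#' @param data Data frame, one row per subject.
#' @param ... Rater columns, tidy-eval (at least two).
#' @param categories Shared cause list.
#' @param conf_level Confidence level (default 0.95).
#' @param boot Number of bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param indeterminate `"mismatch"` (default) or `"agree"`.
#' @return A `va_kappa` with `method = "fleiss"`.
#' @export
multirater_kappa <- function(data, ..., categories = NULL, conf_level = 0.95,
                             boot = 2000, seed = NULL,
                             indeterminate = c("mismatch", "agree")) {
  indeterminate <- match.arg(indeterminate)
  cols <- dplyr::select(tibble::as_tibble(data), ...)
  if (ncol(cols) < 2) stop("Need at least two rater columns.", call. = FALSE)
  lens <- vapply(cols, length, integer(1))
  if (length(unique(lens)) != 1) stop("Rater vectors differ in length.", call. = FALSE)
  ratings <- as.matrix(cols)
  if (indeterminate == "mismatch") {
    for (j in seq_len(ncol(ratings))) {
      hit <- ratings[, j] == va_indeterminate()
      ratings[hit, j] <- paste0(va_indeterminate(), ".", j)
    }
  }
  lev <- categories %||% sort(unique(as.vector(ratings)))
  lev <- union(lev, unique(as.vector(ratings)))
  counts <- fleiss_counts(ratings, lev)
  kap <- fleiss_kappa_counts(counts)
  ci <- c(NA_real_, NA_real_)
  if (boot > 0 && nrow(counts) > 1) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(split_seed(seed, "bootstrap"))
    }
    n <- nrow(counts)
    reps <- vapply(seq_len(boot), function(b) {
      fleiss_kappa_counts(counts[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    alpha <- 1 - conf_level
    ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                          na.rm = TRUE, names = FALSE)
  }
  structure(
    list(
      kappa = as.numeric(kap), p_a = attr(kap, "p_a"), p_e = attr(kap, "p_e"),
      se = NA_real_, ci_low = ci[1], ci_high = ci[2],
      strength = if (is.na(kap)) NA_character_ else kappa_strength(kap),
      n = nrow(counts), conf_level = conf_level, method = "fleiss"
    ),
    class = "va_kappa"
  )
}

fleiss_counts <- function(ratings, lev) {
  t(apply(ratings, 1, function(r) table(factor(r, levels = lev))))
}

fleiss_kappa_counts <- function(counts) {
  m <- sum(counts[1, ])
  if (any(rowSums(counts) != m)) {
    stop("All subjects must be rated by the same number of raters.",
         call. = FALSE)
  }
  n <- nrow(counts)
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * m)
  p_e <- sum(p_j^2)
  kap <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_bar - p_e) / (1 - p_e)
  attr(kap, "p_a") <- p_bar
  attr(kap, "p_e") <- p_e
  kap
}

#' Strength-of-agreement label for a kappa value
#'
#' The conventional scale: below 0.21 poor, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 good, above 0.80 very good. Band boundaries are
#' inclusive on the upper end.
#'
#' @param kappa Numeric vector of kappa values in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
#' @examples
#' kappa_strength(c(0.32, 0.52, 0.90))
kappa_strength <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < -1) || any(kappa > 1)) {
    stop("kappa must lie in [-1, 1].", call. = FALSE)
  }
  dplyr::case_when(
    kappa < 0.21 ~ "poor",
    kappa <= 0.40 ~ "fair",
    kappa <= 0.60 ~ "moderate",
    kappa <= 0.80 ~ "good",
    TRUE ~ "very good"
  )
}

#' Did at least two of three methods agree?
#'
#' The per-death agreement indicator: 1 when two or three of the methods
#' assign the same condensed cause, 0 otherwise. Indeterminate matches
#' nothing, including another indeterminate.
#'
#' @param a,b,c Character vectors of condensed causes (recycled scalars
#'   allowed).
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' agreement_indicator("HIV", "HIV", "TB")
agreement_indicator <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  ind <- va_indeterminate()
  eq <- function(x, y) x == y & x != ind & y != ind
  as.integer(eq(a, b) | eq(a, c) | eq(b, c))
}
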