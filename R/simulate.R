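#' Simulate a cohort of deaths with known true causes
#'
#' Generates the synthetic analogue of a VA validation cohort: each death
#' receives a true cause drawn from `csmf_true`, then each indicator is drawn
#' Bernoulli from the matrix's cause-conditional emission probability,
#' flipped with probability `flip_noise` (reporting error), and finally set
#' to unknown with probability `missing_rate` (questionnaire items not asked
#' or not answered). Age and sex are generated for stratified reporting only;
#' indicators do not depend on them.
#'
#' @param matrix A [va_matrix()].
#' @param n_deaths Number of deaths to simulate.
#' @param csmf_true Numeric vector of true cause-specific mortality
#'   fractions, one per cause in `matrix`, summing to 1. Default uniform.
#' @param flip_noise Probability an indicator's value is flipped, in `[0, 1)`.
#' @param missing_rate Probability an indicator is set to unknown, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @return A tibble with one row per death: `id`, `age` (years), `sex`
#'   (`"male"`/`"female"`), `true_cause`, and one integer column per
#'   indicator coded `1` present / `0` absent / `NA` unknown.
#' @export
#' @examples
#' m <- build_probability_matrix(3, 12, seed = 1)
#' cohort <- simulate_cohort(m, 20, csmf_true = c(0.5, 0.3, 0.2), seed = 1)
#' dplyr::count(cohort, true_cause)
simulate_cohort <- function(matrix, n_deaths, csmf_true = NULL,
                            flip_noise = 0, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(matrix, "va_matrix"), n_deaths >= 1)
  k <- length(matrix$causes)
  csmf_true <- csmf_true %||% rep(1 / k, k)
  if (length(csmf_true) != k) {
    stop("`csmf_true` has ", length(csmf_true), " entries but the matrix ",
         "has ", k, " causes.", call. = FALSE)
  }
  if (abs(sum(csmf_true) - 1) > 1e-6 || any(csmf_true < 0)) {
    stop("`csmf_true` must be non-negative and sum to 1.", call. = FALSE)
  }
  for (p in list(flip_noise, missing_rate)) {
    if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p < 0 || p >= 1) {
      stop("`flip_noise` and `missing_rate` must be in [0, 1).", call. = FALSE)
    }
  }

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(split_seed(seed, "cohort"))
  }
  n_ind <- length(matrix$indicators)
  cause_idx <- sample.int(k, n_deaths, replace = TRUE, prob = csmf_true)
  # adult cohort: ages 15+, right-skewed around late middle age
  age <- round(pmin(pmax(stats::rnorm(n_deaths, mean = 55, sd = 20), 15), 100))
  sex <- sample(c("male", "female"), n_deaths, replace = TRUE)

  # n_deaths x n_indicators draw in one block
  p_emit <- t(matrix$emit[, cause_idx, drop = FALSE])   # deaths x indicators
  x <- matrix(
    as.integer(stats::runif(n_deaths * n_ind) < p_emit),
    n_deaths, n_ind
  )
  if (flip_noise > 0) {
    flip <- matrix(stats::runif(n_deaths * n_ind) < flip_noise, n_deaths, n_ind)
    x[flip] <- 1L - x[flip]
  }
  if (missing_rate > 0) {
    x[matrix(stats::runif(n_deaths * n_ind) < missing_rate, n_deaths, n_ind)] <- NA_integer_
  }
  colnames(x) <- matrix$indicators

  dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("d%05d", seq_len(n_deaths)),
      age = age,
      sex = sex,
      true_cause = matrix$causes[cause_idx]
    ),
    tibble::as_tibble(x)
  )
}

#' Define an imperfect categorical rater
#'
#' A rater (a hospital physician issuing the gold-standard diagnosis, or a
#' physician coding the VA form) is modelled by a row-stochastic confusion
#' matrix P(assigned = j | true = i) plus a probability of declaring the
#' case indeterminate regardless of the truth.
#'
#' @param confusion Square numeric matrix with rows summing to 1; row/column
#'   names are cause labels (filled in from the cohort's matrix if absent).
#' @param indeterminate_rate Probability of an indeterminate call, in `[0, 1)`.
#' @return An object of class `va_rater`.
#' @seealso [diagonal_confusion()] to build a confusion matrix with a given
#'   accuracy, [simulate_rater()] to apply the rater to a cohort.
#' @export
rater_model <- function(confusion, indeterminate_rate = 0) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("`confusion` must be square.", call. = FALSE)
  }
  if (any(!is.finite(confusion)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("`confusion` rows must be non-negative and sum to 1 (+- 1e-9).",
         call. = FALSE)
  }
  if (!is.numeric(indeterminate_rate) || indeterminate_rate < 0 ||
      indeterminate_rate >= 1) {
    stop("`indeterminate_rate` must be in [0, 1).", call. = FALSE)
  }
  structure(
    list(confusion = confusion, indeterminate_rate = indeterminate_rate),
    class = "va_rater"
  )
}

#' Confusion matrix with constant per-cause accuracy
#'
#' Diagonal entries are `accuracy`; the remaining mass is spread uniformly
#' over the other causes. `accuracy = 1` is a perfect rater.
#'
#' @param causes Character vector of cause labels (or a count).
#' @param accuracy Probability the rater assigns the true cause, in `(0, 1]`.
#' @return A row-stochastic matrix with `causes` as dimnames.
#' @export
diagonal_confusion <- function(causes, accuracy = 0.8) {
  if (is.numeric(causes) && length(causes) == 1) {
    causes <- paste0("cause", seq_len(causes))
  }
  k <- length(causes)
  stopifnot(k >= 2, accuracy > 0, accuracy <= 1)
  off <- (1 - accuracy) / (k - 1)
  m <- matrix(off, k, k, dimnames = list(causes, causes))
  diag(m) <- accuracy
  m
}

#' Apply an imperfect rater to a cohort
#'
#' For each death the assignment is drawn from the confusion-matrix row of
#' its true cause, or set to the indeterminate label with the rater's
#' `indeterminate_rate`.
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (needs `id` and
#'   `true_cause`).
#' @param rater A [rater_model()], or a bare confusion matrix.
#' @param seed Integer seed.
#' @param stream Substream label (`"hcod"`, `"pcva"`, or anything else);
#'   lets two raters share one study seed without sharing draws.
#' @return A character vector of assigned causes, one per cohort row, in
#'   cohort order.
#' @export
simulate_rater <- function(cohort, rater, seed = NULL, stream = "generic") {
  if (!inherits(rater, "va_rater")) rater <- rater_model(rater)
  stopifnot(is.data.frame(cohort), all(c("id", "true_cause") %in% names(cohort)))
  causes <- colnames(rater$confusion)
  if (is.null(causes)) {
    causes <- sort(unique(cohort$true_cause))
    if (length(causes) != ncol(rater$confusion)) {
      stop("Unnamed confusion matrix of dimension ", ncol(rater$confusion),
           " cannot be matched to ", length(causes),
           " observed causes.", call. = FALSE)
    }
    dimnames(rater$confusion) <- list(causes, causes)
  }
  missing <- setdiff(unique(cohort$true_cause), causes)
  if (length(missing) > 0) {
    stop("Confusion matrix lacks rows for true causes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(split_seed(seed, stream))
  }
  n <- nrow(cohort)
  idx <- match(cohort$true_cause, causes)
  # inverse-CDF draw per death from that death's confusion row
  cum <- t(apply(rater$confusion, 1, cumsum))
  u <- stats::runif(n)
  assigned <- causes[
    max.col(cum[idx, , drop = FALSE] >= u, ties.method = "first")
  ]
  if (rater$indeterminate_rate > 0) {
    assigned[stats::runif(n) < rater$indeterminate_rate] <- va_indeterminate()
  }
  assigned
}

#' Cohort CSV interchange
#'
#' Mirrors VA batch-file conventions: header
#' `id,age,sex,true_cause,<indicators...>[,hcod,pcva]`, with indicator cells
#' coded `Y` (present), `N` (absent) or empty (unknown).
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @param indicators Character vector naming the indicator columns; by
#'   default every column not in
#'   `id/age/sex/true_cause/hcod/pcva` is treated as an indicator.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort tibble with integer-coded indicators.
#' @export
write_cohort_csv <- function(cohort, path, indicators = NULL) {
  reserved <- c("id", "age", "sex", "true_cause", "hcod", "pcva")
  indicators <- indicators %||% setdiff(names(cohort), reserved)
  out <- cohort
  for (col in indicators) {
    out[[col]] <- dplyr::case_when(
      is.na(cohort[[col]]) ~ "",
      cohort[[col]] == 1 ~ "Y",
      TRUE ~ "N"
    )
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, indicators = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  reserved <- c("id", "age", "sex", "true_cause", "hcod", "pcva")
  indicators <- indicators %||% setdiff(names(df), reserved)
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  for (col in indicators) {
    v <- df[[col]]
    bad <- !(is.na(v) | v %in% c("Y", "N", ""))
    if (any(bad)) {
      stop("Invalid indicator value in column `", col, "`, line ",
           which(bad)[1] + 1L, ": `", v[bad][1],
           "` (expected Y, N or empty).", call. = FALSE)
    }
    df[[col]] <- dplyr::case_when(v == "Y" ~ 1L, v == "N" ~ 0L,
                                  .default = NA_integer_)
  }
  df
}
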