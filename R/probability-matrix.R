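#' Construct a cause/indicator probability matrix
#'
#' Bundles the quantities the Bayes engine needs: per-cause prior
#' probabilities and a matrix of emission probabilities
#' P(indicator present | cause). Designated causes whose local prevalence
#' varies strongly between settings (classically HIV and malaria) can later
#' have their priors scaled up or down with [apply_prevalence()].
#'
#' @param emit Numeric matrix, indicators in rows, causes in columns, all
#'   entries in `[0, 1]`. Row and column names are used as indicator and
#'   cause labels; unnamed dimensions get `ind1..n` / `cause1..k`.
#' @param priors Numeric vector of per-cause prior probabilities, one per
#'   column of `emit`; normalized to sum to 1. Default uniform.
#' @return An object of class `va_matrix`: a list with elements `emit`,
#'   `priors`, `causes`, `indicators`.
#' @seealso [build_probability_matrix()] for a simulated matrix,
#'   [read_matrix_csv()] / [write_matrix_csv()] for the CSV interchange format.
#' @export
va_matrix <- function(emit, priors = NULL) {
  emit <- as.matrix(emit)
  if (!is.numeric(emit) || any(!is.finite(emit)) ||
      any(emit < 0) || any(emit > 1)) {
    stop("All emission probabilities must be finite and in [0, 1].",
         call. = FALSE)
  }
  if (is.null(colnames(emit))) colnames(emit) <- paste0("cause", seq_len(ncol(emit)))
  if (is.null(rownames(emit))) rownames(emit) <- paste0("ind", seq_len(nrow(emit)))
  check_cause_list(colnames(emit))
  k <- ncol(emit)
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (length(priors) != k || any(!is.finite(priors)) || any(priors < 0) ||
      sum(priors) <= 0) {
    stop("`priors` must be ", k, " non-negative finite values with a ",
         "positive sum.", call. = FALSE)
  }
  priors <- priors / sum(priors)
  names(priors) <- colnames(emit)
  structure(
    list(
      emit = emit,
      priors = priors,
      causes = colnames(emit),
      indicators = rownames(emit)
    ),
    class = "va_matrix"
  )
}

#' @export
print.va_matrix <- function(x, ...) {
  cat("<va_matrix> ", length(x$causes), " causes x ",
      length(x$indicators), " indicators\n", sep = "")
  cat("causes: ", paste(utils::head(x$causes, 6), collapse = ", "),
      if (length(x$causes) > 6) ", ..." else "", "\n", sep = "")
  cat("priors: ", paste(signif(utils::head(x$priors, 6), 3), collapse = ", "),
      if (length(x$priors) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Build a synthetic signature-block probability matrix
#'
#' Each cause is given a random subset of "signature" indicators. Signature
#' indicators fire with probability `0.5 + 0.5 * informativeness`;
#' all other indicators fire with probability `0.5 * (1 - informativeness)`.
#' At `informativeness = 1` indicators are a deterministic function of the
#' cause; at `informativeness = 0` every indicator is a coin flip and carries
#' no information. Priors are uniform. The construction makes
#' `informativeness` a monotone difficulty dial for parameter-recovery
#' experiments.
#'
#' @param n_causes Number of causes (>= 2).
#' @param n_indicators Number of indicators (>= 1).
#' @param informativeness Separation of signature from background emissions,
#'   in `[0, 1]`.
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @param cause_names,indicator_names Optional label vectors.
#' @param signature_size Number of signature indicators per cause; default
#'   `max(1, floor(n_indicators / n_causes))` gives (near-)disjoint blocks.
#' @return A [va_matrix()] with an extra `signature` element: a logical
#'   indicators-by-causes matrix marking each cause's signature block.
#' @export
#' @examples
#' m <- build_probability_matrix(5, 30, informativeness = 0.8, seed = 1)
#' m$priors
build_probability_matrix <- function(n_causes, n_indicators,
                                     informativeness = 0.8, seed = NULL,
                                     cause_names = NULL,
                                     indicator_names = NULL,
                                     signature_size = NULL) {
  stopifnot(n_causes >= 2, n_indicators >= 1)
  if (!is.numeric(informativeness) || length(informativeness) != 1 ||
      !is.finite(informativeness) || informativeness < 0 || informativeness > 1) {
    stop("`informativeness` must be a single finite value in [0, 1].",
         call. = FALSE)
  }
  causes <- cause_names %||% paste0("cause", seq_len(n_causes))
  inds <- indicator_names %||% sprintf("ind%02d", seq_len(n_indicators))
  stopifnot(length(causes) == n_causes, length(inds) == n_indicators)
  signature_size <- signature_size %||% max(1L, floor(n_indicators / n_causes))

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(split_seed(seed, "matrix"))
  }
  hi <- 0.5 + 0.5 * informativeness
  lo <- 0.5 * (1 - informativeness)
  emit <- matrix(lo, n_indicators, n_causes, dimnames = list(inds, causes))
  signature <- matrix(FALSE, n_indicators, n_causes,
                      dimnames = list(inds, causes))
  for (j in seq_len(n_causes)) {
    sig <- sample.int(n_indicators, signature_size)
    emit[sig, j] <- hi
    signature[sig, j] <- TRUE
  }
  m <- va_matrix(emit)
  m$signature <- signature
  m
}

#' Write / read a probability matrix as CSV
#'
#' Interchange format: one row per indicator with the indicator name in the
#' first column and one column per cause, plus a final `_prior` row holding
#' the per-cause priors.
#'
#' @param matrix A [va_matrix()].
#' @param path File path.
#' @return `write_matrix_csv()` returns `path` invisibly; `read_matrix_csv()`
#'   returns a [va_matrix()].
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "va_matrix"))
  df <- tibble::as_tibble(matrix$emit)
  df <- dplyr::bind_cols(tibble::tibble(indicator = matrix$indicators), df)
  df <- dplyr::bind_rows(
    df,
    dplyr::bind_cols(tibble::tibble(indicator = "_prior"),
                     tibble::as_tibble(as.list(matrix$priors)))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "indicator" || !"_prior" %in% df$indicator) {
    stop("Not a probability-matrix CSV: expected an `indicator` first ",
         "column and a `_prior` row.", call. = FALSE)
  }
  pri <- df[df$indicator == "_prior", -1, drop = FALSE]
  emitdf <- df[df$indicator != "_prior", , drop = FALSE]
  emit <- as.matrix(emitdf[, -1, drop = FALSE])
  rownames(emit) <- emitdf$indicator
  va_matrix(emit, priors = as.numeric(pri[1, ]))
}
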