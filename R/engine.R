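#' Adjust cause priors for local prevalence
#'
#' InterVA-style engines take a "high"/"low" switch for causes whose
#' prevalence varies strongly between settings (HIV and malaria in coastal
#' East Africa). A flagged cause's prior is multiplied by the corresponding
#' multiplier and all priors are renormalized to sum to 1.
#'
#' @param matrix A [va_matrix()].
#' @param flags Named character vector, e.g.
#'   `c(HIV = "high", malaria = "high")`. Names must be causes in the matrix;
#'   values `"high"` or `"low"`.
#' @param multipliers Positive scalars applied to `"high"` and `"low"`
#'   priors. Prevalence of these causes can differ by more than an order of
#'   magnitude between settings; the defaults (5, 0.2) are reciprocal so a
#'   high-then-low round trip restores the original priors.
#' @return A [va_matrix()] with adjusted, renormalized priors.
#' @export
#' @examples
#' m <- va_matrix(matrix(0.5, 2, 4, dimnames = list(NULL, c("HIV", "TB", "CVD", "other"))))
#' apply_prevalence(m, c(HIV = "high"), multipliers = c(high = 3, low = 1/3))$priors
apply_prevalence <- function(matrix, flags,
                             multipliers = c(high = 5, low = 0.2)) {
  stopifnot(inherits(matrix, "va_matrix"))
  if (length(flags) == 0) return(matrix)
  if (is.null(names(flags)) || !all(nzchar(names(flags)))) {
    stop("`flags` must be named by cause.", call. = FALSE)
  }
  unknown <- setdiff(names(flags), matrix$causes)
  if (length(unknown) > 0) {
    stop("Prevalence flags reference unknown causes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(flags %in% c("high", "low"))) {
    stop("Prevalence flags must be \"high\" or \"low\".", call. = FALSE)
  }
  stopifnot(all(multipliers > 0), all(c("high", "low") %in% names(multipliers)))
  priors <- matrix$priors
  priors[names(flags)] <- priors[names(flags)] * multipliers[flags]
  matrix$priors <- priors / sum(priors)
  matrix
}

#' Posterior cause probabilities for indicator profiles
#'
#' The successive-indicator Bayes update: for each cause c,
#' `score(c) = prior(c) * prod_i L_i(c)` where a present indicator
#' contributes its emission probability, an absent indicator contributes one
#' minus it, and an unknown indicator contributes nothing (the conditional
#' independence assumption of naive Bayes). Scores are accumulated in log
#' space and normalized to sum to 1.
#'
#' A profile impossible under the matrix (every cause's score is zero, e.g. a
#' present indicator with emission probability 0 for all causes) yields a row
#' of `NA`: a degenerate posterior that callers treat as indeterminate.
#'
#' @param cohort Cohort tibble (or a single-row data frame / named vector of
#'   indicator values coded 1/0/NA).
#' @param matrix A [va_matrix()]; its indicators must all be columns of
#'   `cohort`.
#' @return A numeric matrix, deaths in rows (named by `id` when present),
#'   causes in columns; each non-degenerate row sums to 1.
#' @export
posterior_causes <- function(cohort, matrix) {
  stopifnot(inherits(matrix, "va_matrix"))
  if (!is.data.frame(cohort)) cohort <- tibble::as_tibble(as.list(cohort))
  missing <- setdiff(matrix$indicators, names(cohort))
  if (length(missing) > 0) {
    stop("Cohort lacks indicator columns: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  x <- as.matrix(cohort[, matrix$indicators, drop = FALSE]) # deaths x ind
  storage.mode(x) <- "numeric"
  if (any(!is.na(x) & !(x %in% c(0, 1)))) {
    stop("Indicator values must be 1 (present), 0 (absent) or NA (unknown).",
         call. = FALSE)
  }
  n <- nrow(x); k <- length(matrix$causes)
  log_emit <- log(matrix$emit)        # indicators x causes; log(0) = -Inf ok
  log_nemit <- log1p(-matrix$emit)
  present <- x; present[is.na(present)] <- 0
  absent <- 1 - x; absent[is.na(absent)] <- 0
  # (deaths x ind) %*% (ind x causes); -Inf * 0 handled by masking first
  loglik <- masked_mm(present, log_emit) + masked_mm(absent, log_nemit)
  logpost <- sweep(loglik, 2, log(matrix$priors), `+`)
  # normalize each row with log-sum-exp; all -Inf => degenerate
  mx <- apply(logpost, 1, max)
  degenerate <- !is.finite(mx)
  post <- exp(logpost - ifelse(is.finite(mx), mx, 0))
  post <- post / rowSums(post)
  post[degenerate, ] <- NA_real_
  ids <- if ("id" %in% names(cohort)) cohort$id else NULL
  dimnames(post) <- list(ids, matrix$causes)
  post
}

# weights %*% logmat with the convention 0 * -Inf = 0
masked_mm <- function(w, logmat) {
  finite <- logmat
  inf_mask <- !is.finite(logmat)
  finite[inf_mask] <- 0
  out <- w %*% finite
  if (any(inf_mask)) {
    hits <- w %*% (inf_mask * 1)      # count of -Inf terms actually weighted
    out[hits > 0] <- -Inf
  }
  out
}

#' Reporting policy for multi-cause output
#'
#' The engine reports up to three likely causes per death. The top cause is
#' reported only if its normalized posterior reaches `top_min` (otherwise
#' the death is indeterminate); a second or third cause is reported only if
#' its posterior is at least `extra_frac` times the top cause's and also
#' reaches `top_min`.
#'
#' @param top_min Minimum normalized posterior for any reported cause,
#'   in `(0, 1)`.
#' @param extra_frac Fraction of the top posterior a 2nd/3rd cause must
#'   reach, in `(0, 1]`.
#' @return An object of class `va_policy`.
#' @export
reporting_policy <- function(top_min = 0.4, extra_frac = 0.5) {
  stopifnot(top_min > 0, top_min < 1, extra_frac > 0, extra_frac <= 1)
  structure(list(top_min = top_min, extra_frac = extra_frac),
            class = "va_policy")
}

# Assignment for one posterior vector. Ties broken by cause-list order.
assign_one <- function(post, policy, causes) {
  if (anyNA(post)) {
    return(list(causes = character(0), liks = numeric(0), indeterminate = TRUE))
  }
  ord <- order(-post)                  # stable: ties keep cause-list order
  top <- post[ord[1]]
  if (top < policy$top_min) {
    return(list(causes = character(0), liks = numeric(0), indeterminate = TRUE))
  }
  keep <- ord[1]
  for (j in ord[2:min(3, length(ord))]) {
    if (post[j] >= policy$extra_frac * top && post[j] >= policy$top_min) {
      keep <- c(keep, j)
    }
  }
  list(causes = causes[keep], liks = unname(post[keep]), indeterminate = FALSE)
}

#' Assign up to three likely causes to every death
#'
#' Runs the Bayes update on every cohort row and applies the reporting
#' policy. The result is the engine's per-death output table; the
#' distribution of 1-, 2-, 3-cause and indeterminate outputs is available
#' via [output_mix()].
#'
#' @param cohort Cohort tibble with the matrix's indicator columns.
#' @param matrix A [va_matrix()] (apply [apply_prevalence()] first if
#'   needed).
#' @param policy A [reporting_policy()].
#' @return A tibble of class `va_assignments`: `id`, `cause1`, `lik1`,
#'   `cause2`, `lik2`, `cause3`, `lik3`, `indeterminate`. Likelihoods are
#'   normalized posteriors, non-increasing across the listed causes. The
#'   full posterior matrix is attached as attribute `"posterior"`.
#' @export
batch_assign <- function(cohort, matrix, policy = reporting_policy()) {
  stopifnot(inherits(policy, "va_policy"))
  post <- posterior_causes(cohort, matrix)
  n <- nrow(post)
  out <- tibble::tibble(
    id = if ("id" %in% names(cohort)) cohort$id else
      sprintf("d%05d", seq_len(n)),
    cause1 = NA_character_, lik1 = NA_real_,
    cause2 = NA_character_, lik2 = NA_real_,
    cause3 = NA_character_, lik3 = NA_real_,
    indeterminate = FALSE
  )
  for (i in seq_len(n)) {
    a <- assign_one(post[i, ], policy, matrix$causes)
    out$indeterminate[i] <- a$indeterminate
    m <- length(a$causes)
    if (m >= 1) { out$cause1[i] <- a$causes[1]; out$lik1[i] <- a$liks[1] }
    if (m >= 2) { out$cause2[i] <- a$causes[2]; out$lik2[i] <- a$liks[2] }
    if (m >= 3) { out$cause3[i] <- a$causes[3]; out$lik3[i] <- a$liks[3] }
  }
  attr(out, "posterior") <- post
  class(out) <- c("va_assignments", class(out))
  out
}

#' Distribution of single-, two-, three-cause and indeterminate outputs
#'
#' @param assignments A `va_assignments` tibble from [batch_assign()].
#' @return A tibble with `outcome` (`1 cause`, `2 causes`, `3 causes`,
#'   `indeterminate`), `n` and `percent` (round-half-up to integer; an
#'   empty input yields all-zero counts).
#' @export
output_mix <- function(assignments) {
  n_causes_listed <- ifelse(
    assignments$indeterminate, -1L,
    (!is.na(assignments$cause1)) + (!is.na(assignments$cause2)) +
      (!is.na(assignments$cause3))
  )
  lev <- c("1 cause", "2 causes", "3 causes", "indeterminate")
  outcome <- factor(
    dplyr::case_when(
      n_causes_listed == -1L ~ "indeterminate",
      n_causes_listed == 1L ~ "1 cause",
      n_causes_listed == 2L ~ "2 causes",
      n_causes_listed == 3L ~ "3 causes"
    ),
    levels = lev
  )
  counts <- as.integer(table(outcome))
  total <- sum(counts)
  tibble::tibble(
    outcome = lev,
    n = counts,
    percent = if (total == 0) rep(0, 4) else round_half_up(100 * counts / total)
  )
}

#' Primary cause for cross-tabulation, with 2nd/3rd-cause resolution
#'
#' When the engine's most likely cause disagrees with the reference (gold
#' standard) but the second or third listed cause matches it, the matching
#' cause is carried into the comparison instead. Indeterminate assignments
#' stay indeterminate.
#'
#' @param assignments A `va_assignments` tibble.
#' @param reference Character vector of reference causes, one per row.
#' @return Character vector of comparison causes.
#' @export
resolve_comparison_cause <- function(assignments, reference) {
  stopifnot(nrow(assignments) == length(reference))
  out <- assignments$cause1
  out[assignments$indeterminate] <- va_indeterminate()
  hit2 <- !assignments$indeterminate & !is.na(assignments$cause2) &
    assignments$cause1 != reference & assignments$cause2 == reference
  hit3 <- !assignments$indeterminate & !is.na(assignments$cause3) &
    assignments$cause1 != reference & !hit2 & assignments$cause3 == reference
  out[hit2] <- assignments$cause2[hit2]
  out[hit3] <- assignments$cause3[hit3]
  out
}

#' Assignment table CSV interchange
#'
#' @param assignments A `va_assignments` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assignments_csv <- function(assignments, path) {
  readr::write_csv(
    assignments[, c("id", "cause1", "lik1", "cause2", "lik2",
                    "cause3", "lik3", "indeterminate")],
    path, na = ""
  )
  invisible(path)
}
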