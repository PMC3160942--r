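small_matrix <- function() {
  emit <- matrix(
    c(0.8, 0.1,
      0.3, 0.7,
      0.5, 0.5),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("i1", "i2", "i3"), c("A", "B"))
  )
  va_matrix(emit)
}

test_that("prevalence adjustment renormalizes flagged priors", {
  m <- va_matrix(matrix(0.5, 2, 4,
                        dimnames = list(NULL, c("HIV", "TB", "CVD", "other"))))
  expect_identical(apply_prevalence(m, character(0))$priors, m$priors)

  adj <- apply_prevalence(m, c(HIV = "high"),
                          multipliers = c(high = 3, low = 1 / 3))
  expect_equal(unname(adj$priors), c(0.5, 1 / 6, 1 / 6, 1 / 6))
  expect_equal(sum(adj$priors), 1, tolerance = 1e-12)

  back <- apply_prevalence(adj, c(HIV = "low"),
                           multipliers = c(high = 3, low = 1 / 3))
  expect_equal(unname(back$priors), unname(m$priors), tolerance = 1e-12)

  expect_error(apply_prevalence(m, c(malaria = "high")), "unknown cause")
  expect_error(apply_prevalence(m, c(HIV = "medium")), "high")
})

test_that("posterior equals prior when every indicator is unknown", {
  m <- small_matrix()
  rec <- tibble::tibble(id = "d1", i1 = NA_integer_, i2 = NA_integer_,
                        i3 = NA_integer_)
  post <- posterior_causes(rec, m)
  expect_equal(unname(post[1, ]), unname(m$priors))
})

test_that("single present indicator reproduces the hand Bayes update", {
  m <- small_matrix()
  rec <- tibble::tibble(id = "d1", i1 = 1L, i2 = NA_integer_, i3 = NA_integer_)
  post <- posterior_causes(rec, m)
  # 0.5*0.8 : 0.5*0.1
  expect_equal(unname(post[1, ]), c(8 / 9, 1 / 9), tolerance = 1e-12)
})

test_that("an indicator with identical emissions cancels out", {
  m <- small_matrix()
  base <- posterior_causes(
    tibble::tibble(i1 = 1L, i2 = 0L, i3 = NA_integer_), m)
  on_ <- posterior_causes(tibble::tibble(i1 = 1L, i2 = 0L, i3 = 1L), m)
  off <- posterior_causes(tibble::tibble(i1 = 1L, i2 = 0L, i3 = 0L), m)
  expect_equal(unname(on_[1, ]), unname(base[1, ]), tolerance = 1e-12)
  expect_equal(unname(off[1, ]), unname(base[1, ]), tolerance = 1e-12)
})

test_that("log-space posterior matches the direct-product oracle", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    ni <- sample(3:8, 1)
    emit <- matrix(runif(ni * k), ni, k)
    priors <- runif(k); priors <- priors / sum(priors)
    m <- va_matrix(emit, priors)
    ind <- sample(c(0L, 1L, NA_integer_), ni, replace = TRUE)
    rec <- tibble::as_tibble(as.list(stats::setNames(ind, m$indicators)))
    got <- posterior_causes(rec, m)[1, ]
    want <- oracle_posterior(ind, m$priors, m$emit)
    expect_equal(unname(got), want, tolerance = 1e-9)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("a cause-favouring present indicator strictly increases that cause's posterior", {
  set.seed(7)
  for (rep in 1:20) {
    k <- 4; ni <- 6
    emit <- matrix(runif(ni * k, 0.05, 0.95), ni, k)
    # make indicator 1 favour cause 2
    emit[1, ] <- c(0.2, 0.9, 0.2, 0.2)
    m <- va_matrix(emit)
    others <- sample(c(0L, 1L, NA_integer_), ni - 1, replace = TRUE)
    without <- c(NA_integer_, others)
    with_ <- c(1L, others)
    rec <- function(v) tibble::as_tibble(as.list(stats::setNames(v, m$indicators)))
    p0 <- posterior_causes(rec(without), m)[1, 2]
    p1 <- posterior_causes(rec(with_), m)[1, 2]
    expect_gt(p1, p0)
  }
})

test_that("an impossible profile yields a degenerate posterior and indeterminate assignment", {
  emit <- matrix(c(0, 0, 0.5, 0.5), 2, 2, byrow = TRUE,
                 dimnames = list(c("i1", "i2"), c("A", "B")))
  m <- va_matrix(emit)
  rec <- tibble::tibble(id = "d1", i1 = 1L, i2 = 1L)
  post <- posterior_causes(rec, m)
  expect_true(all(is.na(post[1, ])))
  a <- batch_assign(rec, m)
  expect_true(a$indeterminate[1])
  expect_true(is.na(a$cause1[1]))
})

test_that("reporting policy gates top and extra causes", {
  causes <- c("A", "B", "C")
  mk <- function(post, policy) {
    vaval:::assign_one(stats::setNames(post, causes), policy, causes)
  }
  dom <- mk(c(0.9, 0.05, 0.05), reporting_policy(0.4, 0.5))
  expect_identical(dom$causes, "A")
  expect_false(dom$indeterminate)

  flat <- mk(c(0.34, 0.33, 0.33), reporting_policy(0.4, 0.5))
  expect_true(flat$indeterminate)
  expect_length(flat$causes, 0)

  two <- mk(c(0.5, 0.3, 0.2), reporting_policy(0.1, 0.5))
  expect_identical(two$causes, c("A", "B"))
  expect_identical(two$liks, c(0.5, 0.3))

  # tie broken by cause-list order
  tie <- mk(c(0.4, 0.4, 0.2), reporting_policy(0.1, 0.5))
  expect_identical(tie$causes[1], "A")
})

test_that("listed likelihoods are non-increasing and above threshold", {
  m <- build_probability_matrix(5, 20, informativeness = 0.6, seed = 3)
  co <- simulate_cohort(m, 100, flip_noise = 0.1, seed = 3)
  a <- batch_assign(co, m, reporting_policy(0.2, 0.3))
  for (i in seq_len(nrow(a))) {
    liks <- c(a$lik1[i], a$lik2[i], a$lik3[i])
    liks <- liks[!is.na(liks)]
    if (length(liks) > 1) expect_true(all(diff(liks) <= 1e-12))
    if (!a$indeterminate[i]) expect_true(all(liks >= 0.2))
  }
})

test_that("second/third-cause resolution picks the reference match", {
  a <- tibble::tibble(
    id = c("d1", "d2", "d3", "d4"),
    cause1 = c("TB", "TB", "TB", NA),
    lik1 = c(0.9, 0.6, 0.6, NA),
    cause2 = c(NA, "HIV", "HIV", NA),
    lik2 = c(NA, 0.3, 0.3, NA),
    cause3 = c(NA, NA, NA, NA),
    lik3 = c(NA, NA, NA, NA),
    indeterminate = c(FALSE, FALSE, FALSE, TRUE)
  )
  ref <- c("TB", "HIV", "CVD", "TB")
  expect_identical(resolve_comparison_cause(a, ref),
                   c("TB", "HIV", "TB", va_indeterminate()))
})

test_that("output mix counts and round-half-up percentages", {
  mk_assign <- function(n1, n2, n3, nind) {
    tibble::tibble(
      id = sprintf("d%03d", seq_len(n1 + n2 + n3 + nind)),
      cause1 = c(rep("A", n1 + n2 + n3), rep(NA, nind)),
      lik1 = 0.9,
      cause2 = c(rep(NA, n1), rep("B", n2 + n3), rep(NA, nind)),
      lik2 = 0.5,
      cause3 = c(rep(NA, n1 + n2), rep("C", n3), rep(NA, nind)),
      lik3 = 0.4,
      indeterminate = c(rep(FALSE, n1 + n2 + n3), rep(TRUE, nind))
    )
  }
  mix <- output_mix(mk_assign(118, 20, 2, 5))
  expect_identical(mix$n, c(118L, 20L, 2L, 5L))
  expect_identical(mix$percent, c(81, 14, 1, 3))

  empty <- output_mix(mk_assign(0, 0, 0, 0))
  expect_identical(empty$n, rep(0L, 4))
  expect_identical(empty$percent, rep(0, 4))
})

test_that("a sharply informative cohort is assigned a single cause throughout", {
  m <- build_probability_matrix(4, 20, informativeness = 1, seed = 5)
  co <- simulate_cohort(m, 60, seed = 5)
  mix <- output_mix(batch_assign(co, m))
  expect_identical(mix$percent[mix$outcome == "1 cause"], 100)
})

test_that("matrix CSV round-trips through the interchange format", {
  m <- build_probability_matrix(4, 10, seed = 2)
  m <- apply_prevalence(m, c(cause2 = "high"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, f)
  back <- read_matrix_csv(f)
  expect_equal(back$emit, m$emit)
  expect_equal(back$priors, m$priors)
})
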