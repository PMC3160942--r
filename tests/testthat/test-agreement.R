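test_that("CSMF reproduces hand fractions and sums to one", {
  d <- tibble::tibble(cod = c(rep("HIV/AIDS-related death", 38),
                              rep("other", 107)))
  cs <- csmf(d, cod)
  expect_identical(cs$n[cs$cause == "HIV/AIDS-related death"], 38L)
  expect_identical(cs$percent[cs$cause == "HIV/AIDS-related death"], 26.2)
  expect_equal(sum(cs$fraction), 1, tolerance = 1e-9)

  d2 <- tibble::tibble(cod = c(rep("meningitis", 9), rep("other", 136)))
  expect_identical(csmf(d2, cod)$percent[1], 6.2)

  one <- csmf(tibble::tibble(cod = rep("A", 10)), cod,
              categories = c("A", "B"))
  expect_identical(one$percent, c(100, 0, 0))

  expect_error(csmf(tibble::tibble(cod = character(0)), cod), "zero deaths")
  expect_error(csmf(d, cod, categories = "other"), "outside")
})

test_that("CSMF tolerance check flags differences beyond the band", {
  a <- csmf(tibble::tibble(cod = c(rep("HIV", 38), rep("x", 107))), cod,
            categories = c("HIV", "x"))
  g <- csmf(tibble::tibble(cod = c(rep("HIV", 33), rep("x", 112))), cod,
            categories = c("HIV", "x"))
  tc <- csmf_tolerance_check(a, g, tolerance = 5)
  expect_true(all(tc$pass))
  expect_true(all(csmf_tolerance_check(a, a)$pass))

  far <- csmf(tibble::tibble(cod = c(rep("HIV", 15), rep("x", 130))), cod,
              categories = c("HIV", "x"))
  tc2 <- csmf_tolerance_check(a, far, tolerance = 5)
  expect_false(tc2$pass[tc2$cause == "HIV"])
})

test_that("contingency matches a brute-force cross-tab", {
  a <- c("x", "x", "y", "z", "y", "x")
  b <- c("x", "y", "y", "z", "x", "x")
  tab <- contingency(tibble::tibble(a = a, b = b), a, b,
                     categories = c("x", "y", "z"))
  for (i in c("x", "y", "z")) for (j in c("x", "y", "z")) {
    expect_identical(tab[i, j], sum(a == i & b == j))
  }
  expect_identical(sum(tab), 6L)

  same <- contingency(tibble::tibble(a = a, b = a), a, b)
  expect_true(all(same[upper.tri(same) | lower.tri(same)] == 0))

  disjoint <- contingency(tibble::tibble(a = rep("x", 3), b = rep("y", 3)),
                          a, b, categories = c("x", "y"))
  expect_true(all(diag(disjoint) == 0))
})

test_that("Cohen's kappa reproduces hand-computed values", {
  # identical raters
  d <- tibble::tibble(a = c("x", "y", "z", "x"), b = c("x", "y", "z", "x"))
  expect_equal(cohen_kappa(d, a, b)$kappa, 1)

  # balanced 2x2, agreement exactly at chance
  k0 <- cohen_kappa(matrix(c(25, 25, 25, 25), 2, 2))
  expect_equal(k0$kappa, 0)
  expect_equal(k0$p_a, 0.5)
  expect_equal(k0$p_e, 0.5)

  # 3x3 hand computation: P_A = 0.8, P_E = 0.34
  tab <- matrix(c(10, 2, 0, 1, 12, 3, 0, 2, 10), 3, 3, byrow = TRUE)
  k <- cohen_kappa(tab)
  expect_equal(k$p_a, 0.8)
  expect_equal(k$p_e, 0.34)
  expect_equal(k$kappa, 0.697, tolerance = 5e-4)
  expect_identical(k$strength, "good")
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
})

test_that("kappa is symmetric, bounded, and 1 only for diagonal tables", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    tab <- matrix(rpois(k * k, 3), k, k)
    if (sum(tab) == 0 || sum(diag(tab)) == sum(tab)) next
    ka <- suppressWarnings(cohen_kappa(tab)$kappa)
    kb <- suppressWarnings(cohen_kappa(t(tab))$kappa)
    if (is.na(ka)) next
    expect_equal(ka, kb, tolerance = 1e-12)
    expect_true(ka >= -1 && ka <= 1)
    expect_lt(ka, 1)
  }
})

test_that("constant identical raters leave kappa undefined", {
  d <- tibble::tibble(a = rep("x", 5), b = rep("x", 5))
  expect_warning(k <- cohen_kappa(d, a, b), "undefined")
  expect_true(is.na(k$kappa))
})

test_that("indeterminate never agrees under the default convention", {
  ind <- va_indeterminate()
  d <- tibble::tibble(a = c("x", ind, ind), b = c("x", ind, "x"))
  tab <- contingency(d, a, b, categories = "x")
  k_mismatch <- cohen_kappa(tab)
  # only the (x, x) pair agrees; two shared indeterminates do not
  expect_equal(k_mismatch$p_a, 1 / 3)
  k_agree <- cohen_kappa(tab, indeterminate = "agree")
  expect_equal(k_agree$p_a, 2 / 3)
  k_drop <- suppressWarnings(cohen_kappa(tab, indeterminate = "drop"))
  expect_equal(k_drop$n, 1)
})

test_that("kappa matches e1071's independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    n <- sample(10:50, 1)
    a <- random_labels(n, k)
    b <- if (runif(1) < 0.5) a else random_labels(n, k)
    lev <- paste0("c", seq_len(k))
    tab <- table(factor(a, lev), factor(b, lev))
    ref <- e1071::classAgreement(tab)$kappa
    got <- suppressWarnings(cohen_kappa(unclass(as.matrix(tab)))$kappa)
    if (is.na(ref) || is.nan(ref) || is.na(got)) next
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("Fleiss' kappa reproduces limits and the brute-force formula", {
  # all three raters identical
  d <- tibble::tibble(r1 = c("x", "y", "z", "x", "y"))
  d$r2 <- d$r1; d$r3 <- d$r1
  expect_equal(multirater_kappa(d, r1, r2, r3, boot = 0)$kappa, 1)

  # hand-worked 6-subject 2-category table
  ratings <- rbind(
    c("a", "a", "a"), c("a", "a", "b"), c("b", "b", "b"),
    c("a", "b", "b"), c("b", "b", "a"), c("a", "a", "a")
  )
  d2 <- tibble::tibble(r1 = ratings[, 1], r2 = ratings[, 2], r3 = ratings[, 3])
  got <- multirater_kappa(d2, r1, r2, r3, boot = 0)$kappa
  expect_equal(got, oracle_fleiss_kappa(ratings), tolerance = 1e-12)
})

test_that("independent uniform raters give Fleiss kappa near zero", {
  set.seed(31)
  n <- 5000
  d <- tibble::tibble(
    r1 = random_labels(n, 4), r2 = random_labels(n, 4),
    r3 = random_labels(n, 4)
  )
  k <- multirater_kappa(d, r1, r2, r3, boot = 0)$kappa
  expect_lt(abs(k), 0.05)
})

test_that("two-rater Fleiss is close to Cohen on balanced data", {
  set.seed(41)
  n <- 2000
  a <- random_labels(n, 3)
  agree <- runif(n) < 0.6
  b <- ifelse(agree, a, random_labels(n, 3))
  d <- tibble::tibble(a = a, b = b)
  kc <- cohen_kappa(d, a, b)$kappa
  kf <- multirater_kappa(d, a, b, boot = 0)$kappa
  expect_lt(abs(kc - kf), 0.02)
})

test_that("bootstrap CI brackets the multirater kappa and respects the seed", {
  set.seed(51)
  n <- 100
  a <- random_labels(n, 3)
  d <- tibble::tibble(r1 = a,
                      r2 = ifelse(runif(n) < 0.7, a, random_labels(n, 3)),
                      r3 = ifelse(runif(n) < 0.7, a, random_labels(n, 3)))
  k1 <- multirater_kappa(d, r1, r2, r3, boot = 300, seed = 5)
  k2 <- multirater_kappa(d, r1, r2, r3, boot = 300, seed = 5)
  expect_identical(k1$ci_low, k2$ci_low)
  expect_true(k1$ci_low <= k1$kappa && k1$kappa <= k1$ci_high)
})

test_that("rater vectors of different lengths are rejected", {
  d <- tibble::tibble(r1 = c("x", "y"), r2 = c("x", "y"))
  expect_error(multirater_kappa(d, r1), "two rater")
})

test_that("strength scale bands label kappa as conventional", {
  expect_identical(kappa_strength(0.52), "moderate")
  expect_identical(kappa_strength(0.32), "fair")
  expect_identical(kappa_strength(0.90), "very good")
  # upper boundaries inclusive
  expect_identical(kappa_strength(c(0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80, 0.81)),
                   c("poor", "fair", "fair", "moderate", "moderate", "good",
                     "good", "very good"))
  expect_identical(kappa_strength(-0.5), "poor")
  expect_error(kappa_strength(1.2), "\\[-1, 1\\]")
})

test_that("agreement indicator needs two matching non-indeterminate labels", {
  ind <- va_indeterminate()
  expect_identical(agreement_indicator("HIV", "HIV", "TB"), 1L)
  expect_identical(agreement_indicator("HIV", "TB", "CVD"), 0L)
  expect_identical(agreement_indicator(ind, ind, "HIV"), 0L)
  expect_identical(agreement_indicator("HIV", ind, "HIV"), 1L)
  expect_identical(
    agreement_indicator(c("a", "b"), c("a", "c"), c("x", "y")),
    c(1L, 0L)
  )
})
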