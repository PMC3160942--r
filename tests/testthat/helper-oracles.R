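# Independent brute-force oracles. These deliberately avoid the package's
# own computation paths: plain loops, direct formulas, full enumeration.

# Cohen's kappa straight from paired label vectors by counting.
oracle_cohen_kappa <- function(a, b) {
  n <- length(a)
  lev <- union(a, b)
  p_a <- sum(a == b) / n
  p_e <- 0
  for (l in lev) {
    p_e <- p_e + (sum(a == l) / n) * (sum(b == l) / n)
  }
  (p_a - p_e) / (1 - p_e)
}

# Fleiss' kappa from a subjects x raters character matrix, formula by hand.
oracle_fleiss_kappa <- function(ratings) {
  lev <- sort(unique(as.vector(ratings)))
  n <- nrow(ratings); m <- ncol(ratings)
  p_i <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- sapply(lev, function(l) sum(ratings[i, ] == l))
    p_i[i] <- (sum(cnt^2) - m) / (m * (m - 1))
  }
  p_j <- sapply(lev, function(l) sum(ratings == l)) / (n * m)
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

# One-vs-rest 2x2 metrics by explicit looping.
oracle_validity <- function(pred, gold, cause) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == cause
    g <- gold[i] == cause
    if (p && g) tp <- tp + 1
    if (p && !g) fp <- fp + 1
    if (!p && g) fn <- fn + 1
    if (!p && !g) tn <- tn + 1
  }
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
  )
}

# Mann-Whitney concordance over every (positive, negative) score pair.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Trapezoid area from sorted (x, y) points, summed segment by segment.
oracle_trapezoid <- function(x, y) {
  a <- 0
  for (i in seq_len(length(x) - 1)) {
    a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  a
}

# Direct-product naive-Bayes posterior (no log space), one record.
oracle_posterior <- function(ind, priors, emit) {
  k <- length(priors)
  score <- numeric(k)
  for (c in seq_len(k)) {
    s <- priors[c]
    for (i in seq_along(ind)) {
      if (is.na(ind[i])) next
      s <- s * if (ind[i] == 1) emit[i, c] else 1 - emit[i, c]
    }
    score[c] <- s
  }
  if (sum(score) == 0) return(rep(NA_real_, k))
  score / sum(score)
}

# Small helper: random label vectors over k categories.
random_labels <- function(n, k, prefix = "c") {
  sample(paste0(prefix, seq_len(k)), n, replace = TRUE)
}
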