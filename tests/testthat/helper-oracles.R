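# Independent oracles used to cross-check the package's own algorithms.
# These deliberately re-derive each quantity by brute force or through a
# different code path (stats::lm, exhaustive enumeration, finite
# differences) and never call the implementation they check.

# Global 1-D K-means optimum by exhaustive enumeration of contiguous
# partitions of the sorted values (optimal 1-D clusters are contiguous).
kmeans_1d_exhaustive <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  if (k == 1) return(sum((xs - mean(xs))^2))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    e <- 0
    for (g in seq_len(k)) {
      seg <- xs[(bounds[g] + 1):bounds[g + 1]]
      e <- e + sum((seg - mean(seg))^2)
    }
    best <- min(best, e)
  }
  best
}

# Double-loop transliteration of the Garson partitioning formula.
garson_oracle <- function(W1, W2) {
  n_in <- nrow(W1)
  m <- ncol(W1)
  r <- matrix(0, n_in, m)
  for (j in seq_len(m)) {
    tot <- 0
    for (i in seq_len(n_in)) tot <- tot + abs(W1[i, j] * W2[j])
    if (tot == 0) next
    for (i in seq_len(n_in)) r[i, j] <- abs(W1[i, j] * W2[j]) / tot
  }
  ri <- numeric(n_in)
  for (i in seq_len(n_in)) ri[i] <- sum(r[i, ])
  100 * ri / sum(ri)
}

# Central finite-difference gradient of the half-SSE cost with respect to
# every parameter of a network, via the public forward pass only.
numeric_gradients <- function(params, X, y, h = 1e-6) {
  cost <- function(p) {
    pred <- ann_forward(p, X)
    0.5 * sum((pred - y)^2)
  }
  grad_of <- function(name) {
    g <- params[[name]]
    for (idx in seq_along(params[[name]])) {
      up <- params; up[[name]][idx] <- up[[name]][idx] + h
      dn <- params; dn[[name]][idx] <- dn[[name]][idx] - h
      g[idx] <- (cost(up) - cost(dn)) / (2 * h)
    }
    g
  }
  list(W1 = grad_of("W1"), b1 = grad_of("b1"),
       W2 = grad_of("W2"), b2 = grad_of("b2"))
}

# Rank drivers by |standardized OLS coefficient| of log(CHLA) on the five
# inputs -- the regression oracle for ground-truth recoverability.
ols_driver_ranking <- function(data) {
  d <- data.frame(scale(data[c("WT", "EC", "TN", "TP", "Q")]),
                  y = log(data$CHLA))
  fit <- stats::lm(y ~ WT + EC + TN + TP + Q, data = d)
  b <- abs(stats::coef(fit)[-1])
  names(sort(b, decreasing = TRUE))
}

# Small deterministic monitoring table for plumbing tests.
toy_monitoring <- function(n = 12) {
  tibble::tibble(
    date = as.Date("2015-01-01") + seq_len(n) - 1,
    WT = seq(5, 28, length.out = n),
    EC = seq(500, 300, length.out = n),
    TN = rep(3.8, n) + seq(-0.5, 0.5, length.out = n),
    TP = seq(0.02, 0.05, length.out = n),
    Q = seq(30, 400, length.out = n),
    CHLA = seq(10, 40, length.out = n)
  )
}
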