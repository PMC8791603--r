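# Independent brute-force oracles used to validate the implementation.
# Deliberately naive and separate from the package code paths.

# Connected-component labeling by queue-based flood fill (8- or
# 4-connectivity); returns an integer matrix of provisional labels in
# scan order.
flood_fill_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nbr <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nbr <- cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  lbl <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    lbl <- lbl + 1L
    queue <- list(c(i, j))
    lab[i, j] <- lbl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        qi <- p[1] + nbr[k, 1]; qj <- p[2] + nbr[k, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- lbl
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# Compare two labelings as partitions (label ids may differ).
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  on <- which(a > 0)
  if (!length(on)) return(TRUE)
  key_a <- a[on]; key_b <- b[on]
  identical(as.integer(factor(key_a, levels = unique(key_a))),
            as.integer(factor(key_b, levels = unique(key_b))))
}

# Exhaustive Otsu: maximize between-class variance over every candidate
# threshold halfway between consecutive distinct values.
otsu_oracle <- function(x) {
  v <- sort(unique(as.vector(x)))
  cand <- (v[-1] + v[-length(v)]) / 2
  bcv <- vapply(cand, function(th) {
    lo <- x[x <= th]; hi <- x[x > th]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# Naive gamma sampler via inverse-CDF, independent of rgamma's algorithm.
naive_gamma <- function(n, mean, shape) {
  qgamma(runif(n), shape = shape, rate = shape / mean)
}

# Pooled means by an explicit loop.
naive_pooled_means <- function(durations, window) {
  out <- numeric(0)
  i <- 1L
  while (i + window - 1L <= length(durations)) {
    acc <- 0
    for (k in seq_len(window)) acc <- acc + durations[i + k - 1L]
    out <- c(out, acc / window)
    i <- i + window
  }
  out
}

# One-way ANOVA from the raw sum-of-squares decomposition.
anova_oracle <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  F <- (ss_between / df1) / (ss_within / df2)
  list(ss_between = ss_between, ss_within = ss_within, df1 = df1,
       df2 = df2, F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Polyline length by pairwise distance summation.
polyline_length <- function(v) {
  sum(sqrt(rowSums((v[-1, , drop = FALSE] -
                      v[-nrow(v), , drop = FALSE])^2)))
}
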