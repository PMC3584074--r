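# Independent brute-force oracles used to cross-check the package's metric
# implementations. These deliberately share no code with the package: plain
# loops and textbook formulas only.

# consumer NODF by direct enumeration of column pairs
oracle_nodf_consumers <- function(a, original = FALSE) {
  deg <- colSums(a)
  S <- ncol(a)
  # stable descending sort of columns by degree
  ord <- order(-deg)
  a <- a[, ord, drop = FALSE]
  deg <- deg[ord]
  vals <- c()
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      if (deg[j] == 0) next
      if (deg[i] == deg[j]) {
        if (original) vals <- c(vals, 0)
        next
      }
      shared <- 0
      for (row in seq_len(nrow(a))) {
        if (a[row, i] == 1 && a[row, j] == 1) shared <- shared + 1
      }
      vals <- c(vals, 100 * shared / deg[j])
    }
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Spearman rho with average ranks, from first principles
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# OLS slope/intercept/R^2 from textbook sums
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# two-sample KS D as the sup of |ECDF1 - ECDF2| over all pooled points
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (p in pts) {
    d <- max(d, abs(mean(x <= p) - mean(y <= p)))
  }
  d
}

# random 0/1 matrix that has at least one link
random_binary_matrix <- function(nr, nc, p = 0.4) {
  repeat {
    a <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (sum(a) >= 1) return(a)
  }
}
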