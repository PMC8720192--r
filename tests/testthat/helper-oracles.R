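# Independent brute-force oracles. Each recomputes a statistic from first
# principles, on a different code path than the package implementation.

# ICC(A,1) through R's ANOVA machinery on the long-format two-way layout
oracle_icc_a1 <- function(scan1, scan2) {
  n <- length(scan1)
  long <- data.frame(
    y = c(scan1, scan2),
    subject = factor(rep(seq_len(n), 2L)),
    session = factor(rep(1:2, each = n))
  )
  ms <- anova(stats::aov(y ~ subject + session, data = long))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["session", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Cronbach alpha from the item covariance matrix: alpha =
# k/(k-1) * (1 - trace(C) / sum(C))
oracle_cronbach <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  cmat <- stats::cov(items)
  k <- ncol(items)
  k / (k - 1) * (1 - sum(diag(cmat)) / sum(cmat))
}

# Cohen's d written long-hand
oracle_cohen_d <- function(values, group) {
  v1 <- values[group == 1]
  v0 <- values[group == 0]
  n1 <- length(v1); n0 <- length(v0)
  s1 <- sum((v1 - mean(v1))^2) / (n1 - 1)
  s0 <- sum((v0 - mean(v0))^2) / (n0 - 1)
  sp <- sqrt(((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2))
  (mean(v1) - mean(v0)) / sp
}

# Spearman rho with hand-computed average ranks, plus the t-approximation p
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

# KS statistic as the max ECDF gap over all observed points, with the
# asymptotic Kolmogorov-series p value
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  gaps <- vapply(pts, function(s) {
    abs(mean(a <= s) - mean(b <= s))
  }, numeric(1))
  d <- max(gaps)
  t <- sqrt(length(a) * length(b) / (length(a) + length(b))) * d
  k <- 1:300
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(statistic = d, p = min(max(p, 0), 1))
}

# exhaustive nearest-neighbour imputation: all pair distances over shared
# observed columns, then k-nearest donor means
oracle_knn <- function(mat, k) {
  out <- mat
  n <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    for (i in which(is.na(mat[, j]))) {
      d <- rep(Inf, n)
      for (r in seq_len(n)) {
        if (r == i || is.na(mat[r, j])) next
        shared <- which(!is.na(mat[i, ]) & !is.na(mat[r, ]))
        if (!length(shared)) next
        d[r] <- sqrt(sum((mat[i, shared] - mat[r, shared])^2))
      }
      donors <- order(d)[seq_len(k)]
      out[i, j] <- mean(mat[donors, j])
    }
  }
  out
}

# mid-percentile rank by direct counting
oracle_percentile <- function(sample, s) {
  100 * (sum(sample < s) + 0.5 * sum(sample == s)) / length(sample)
}
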