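# From-scratch textbook oracles, kept independent of the package code
# paths they are used to check.

# Pearson correlation from the raw covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# Two-way fixed-effects ANOVA (one observation per block x treatment
# cell) by explicit sums of squares; returns F and p for the treatment.
anova_block_oracle <- function(y, block, treat) {
  block <- as.factor(block)
  treat <- as.factor(treat)
  b <- nlevels(block)
  t <- nlevels(treat)
  g <- mean(y)
  ss_total <- sum((y - g)^2)
  ss_block <- t * sum((tapply(y, block, mean) - g)^2)
  ss_treat <- b * sum((tapply(y, treat, mean) - g)^2)
  ss_err <- ss_total - ss_block - ss_treat
  df_treat <- t - 1L
  df_err <- (b - 1L) * (t - 1L)
  f <- (ss_treat / df_treat) / (ss_err / df_err)
  c(F = f, p = stats::pf(f, df_treat, df_err, lower.tail = FALSE))
}

# Classical MDS by explicit double-centering and eigendecomposition.
cmds_oracle <- function(d, k) {
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  list(points = pts, values = e$values)
}

# Align the columns of two coordinate matrices up to sign flips.
align_signs <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  }
  b
}

# TRUE for each patient whose samples form a pure subtree of hc.
pure_subtrees <- function(hc, patients) {
  leafsets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    s <- integer(0L)
    for (x in hc$merge[i, ]) {
      s <- c(s, if (x < 0) -x else leafsets[[x]])
    }
    leafsets[[i]] <- s
  }
  vapply(unique(patients), function(p) {
    idx <- which(patients == p)
    if (length(idx) == 1L) return(TRUE)
    any(vapply(leafsets, function(s) {
      length(s) == length(idx) && setequal(s, idx)
    }, logical(1L)))
  }, logical(1L))
}

# A simple analytic chromatogram: sum of Gaussians evaluated on a grid.
gaussian_trace <- function(id, mu, amp, sigma, from, to, step = 0.005) {
  t <- seq(from, to, by = step)
  y <- numeric(length(t))
  for (k in seq_along(mu)) {
    y <- y + amp[k] * exp(-(t - mu[k])^2 / (2 * sigma[k]^2))
  }
  chromatogram(id, t, y)
}

# Peak lists placed at known apex positions (for matching tests where
# detection is not under test).
apex_peak_list <- function(apex, half_width = 0.1) {
  data.frame(apex = apex, left = apex - half_width,
             right = apex + half_width, height = 1, area = 1)
}
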