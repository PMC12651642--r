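# Independent straight-line oracles used to cross-check the implementation.
# Each is written as a direct, loop-based evaluation of the defining formulas
# and shares no code with the package internals.

# Reciprocal matrix -> column normalization -> row-mean weights -> AW,
# lambda_max (mean of component ratios), CI, CR.
oracle_ahp <- function(A, ri = 1.49) {
  n <- nrow(A)
  N <- matrix(0, n, n)
  for (j in 1:n) {
    s <- 0
    for (i in 1:n) s <- s + A[i, j]
    for (i in 1:n) N[i, j] <- A[i, j] / s
  }
  w <- numeric(n)
  for (i in 1:n) w[i] <- sum(N[i, ]) / n
  aw <- numeric(n)
  for (i in 1:n) aw[i] <- sum(A[i, ] * w)
  lambda <- mean(aw / w)
  ci <- (lambda - n) / (n - 1)
  list(N = N, w = w, lambda = lambda, ci = ci, cr = ci / ri)
}

# Weighted matrix + ideal pair -> D+, D-, closeness, elementwise loops.
oracle_topsis <- function(W, pos, neg) {
  n <- nrow(W)
  out <- data.frame(d_plus = numeric(n), d_minus = numeric(n),
                    closeness = numeric(n))
  for (i in 1:n) {
    dp <- 0; dm <- 0
    for (j in 1:ncol(W)) {
      dp <- dp + (W[i, j] - pos[j])^2
      dm <- dm + (W[i, j] - neg[j])^2
    }
    out$d_plus[i] <- sqrt(dp)
    out$d_minus[i] <- sqrt(dm)
    out$closeness[i] <- sqrt(dm) / (sqrt(dp) + sqrt(dm))
  }
  out
}

# One-vs-rest metrics from a contingency table, direct formula evaluation.
oracle_metrics <- function(tab) {
  n <- sum(tab)
  levs <- rownames(tab)
  per <- lapply(seq_along(levs), function(i) {
    tp <- tab[i, i]
    fp <- sum(tab[, i]) - tp
    fn <- sum(tab[i, ]) - tp
    tn <- n - tp - fp - fn
    acc <- (tp + tn) / (tp + tn + fp + fn)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    c(accuracy = acc, precision = prec, recall = rec, f1 = f1, mcc = mcc)
  })
  do.call(rbind, per)
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# ranks (tie-free inputs only).
oracle_mwu_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Principal eigenvalue by power iteration (diagnostic cross-check for the
# ratio-average lambda_max).
oracle_power_eigen <- function(A, iters = 500) {
  v <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(A %*% v)
    v <- v2 / sqrt(sum(v2^2))
  }
  as.numeric(t(v) %*% A %*% v) / as.numeric(t(v) %*% v)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "thalrisk", mustWork = TRUE)
}

table10_matrix <- function() {
  df <- utils::read.csv(fixture_path("table10_normalized.csv"))
  m <- as.matrix(df[, -1])
  colnames(m) <- names(df)[-1]
  m
}

table9_weight_vector <- function() {
  df <- utils::read.csv(fixture_path("table9_weights.csv"))
  stats::setNames(df$weight, df$feature)
}
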