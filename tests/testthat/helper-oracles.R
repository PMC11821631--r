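# Independent reference implementations used as oracles. These deliberately
# use the most direct (often brute-force) formulation so they share no code
# with the package internals they check.

# exhaustive rolling-median maximum: O(n * w)
oracle_mvic <- function(x, window, floor = 20) {
  n <- length(x)
  h <- (window - 1) / 2
  best <- NA_real_
  for (c in (h + 1):(n - h)) {
    if (x[c] > floor) {
      m <- median(x[(c - h):(c + h)])
      if (is.na(best) || m > best) best <- m
    }
  }
  best
}

# O(n^2) pairwise AUROC with half-credit ties
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# contraction-velocity formulas coded independently, scalar at a time
oracle_vc <- function(dm, td, tc) {
  c(Vc0_10 = 1000 * 0.1 * dm / td,
    Vc0_90 = 1000 * 0.9 * dm / (td + tc),
    Vc10_90 = 1000 * 0.8 * dm / tc,
    Vcnorm = 1000 * 0.8 / tc)
}

# paired t statistic from first principles
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# ICC(A,1) via aov() mean squares (different decomposition path than the
# package's direct sums of squares)
oracle_icc_a1 <- function(x1, x2) {
  n <- length(x1)
  d <- data.frame(y = c(x1, x2),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# dense-grid maximiser of the raw bi-exponential pulse
oracle_biexp_peak <- function(tau_rise, tau_decay, onset, grid_ms = 2000,
                              step_ms = 0.001) {
  t <- seq(0, grid_ms, by = step_ms)
  s <- t - onset
  v <- ifelse(s > 0, exp(-s / tau_decay) - exp(-s / tau_rise), 0)
  list(t_peak = t[which.max(v)], v_peak = max(v))
}

# displacement parameters from a 10x oversampled trace by direct crossing
# search (reference extraction for the sampled-path implementation)
oracle_displacement <- function(shape, oversample_rate = 10000,
                                duration_ms = 600) {
  t_ms <- seq(0, duration_ms, by = 1000 / oversample_rate)
  v <- tmgtwitch:::eval_twitch(shape, t_ms)
  dm <- max(v)
  i10 <- which(v >= 0.1 * dm)[1]
  i90 <- which(v >= 0.9 * dm)[1]
  interp <- function(i, level) {
    t_ms[i - 1] + (level - v[i - 1]) / (v[i] - v[i - 1]) *
      (t_ms[i] - t_ms[i - 1])
  }
  t10 <- interp(i10, 0.1 * dm)
  t90 <- interp(i90, 0.9 * dm)
  c(Dm = dm, Td = t10, Tc = t90 - t10)
}
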