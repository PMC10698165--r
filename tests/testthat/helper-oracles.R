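# Independent oracles used across the suite. These are deliberately
# written with different algorithms than the package internals.

# Exact Kalman filter + RTS smoother for the local-level model with
# replicate observations, at fixed (Q, R). Returns smoothed means and
# variances per year. n_t/s_t are per-year counts and sums on the full
# grid (n_t = 0 for missing years).
kalman_smoother_oracle <- function(n_t, s_t, Q, R, m0, C0) {
  T <- length(n_t)
  m_f <- C_f <- m_p <- C_p <- numeric(T)
  for (t in seq_len(T)) {
    a <- if (t == 1) m0 else m_f[t - 1]
    P <- if (t == 1) C0 else C_f[t - 1] + Q
    m_p[t] <- a; C_p[t] <- P
    if (n_t[t] > 0) {
      # treat the yearly mean as one observation with variance R/n_t
      ybar <- s_t[t] / n_t[t]
      Rbar <- R / n_t[t]
      K <- P / (P + Rbar)
      m_f[t] <- a + K * (ybar - a)
      C_f[t] <- (1 - K) * P
    } else {
      m_f[t] <- a; C_f[t] <- P
    }
  }
  m_s <- m_f; C_s <- C_f
  for (t in seq.int(T - 1, 1)) {
    J <- C_f[t] / C_p[t + 1]
    m_s[t] <- m_f[t] + J * (m_s[t + 1] - m_p[t + 1])
    C_s[t] <- C_f[t] + J^2 * (C_s[t + 1] - C_p[t + 1])
  }
  list(mean = m_s, var = C_s)
}

# Brute-force joint-Gaussian conditioning for the same model: the prior
# of (x_1..x_T) is multivariate normal with Cov(x_s, x_t) =
# C0 + Q * (min(s,t) - 1); observations add n_t/R to the precision.
# Used to validate the smoother itself on tiny instances.
joint_gaussian_oracle <- function(n_t, s_t, Q, R, m0, C0) {
  T <- length(n_t)
  S <- outer(seq_len(T), seq_len(T), function(s, t) C0 + Q * (pmin(s, t) - 1))
  prior_prec <- solve(S)
  prec <- prior_prec + diag(n_t / R, T)
  b <- prior_prec %*% rep(m0, T) + s_t / R
  V <- solve(prec)
  list(mean = as.numeric(V %*% b), var = diag(V))
}

# Exhaustive search over contiguous 2-partitions minimising total
# within-zone dispersion sum(d^2)/size, the criterion used by the
# constrained clustering.
brute_force_two_zones <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  disp <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
  }
  costs <- vapply(seq_len(n - 1), function(b)
    disp(seq_len(b)) + disp(seq.int(b + 1, n)), numeric(1))
  which.min(costs)  # last index of the first zone
}

# Reference synthetic series: 45-year latent walk (Q = 0.04) observed
# with 5 replicates/year at R = 0.25 and 40% of years missing.
make_reference_series <- function(seed = 20240101) {
  set.seed(seed)
  years <- 1961:2005
  x <- simulate_latent_walk(45, Q = 0.04, x1 = 3, years = years)
  missing <- sample(years, round(0.4 * 45))
  obs_years <- setdiff(years, missing)
  yrs <- rep(obs_years, each = 5)
  vals <- x[as.character(yrs)] + rnorm(length(yrs), 0, sqrt(0.25))
  list(series = annual_series(yrs, vals, name = "reference",
                              year_range = range(years)),
       truth = x, Q = 0.04, R = 0.25)
}

# Per-year sufficient statistics of an annual_series on its full grid.
series_stats <- function(series) {
  rng <- attr(series, "year_range")
  grid <- seq.int(rng[1], rng[2])
  idx <- match(series$year, grid)
  n_t <- tabulate(idx, nbins = length(grid))
  s_t <- numeric(length(grid))
  agg <- rowsum(series$value, idx)
  s_t[as.integer(rownames(agg))] <- agg[, 1]
  list(grid = grid, n_t = n_t, s_t = s_t)
}
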