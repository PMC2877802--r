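# Independent oracles used across the suite. These deliberately take
# the dumbest correct route (explicit loops, closed forms, classical
# sums of squares) so they share no code path with the package.

# Small triangular kernel on [0, 1) s for cheap exact tests.
tri_kernel <- function(dt = 0.1) {
  lags <- seq(0, 1 - dt, by = dt)
  vals <- ifelse(lags <= 0.5, lags / 0.5, (1 - lags) / 0.5)
  response_function(vals, c(0, 1), dt, peak_lag = 0.5)
}

# Brute-force superposition: evaluate sum_i a_i RF(t - T_i) pointwise
# with an explicit double loop (events snapped to the grid as the
# forward model documents).
bruteforce_conv <- function(events, rf, duration, dt, baseline = 0) {
  n <- round(duration / dt)
  tgrid <- (seq_len(n) - 1) * dt
  lags <- rf$window[1] + (seq_along(rf$values) - 1) * dt
  out <- rep(baseline, n)
  for (i in seq_along(events$times)) {
    ti <- round(events$times[i] / dt) * dt
    for (j in seq_len(n)) {
      kidx <- round((tgrid[j] - ti - rf$window[1]) / dt) + 1
      if (kidx >= 1 && kidx <= length(rf$values))
        out[j] <- out[j] + events$amplitudes[i] * rf$values[kidx]
    }
  }
  out
}

# Classical sums-of-squares partition of the fully within-subject
# 2 x 2 ANOVA; returns F for treatment, method, interaction.
anova_ss_oracle <- function(arr) {
  ns <- dim(arr)[1]
  gm <- mean(arr)
  m_s <- apply(arr, 1, mean)
  m_t <- apply(arr, 2, mean)
  m_m <- apply(arr, 3, mean)
  m_st <- apply(arr, c(1, 2), mean)
  m_sm <- apply(arr, c(1, 3), mean)
  m_tm <- apply(arr, c(2, 3), mean)
  ss_t <- 2 * ns * sum((m_t - gm)^2)
  ss_m <- 2 * ns * sum((m_m - gm)^2)
  ss_tm <- ns * sum((m_tm - outer(m_t, rep(1, 2)) -
                       outer(rep(1, 2), m_m) + gm)^2)
  err_t <- 2 * sum((m_st - outer(m_s, rep(1, 2)) -
                      outer(rep(1, ns), m_t) + gm)^2)
  err_m <- 2 * sum((m_sm - outer(m_s, rep(1, 2)) -
                      outer(rep(1, ns), m_m) + gm)^2)
  err_tm <- 0
  for (s in seq_len(ns)) for (t in 1:2) for (m in 1:2)
    err_tm <- err_tm + (arr[s, t, m] - m_st[s, t] - m_sm[s, m] -
                          m_tm[t, m] + m_s[s] + m_t[t] + m_m[m] - gm)^2
  c(treatment = ss_t / (err_t / (ns - 1)),
    method = ss_m / (err_m / (ns - 1)),
    interaction = ss_tm / (err_tm / (ns - 1)))
}

# Numeric Fourier-series coefficient of a centred rectangular pulse
# train (height 1, duration d, period 1/n), harmonic i, by direct
# quadrature of one period at step dt.
rect_fourier_numeric <- function(i, n, d, dt = 1e-4) {
  period <- 1 / n
  t <- seq(-period / 2, period / 2 - dt, by = dt)
  f <- as.numeric(abs(t) <= d / 2)
  Re(sum(f * exp(-2i * pi * i * t / period)) * dt / period)
}

# A quiet simulated epoch with well-separated, comfortably
# suprathreshold events: the easy detection regime.
easy_epoch <- function(onsets = c(5, 15, 25, 35, 45),
                       amps = c(0.3, 0.5, 0.2, 0.4, 0.35),
                       noise_sd = 0, seed = 1, dt = 0.1) {
  k <- default_kernel(dt)
  tr <- event_train(onsets, amps, anchor = "onset")
  rec <- convolve_events(tr, k, 60, dt, baseline = 2)
  if (noise_sd > 0) {
    set.seed(seed)
    rec$samples <- rec$samples + rnorm(length(rec$samples), 0, noise_sd)
  }
  list(record = rec, truth = tr, kernel = k)
}
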