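#' Frequency-domain view of the convolution model
#'
#' In the frequency domain the LTI model reads
#' \deqn{FT(SC - SCL) = FT(SN) \cdot FT(RF):}
#' the spectrum of the level-corrected conductance is the product of
#' the burst-train and response-function spectra. This module exposes
#' the one-sided power spectrum, a numeric check of the discrete
#' convolution theorem, the closed-form Fourier coefficients of a
#' rectangular burst train together with their burst-rate sensitivity,
#' and the naive inverse-filter deconvolution whose fragility under
#' noise motivates the time-domain AUC measure.
#'
#' DFT convention: forward transform unscaled, inverse scaled by 1/N,
#' so Parseval's identity reads `sum(|X_k|^2) = N * sum(x_t^2)`.
#'
#' @name spectral_analysis
NULL

#' One-sided power spectrum of a level-corrected epoch
#'
#' The DFT of `samples - min(samples)`; conjugate bins are folded so
#' that `sum(power)` equals the time-domain sum of squared deviations
#' from the minimum (Parseval under the stated normalisation).
#'
#' @param record An `sc_record`.
#' @return A list of class `spectrum_result` with `frequencies` (Hz,
#'   ascending from 0 to Nyquist), `power` ((uS)^2 per bin) and
#'   `total_power` ((uS)^2).
#' @export
power_spectrum <- function(record) {
  stopifnot(inherits(record, "sc_record"))
  x <- record$samples - min(record$samples)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  p_full <- Mod(X)^2 / n
  power <- p_full[1:(half + 1)]
  if (n %% 2 == 0) {
    if (half >= 2) power[2:half] <- 2 * power[2:half]
  } else {
    power[2:(half + 1)] <- 2 * power[2:(half + 1)]
  }
  freqs <- (0:half) / (n * record$sample_interval)
  structure(list(frequencies = freqs, power = power,
                 total_power = sum(power)),
            class = "spectrum_result")
}

# Place a kernel on a circular grid of length n (negative lags wrap).
rf_on_grid <- function(rf, n, sample_interval) {
  if (abs(rf$sample_interval - sample_interval) > 1e-9 * sample_interval)
    stop("kernel and grid sampling intervals differ")
  if (length(rf$values) > n) stop("kernel window is longer than the grid")
  g <- numeric(n)
  lag0 <- as.integer(round(rf$window[1] / sample_interval))
  idx <- ((lag0 + seq_along(rf$values) - 1L) %% n) + 1L
  g[idx] <- g[idx] + rf$values
  g
}

# Sample an event train as impulse weights on a grid of length n.
train_on_grid <- function(events, n, sample_interval) {
  s <- numeric(n)
  for (i in seq_along(events$times)) {
    k <- snap_index(events$times[i], sample_interval)
    if (k < 1L || k > n) stop("event outside grid")
    s[k] <- s[k] + events$amplitudes[i]
  }
  s
}

#' Numeric check of the discrete convolution theorem
#'
#' Convolves an event train with a kernel circularly in the time
#' domain (direct summation, no FFT) and compares the DFT of the
#' result with the product of the DFTs of train and kernel. Returns
#' the maximum discrepancy relative to the largest product magnitude
#' (0 when both sides vanish).
#'
#' @param events An `event_train`.
#' @param rf A `response_function`.
#' @param duration Grid duration (s).
#' @param sample_interval Grid sampling interval (s).
#' @return Maximum relative discrepancy (dimensionless).
#' @export
verify_convolution_theorem <- function(events, rf, duration,
                                       sample_interval) {
  n <- as.integer(round(duration / sample_interval))
  s <- train_on_grid(events, n, sample_interval)
  g <- rf_on_grid(rf, n, sample_interval)
  conv <- numeric(n)
  for (t in seq_len(n)) {
    # circular time-domain sum: conv[t] = sum_tau s[tau] g[t - tau]
    shift <- ((t - seq_len(n)) %% n) + 1L
    conv[t] <- sum(s * g[shift])
  }
  lhs <- stats::fft(conv)
  rhs <- stats::fft(s) * stats::fft(g)
  scale <- max(Mod(rhs))
  if (scale == 0) return(max(Mod(lhs)))
  max(Mod(lhs - rhs)) / scale
}

#' Fourier coefficients of a rectangular burst train
#'
#' For sudomotor bursts modelled as rectangular pulses of duration `d`
#' seconds recurring at rate `n` Hz (duty cycle `n * d`), the i-th
#' Fourier coefficient is `sin(i * pi * n * d) / (i * pi)` and its
#' derivative with respect to the burst rate is
#' `d * cos(i * pi * n * d)`. The derivative shrinks with the harmonic
#' index `i` while `n * d < 1`, which is why burst-rate changes load
#' on the low end of the spectrum.
#'
#' @param i Harmonic index, integer `>= 1` (vectorised).
#' @param n Burst rate in Hz, `> 0`.
#' @param d Burst duration in seconds, `> 0`.
#' @return A list with `coefficient` and `d_coefficient_dn` (the
#'   burst-rate sensitivity), each the length of `i`.
#' @export
rect_train_fourier <- function(i, n, d) {
  if (any(i < 1) || any(i != round(i)))
    stop("harmonic index i must be a positive integer")
  if (n <= 0 || d <= 0) stop("burst rate n and duration d must be > 0")
  if (n * d >= 1)
    warning("duty cycle n * d >= 1: pulses overlap, outside the ",
            "regime the coefficients describe")
  list(coefficient = sin(i * pi * n * d) / (i * pi),
       d_coefficient_dn = d * cos(i * pi * n * d))
}

#' Naive inverse-filter deconvolution
#'
#' Recovers the sudomotor drive by spectral division,
#' \deqn{SN = FT^{-1}\{FT(SC - SCL) / FT(RF)\},}
#' with the kernel spectrum's magnitude floored at
#' `epsilon * max(|FT(RF)|)` to avoid division blow-up. The floor is a
#' machine-precision guard only: this estimator is exact for noiseless
#' circular convolutions but degrades rapidly with measurement noise,
#' which is precisely why the time-domain AUC measure is preferred for
#' real recordings.
#'
#' @param record An `sc_record`.
#' @param rf A `response_function` on the same sampling interval.
#' @param epsilon Relative spectral floor, default `1e-8`.
#' @return Numeric vector: the recovered drive sampled on the
#'   record's grid (impulse weights, uS).
#' @export
naive_deconvolve <- function(record, rf, epsilon = 1e-8) {
  stopifnot(inherits(record, "sc_record"),
            inherits(rf, "response_function"))
  n <- length(record$samples)
  g <- rf_on_grid(rf, n, record$sample_interval)
  G <- stats::fft(g)
  gmax <- max(Mod(G))
  if (gmax == 0) stop("all-zero response function cannot be inverted")
  floor_mag <- epsilon * gmax
  small <- Mod(G) < floor_mag
  G[small] <- floor_mag * exp(1i * Arg(G[small]))
  x <- record$samples - min(record$samples)
  Re(stats::fft(stats::fft(x) / G, inverse = TRUE)) / n
}
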