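#' Core data types for the LTI skin conductance model
#'
#' The package models a skin conductance (SC) epoch as
#' \deqn{SC(t) = SCL + SN(t) \otimes RF(t)}
#' where SCL is the tonic level, \eqn{SN(t) = \sum_i a_i \delta(t - T_i)}
#' is a train of weighted sudomotor bursts and RF is the stereotyped
#' response to a unit burst. Three S3 containers carry these objects:
#' `sc_record` (a sampled epoch), `event_train` (burst times and
#' amplitudes) and `response_function` (the sampled kernel on a lag
#' window).
#'
#' @name signal_model
NULL

#' Construct a skin conductance record
#'
#' A uniformly sampled skin conductance epoch with subject and
#' condition metadata.
#'
#' @param samples Numeric vector of conductance values in microsiemens.
#' @param sample_interval Seconds per sample (e.g. 0.1 for 10 Hz).
#' @param start_time Time of the first sample in seconds.
#' @param subject_id Subject label.
#' @param epoch_label Epoch label, e.g. `"BL1"`, `"BL2"`, `"R1"`, `"R2"`.
#' @param condition Either `"baseline"` or `"anticipation"` (or `NA`).
#' @param truncated Logical flag set by the forward model when a
#'   response extended past the grid and was cut off.
#'
#' @return An object of class `sc_record`.
#' @export
sc_record <- function(samples, sample_interval, start_time = 0,
                      subject_id = NA_character_, epoch_label = NA_character_,
                      condition = NA_character_, truncated = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("sc_record needs at least 2 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("sc_record samples must all be finite")
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0)
    stop("sample_interval must be a single positive number")
  if (!is.na(condition) && !condition %in% c("baseline", "anticipation"))
    stop("condition must be 'baseline', 'anticipation' or NA")
  structure(
    list(samples = samples,
         sample_interval = as.numeric(sample_interval),
         start_time = as.numeric(start_time),
         subject_id = as.character(subject_id),
         epoch_label = as.character(epoch_label),
         condition = as.character(condition),
         truncated = isTRUE(truncated)),
    class = "sc_record")
}

#' @export
print.sc_record <- function(x, ...) {
  cat(sprintf("<sc_record> %d samples @ %g Hz (%.1f s)",
              length(x$samples), 1 / x$sample_interval,
              length(x$samples) * x$sample_interval))
  if (!is.na(x$subject_id) || !is.na(x$epoch_label))
    cat(sprintf("  subject=%s epoch=%s condition=%s",
                x$subject_id, x$epoch_label, x$condition))
  cat(sprintf("\n  range [%.4g, %.4g] uS\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Epoch time axis
#'
#' Sample timestamps of a record (bin left edges, seconds).
#'
#' @param record An `sc_record`.
#' @return Numeric vector of times.
#' @export
sc_times <- function(record) {
  stopifnot(inherits(record, "sc_record"))
  record$start_time +
    (seq_along(record$samples) - 1) * record$sample_interval
}

#' Construct a sudomotor event train
#'
#' Burst times and amplitudes, the discrete-event representation
#' \eqn{SN(t) = \sum_i a_i \delta(t - T_i)} of sudomotor nerve
#' activity. `anchor` declares what the times mark: simulated events
#' are onset-anchored, detected fluctuations are peak-anchored.
#'
#' @param times Event times in seconds, non-decreasing.
#' @param amplitudes Event amplitudes in microsiemens, all `>= 0`.
#' @param anchor `"onset"` or `"peak"`.
#'
#' @return An object of class `event_train`.
#' @export
event_train <- function(times = numeric(), amplitudes = numeric(),
                        anchor = c("onset", "peak")) {
  anchor <- match.arg(anchor)
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  if (length(times) != length(amplitudes))
    stop("times and amplitudes must have equal length")
  if (length(times) && is.unsorted(times))
    stop("event times must be non-decreasing")
  if (any(amplitudes < 0))
    stop("event amplitudes must be >= 0")
  if (!all(is.finite(times)) || !all(is.finite(amplitudes)))
    stop("event times and amplitudes must be finite")
  structure(list(times = times, amplitudes = amplitudes, anchor = anchor),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events (%s-anchored)", length(x$times),
              x$anchor))
  if (length(x$times))
    cat(sprintf(", amplitudes [%.3g, %.3g] uS",
                min(x$amplitudes), max(x$amplitudes)))
  cat("\n")
  invisible(x)
}

#' @export
length.event_train <- function(x) length(x$times)

#' Construct a response function
#'
#' The sampled response kernel RF on a lag window
#' `[lag_min, lag_max)`. Sample `k` sits at lag
#' `lag_min + (k - 1) * sample_interval`. The kernel describes the
#' conductance response (microsiemens) to a unit-amplitude burst.
#'
#' @param values Kernel samples.
#' @param window Length-2 numeric, `c(lag_min, lag_max)` in seconds.
#' @param sample_interval Seconds per sample.
#' @param peak_lag Optional latency (s) of the kernel peak, metadata.
#'
#' @return An object of class `response_function`.
#' @export
response_function <- function(values, window, sample_interval,
                              peak_lag = NA_real_) {
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    stop("response_function values must be finite")
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be c(lag_min, lag_max) with lag_max > lag_min")
  n_expect <- round((window[2] - window[1]) / sample_interval)
  if (length(values) != n_expect)
    stop("expected ", n_expect, " kernel samples for window [",
         window[1], ", ", window[2], ") at dt = ", sample_interval,
         ", got ", length(values))
  structure(
    list(values = values, window = as.numeric(window),
         sample_interval = as.numeric(sample_interval),
         peak_lag = as.numeric(peak_lag)),
    class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf(
    "<response_function> window [%g, %g) s, dt = %g s, integral = %.4g s\n",
    x$window[1], x$window[2], x$sample_interval, rf_integral(x)))
  invisible(x)
}

#' Lag axis of a response function
#'
#' @param rf A `response_function`.
#' @return Numeric vector of lags (s), one per kernel sample.
#' @export
rf_lags <- function(rf) {
  stopifnot(inherits(rf, "response_function"))
  rf$window[1] + (seq_along(rf$values) - 1) * rf$sample_interval
}

#' Time-integral of a response function
#'
#' The constant \eqn{c = \int RF(t)\,dt}: under the LTI model the AUC
#' of an epoch equals `c` times the summed burst amplitudes. Computed
#' by the trapezoidal rule over the kernel's lag window, so `c`
#' carries units of seconds for a unit-peak kernel.
#'
#' @param rf A `response_function`.
#' @return The integral in seconds (kernel value units times s).
#' @export
rf_integral <- function(rf) {
  stopifnot(inherits(rf, "response_function"))
  if (length(rf$values) < 2L) return(0)
  pracma::trapz(rf_lags(rf), rf$values)
}

# Snap a time to the nearest grid index (1-based), grid origin at 0.
snap_index <- function(time_s, dt) as.integer(round(time_s / dt)) + 1L

#' Forward LTI convolution of an event train with a response function
#'
#' Evaluates \eqn{SC(t) = baseline + \sum_i a_i RF(t - T_i)} on a
#' uniform grid. Event times are snapped to the nearest grid point;
#' sub-sample latency is not modelled. In `"linear"` mode,
#' contributions extending past the grid are truncated (silently, but
#' flagged in the returned record's `truncated` field); `"circular"`
#' mode wraps them around, which makes the discrete convolution
#' theorem exact and is used for spectral identity checks.
#'
#' @param events An `event_train`. All event times must lie in
#'   `[0, duration)`.
#' @param rf A `response_function` on the same sampling interval.
#' @param duration Grid duration in seconds.
#' @param sample_interval Grid sampling interval in seconds; must equal
#'   the kernel's.
#' @param baseline Constant level added to the output (microsiemens).
#' @param mode `"linear"` (default) or `"circular"`.
#' @param ... Metadata passed on to [sc_record()].
#'
#' @return An `sc_record` of `round(duration / sample_interval)`
#'   samples.
#' @export
convolve_events <- function(events, rf, duration, sample_interval,
                            baseline = 0, mode = c("linear", "circular"),
                            ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(events, "event_train"),
            inherits(rf, "response_function"))
  if (abs(rf$sample_interval - sample_interval) >
      1e-9 * sample_interval)
    stop("sampling interval mismatch: grid dt = ", sample_interval,
         ", kernel dt = ", rf$sample_interval)
  n <- as.integer(round(duration / sample_interval))
  if (n < 2L) stop("grid must contain at least 2 samples")
  if (length(events) &&
      (any(events$times < 0) || any(events$times >= duration)))
    stop("event times must lie within [0, duration)")

  if (length(rf$values) > n)
    stop("kernel window is longer than the grid")
  out <- rep(baseline, n)
  lag0 <- as.integer(round(rf$window[1] / sample_interval))
  truncated <- FALSE
  for (i in seq_along(events$times)) {
    idx <- snap_index(events$times[i], sample_interval) + lag0 +
      seq_along(rf$values) - 1L
    contrib <- events$amplitudes[i] * rf$values
    if (mode == "circular") {
      idx <- ((idx - 1L) %% n) + 1L
      out[idx] <- out[idx] + contrib
    } else {
      keep <- idx >= 1L & idx <= n
      if (!all(keep | contrib == 0)) truncated <- TRUE
      out[idx[keep]] <- out[idx[keep]] + contrib[keep]
    }
  }
  sc_record(out, sample_interval, truncated = truncated, ...)
}
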