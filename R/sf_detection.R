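#' Detection settings for spontaneous fluctuations
#'
#' @param amplitude_threshold Minimum trough-to-peak amplitude in
#'   microsiemens for a fluctuation to be counted. Default 0.025 uS,
#'   the conventional scoring threshold.
#' @param min_rise Minimum trough-to-peak span in samples. Genuine
#'   fluctuations rise over several hundred milliseconds, so a small
#'   span requirement rejects single-sample spikes. Default 3.
#'
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(amplitude_threshold = 0.025, min_rise = 3L) {
  if (amplitude_threshold <= 0)
    stop("amplitude_threshold must be > 0")
  if (min_rise < 1L) stop("min_rise must be >= 1 sample")
  structure(list(amplitude_threshold = amplitude_threshold,
                 min_rise = as.integer(min_rise)),
            class = "detection_config")
}

#' Detect spontaneous fluctuations by trough-to-peak scoring
#'
#' A deterministic surrogate for semi-automatic fluctuation scoring:
#' peaks are found by a turning-point scan with hysteresis equal to
#' the amplitude threshold. Scanning forward, the detector tracks the
#' running minimum since the last confirmed peak; a peak candidate is
#' the running maximum since that trough, and is confirmed once the
#' signal has descended by at least the threshold below it. The
#' fluctuation amplitude is the confirmed peak value minus the
#' preceding trough value, and only fluctuations with amplitude at or
#' above the threshold and trough-to-peak span of at least `min_rise`
#' samples are retained. Plateaus resolve to their first sample; a
#' terminal rise with no confirmed descent is not counted. No
#' rise-time or decay-shape exclusion heuristics are applied.
#'
#' @param record An `sc_record`.
#' @param config A [detection_config()].
#' @return A peak-anchored `event_train` of peak times (s) and
#'   trough-to-peak amplitudes (uS), sorted by time. Empty on flat or
#'   monotone input.
#' @export
detect_sf <- function(record, config = detection_config()) {
  stopifnot(inherits(record, "sc_record"),
            inherits(config, "detection_config"))
  x <- record$samples
  h <- config$amplitude_threshold
  t0 <- record$start_time
  dt <- record$sample_interval

  peak_idx <- integer()
  peak_amp <- numeric()
  trough_val <- x[1]
  trough_idx <- 1L
  cand_val <- -Inf
  cand_idx <- 0L
  seeking_peak <- TRUE
  for (i in seq_along(x)) {
    if (seeking_peak) {
      if (x[i] > cand_val) { cand_val <- x[i]; cand_idx <- i }
      if (cand_val - x[i] >= h) {
        # descent confirmed: score the candidate against its trough
        amp <- cand_val - trough_val
        if (amp >= h && (cand_idx - trough_idx) >= config$min_rise) {
          peak_idx <- c(peak_idx, cand_idx)
          peak_amp <- c(peak_amp, amp)
        }
        seeking_peak <- FALSE
        trough_val <- x[i]; trough_idx <- i
      }
    } else {
      if (x[i] < trough_val) { trough_val <- x[i]; trough_idx <- i }
      if (x[i] - trough_val >= h) {
        seeking_peak <- TRUE
        cand_val <- x[i]; cand_idx <- i
      }
    }
  }
  event_train(times = t0 + (peak_idx - 1L) * dt, amplitudes = peak_amp,
              anchor = "peak")
}

#' Summarise an event train into n, mean amplitude and their product
#'
#' The conventional per-epoch arousal indices: the fluctuation count
#' `n`, the mean amplitude `abar` (0 for an empty train) and their
#' product `n_times_abar` which equals the summed amplitudes.
#'
#' @param events An `event_train`.
#' @return A list with `n`, `abar` (uS) and `n_times_abar` (uS).
#' @export
summarize_sf <- function(events) {
  stopifnot(inherits(events, "event_train"))
  n <- length(events)
  total <- sum(events$amplitudes)
  list(n = n, abar = if (n) total / n else 0, n_times_abar = total)
}
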