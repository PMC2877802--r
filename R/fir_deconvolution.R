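#' Finite impulse response deconvolution of overlapping fluctuations
#'
#' The "uninformed" FIR model places one free coefficient (a stick or
#' delta function) at every sampled lag of a window around each event,
#' and estimates all coefficients jointly by ordinary least squares.
#' At 10 Hz the default peak-anchored window of (-4, 8) s yields 120
#' lag coefficients. Fitting the model to events of assumed unit
#' amplitude recovers a shared response function; fixing the response
#' function and giving each event its own regressor recovers per-event
#' amplitudes. Both directions share the design-matrix builder
#' [build_fir_design()].
#'
#' @name fir_deconvolution
NULL

#' Build the FIR design matrix for a set of epochs
#'
#' Rows are the concatenated samples of all epochs; columns are one
#' per lag of the window (unit-amplitude event counts: entry (t, j) is
#' the number of events whose time plus lag j lands on sample t;
#' overlapping responses sum) followed by one intercept column per
#' epoch. Events never bleed across epoch boundaries; responses
#' extending beyond an epoch are truncated (zero-padded), and this is
#' reported via the `truncated` attribute.
#'
#' @param event_times List of numeric vectors, one per epoch: event
#'   times in seconds relative to the epoch start.
#' @param epoch_lengths Integer vector of samples per epoch.
#' @param window Lag window `c(lag_min, lag_max)` in seconds; must be
#'   a multiple of `sample_interval`.
#' @param sample_interval Seconds per sample.
#'
#' @return A dense numeric matrix with attributes `lags` (lag of each
#'   FIR column, s), `n_lags`, `epoch_of_row` and `truncated`.
#' @export
build_fir_design <- function(event_times, epoch_lengths, window = c(-4, 8),
                             sample_interval = 0.1) {
  if (length(event_times) != length(epoch_lengths))
    stop("event_times and epoch_lengths must have one entry per epoch")
  span <- (window[2] - window[1]) / sample_interval
  if (abs(span - round(span)) > 1e-8)
    stop("window span must be a whole number of samples")
  n_lags <- as.integer(round(span))
  lag_offsets <- as.integer(round(window[1] / sample_interval)) +
    seq_len(n_lags) - 1L
  n_epochs <- length(epoch_lengths)
  epoch_lengths <- as.integer(epoch_lengths)
  total <- sum(epoch_lengths)
  X <- matrix(0, nrow = total, ncol = n_lags + n_epochs)
  row0 <- c(0L, cumsum(epoch_lengths))
  truncated <- FALSE
  for (e in seq_len(n_epochs)) {
    ne <- epoch_lengths[e]
    for (tm in event_times[[e]]) {
      base <- snap_index(tm, sample_interval)
      if (base < 1L || base > ne)
        stop("event at ", tm, " s lies outside epoch ", e)
      idx <- base + lag_offsets
      keep <- idx >= 1L & idx <= ne
      if (!all(keep)) truncated <- TRUE
      rows <- row0[e] + idx[keep]
      cols <- which(keep)
      X[cbind(rows, cols)] <- X[cbind(rows, cols)] + 1
    }
    X[row0[e] + seq_len(ne), n_lags + e] <- 1
  }
  attr(X, "lags") <- window[1] + (seq_len(n_lags) - 1L) * sample_interval
  attr(X, "n_lags") <- n_lags
  attr(X, "epoch_of_row") <- rep(seq_len(n_epochs), epoch_lengths)
  attr(X, "truncated") <- truncated
  X
}

# QR solve with an explicit full-rank check; names the collinear
# columns on failure.
ols_qr <- function(X, y, what = "design") {
  qrx <- qr(X, LAPACK = FALSE)
  if (qrx$rank < ncol(X)) {
    bad <- qrx$pivot[(qrx$rank + 1L):ncol(X)]
    nm <- colnames(X)
    lab <- if (is.null(nm)) paste(bad, collapse = ", ")
           else paste(nm[bad], collapse = ", ")
    stop("rank-deficient ", what, ": collinear column(s) ", lab)
  }
  qr.coef(qrx, y)
}

# Fraction of variance explained with per-epoch centring; NA for a
# flat signal (nothing to explain).
r2_per_epoch <- function(y, fitted, epoch_of_row) {
  centre <- ave(y, epoch_of_row)
  ss_tot <- sum((y - centre)^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / ss_tot
}

#' Estimate a shared response function by least squares
#'
#' Fits the uninformed FIR model jointly over all epochs: a single
#' response function of assumed unit event amplitude, plus one
#' intercept per epoch to absorb the tonic level. The solver is an
#' ordinary least-squares QR decomposition with no regularisation.
#'
#' @param records List of `sc_record` epochs.
#' @param events List of `event_train` objects, one per epoch (the
#'   anchor of the events defines the anchor of the estimated kernel).
#' @param window Lag window in seconds, default `c(-4, 8)`.
#'
#' @return A list of class `fir_fit` with `rf` (the estimated
#'   `response_function`), `intercepts` (per epoch, uS), `r2`
#'   (variance explained with per-epoch centring), `residual_ss`,
#'   `truncated` (whether any response window was cut by an epoch
#'   edge) and `n_events`.
#' @export
estimate_rf <- function(records, events, window = c(-4, 8)) {
  stopifnot(length(records) == length(events), length(records) >= 1L)
  dt <- records[[1]]$sample_interval
  if (sum(vapply(events, length, 1L)) < 1L)
    stop("at least one event is required to estimate a response function")
  X <- build_fir_design(lapply(events, `[[`, "times"),
                        vapply(records, function(r) length(r$samples), 1L),
                        window = window, sample_interval = dt)
  n_lags <- attr(X, "n_lags")
  colnames(X) <- c(sprintf("lag_%.3fs", attr(X, "lags")),
                   sprintf("intercept_epoch%d", seq_along(records)))
  y <- unlist(lapply(records, `[[`, "samples"), use.names = FALSE)
  beta <- ols_qr(X, y, "FIR design")
  fitted <- drop(X %*% beta)
  r2 <- r2_per_epoch(y, fitted, attr(X, "epoch_of_row"))
  anchor <- events[[which(vapply(events, length, 1L) > 0)[1]]]$anchor
  rf <- response_function(beta[seq_len(n_lags)], window, dt)
  rf$anchor <- anchor
  structure(
    list(rf = rf,
         intercepts = unname(beta[(n_lags + 1L):length(beta)]),
         amplitudes = NULL, r2 = r2,
         residual_ss = sum((y - fitted)^2),
         truncated = attr(X, "truncated"),
         n_events = sum(vapply(events, length, 1L))),
    class = "fir_fit")
}

#' Estimate per-event amplitudes under a fixed response function
#'
#' With the response function held fixed, each event receives one
#' regressor (the kernel shifted to the event's anchor time, truncated
#' at epoch edges) plus a single intercept; amplitudes are the
#' ordinary least-squares coefficients.
#'
#' @param record An `sc_record`.
#' @param events An `event_train` within the epoch.
#' @param rf A `response_function` on the same sampling interval.
#'
#' @return A list of class `fir_fit` with `amplitudes` (uS, one per
#'   event), `intercepts` (length 1), `r2`, `residual_ss` and
#'   `truncated`.
#' @export
estimate_amplitudes <- function(record, events, rf) {
  stopifnot(inherits(record, "sc_record"), inherits(events, "event_train"),
            inherits(rf, "response_function"))
  dt <- record$sample_interval
  if (abs(rf$sample_interval - dt) > 1e-9 * dt)
    stop("kernel and record sampling intervals differ")
  n <- length(record$samples)
  k <- length(events)
  if (k < 1L) stop("no events to estimate amplitudes for")
  lag0 <- as.integer(round(rf$window[1] / dt))
  X <- matrix(0, nrow = n, ncol = k + 1L)
  truncated <- FALSE
  for (i in seq_len(k)) {
    idx <- snap_index(events$times[i], dt) + lag0 + seq_along(rf$values) - 1L
    keep <- idx >= 1L & idx <= n
    if (!all(keep | rf$values == 0)) truncated <- TRUE
    X[idx[keep], i] <- rf$values[keep]
  }
  X[, k + 1L] <- 1
  colnames(X) <- c(sprintf("event_%.3fs", events$times), "intercept")
  beta <- ols_qr(X, record$samples, "amplitude design")
  fitted <- drop(X %*% beta)
  r2 <- r2_per_epoch(record$samples, fitted, rep(1L, n))
  structure(
    list(rf = rf, intercepts = beta[k + 1L],
         amplitudes = unname(beta[seq_len(k)]), r2 = r2,
         residual_ss = sum((record$samples - fitted)^2),
         truncated = truncated, n_events = k),
    class = "fir_fit")
}

#' @export
print.fir_fit <- function(x, ...) {
  cat(sprintf("<fir_fit> %d events, r2 = %.4f%s\n", x$n_events, x$r2,
              if (isTRUE(x$truncated)) " (edge-truncated windows)" else ""))
  invisible(x)
}

#' Fraction of variance explained
#'
#' `1 - sum((obs - fit)^2) / sum((obs - centre)^2)`. The centre is
#' typically the per-epoch mean of the observations, so the statistic
#' measures how much of the within-epoch variance the fit accounts
#' for.
#'
#' @param observed,fitted,center Equal-length numeric vectors.
#' @return The r-squared fraction.
#' @export
variance_explained <- function(observed, fitted, center) {
  if (length(observed) != length(fitted) ||
      length(observed) != length(center))
    stop("observed, fitted and center must have equal lengths")
  ss_tot <- sum((observed - center)^2)
  if (ss_tot == 0) stop("zero total variance: r2 undefined")
  1 - sum((observed - fitted)^2) / ss_tot
}
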