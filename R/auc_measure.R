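#' SCL-corrected time-integral (AUC) of a skin conductance epoch
#'
#' The headline arousal statistic: the trapezoidal time-integral of
#' the epoch after subtracting the skin conductance level (SCL),
#' operationalised as the epoch minimum. Under the LTI model
#' \deqn{AUC = \int SC(t)\,dt - SCL = c\,n\,\bar a + e}
#' where `n` is the number of sudomotor bursts, \eqn{\bar a} their
#' mean amplitude, `c` the time-integral of the response function and
#' `e` an error absorbing noise and model violations. No detrending
#' or filtering is applied before integration.
#'
#' @param record An `sc_record`.
#'
#' @return A list of class `auc_result` with fields `auc` (uS.s),
#'   `scl` (uS, the subtracted minimum), `duration` (s) and the
#'   record's `subject_id`, `epoch_label` and `condition`.
#' @export
compute_auc <- function(record) {
  stopifnot(inherits(record, "sc_record"))
  if (length(record$samples) < 2L)
    stop("epoch must contain at least 2 samples")
  scl <- min(record$samples)
  auc <- pracma::trapz(sc_times(record), record$samples - scl)
  structure(
    list(auc = auc, scl = scl,
         duration = length(record$samples) * record$sample_interval,
         subject_id = record$subject_id,
         epoch_label = record$epoch_label,
         condition = record$condition),
    class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC = %.4g uS.s over %g s (SCL = %.4g uS)\n",
              x$auc, x$duration, x$scl))
  invisible(x)
}

#' AUC for a collection of epochs
#'
#' Applies [compute_auc()] to each record, preserving input order and
#' metadata. Errors in individual records are re-raised with the
#' record's position and label.
#'
#' @param records A list of `sc_record` objects.
#' @return A data frame with one row per record: `subject`, `epoch`,
#'   `condition`, `auc`, `scl`, `duration`.
#' @export
auc_batch <- function(records) {
  rows <- lapply(seq_along(records), function(i) {
    r <- tryCatch(compute_auc(records[[i]]), error = function(e)
      stop("record ", i, " (", records[[i]]$subject_id, "/",
           records[[i]]$epoch_label, "): ", conditionMessage(e),
           call. = FALSE))
    data.frame(subject = r$subject_id, epoch = r$epoch_label,
               condition = r$condition, auc = r$auc, scl = r$scl,
               duration = r$duration, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(subject = character(), epoch = character(),
                      condition = character(), auc = numeric(),
                      scl = numeric(), duration = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
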