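#' Validation battery for the AUC arousal measure
#'
#' The statistics used to judge whether the SCL-corrected AUC behaves
#' as the LTI model predicts: (i) simple regression of per-epoch AUC
#' on the conventional n x abar index, whose slope should equal the
#' response-function integral c and whose intercept should be a small
#' positive noise offset; (ii) a 2 (treatment) x 2 (method)
#' within-subject ANOVA contrasting AUC with the rescaled
#' conventional index c * n * abar; (iii) point-biserial
#' classification of epochs into baseline vs anticipation from each
#' measure; and (iv) an F test on the difference of explained
#' variances between the two classifiers.
#'
#' @name validation_stats
NULL

#' Regress AUC on the conventional n x abar index
#'
#' Ordinary least-squares simple regression with intercept. Under the
#' LTI model the slope estimates the response-function integral c (in
#' seconds) and the intercept the noise-induced AUC offset.
#'
#' @param auc Per-epoch AUC values (uS.s).
#' @param na Per-epoch n x abar values (uS).
#' @return A list with `slope` (s), `intercept` (uS.s) and `r2`.
#' @export
regress_auc_on_na <- function(auc, na) {
  if (length(auc) != length(na)) stop("auc and na lengths differ")
  if (length(auc) < 3) stop("need at least 3 epochs")
  if (stats::var(na) == 0) stop("constant predictor: slope undefined")
  fit <- stats::lm(auc ~ na)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((auc - mean(auc))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot)
}

#' Rescale the conventional index to AUC units
#'
#' Multiplies n x abar (uS) by the response-function integral c (s)
#' so the conventional measure and the AUC share units (uS.s) and
#' scale, making the two methods directly comparable in the ANOVA.
#'
#' @param na n x abar values (uS).
#' @param c_constant The constant c in seconds, `> 0`.
#' @return `c_constant * na` (uS.s).
#' @export
scale_conventional <- function(na, c_constant) {
  if (c_constant <= 0) stop("c must be > 0")
  c_constant * na
}

#' Two-by-two repeated-measures ANOVA
#'
#' Fully within-subject 2 x 2 ANOVA computed from per-subject
#' difference scores: each effect's F is the squared one-sample t
#' statistic of the corresponding per-subject contrast (treatment
#' difference averaged over methods, method difference averaged over
#' treatments, and the double difference for the interaction). This
#' is algebraically identical to the classical partition with error
#' terms subject x treatment, subject x method and
#' subject x treatment x method; each F has (1, n_subjects - 1)
#' degrees of freedom.
#'
#' @param values Numeric array `n_subjects x 2 x 2` (subject,
#'   treatment, method) or a data frame with columns `subject`,
#'   `treatment`, `method`, `value` forming a complete balanced
#'   design.
#' @return A data frame with rows `treatment`, `method`,
#'   `interaction` and columns `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(values) {
  if (is.data.frame(values)) values <- .cells_from_long(values)
  if (!(is.array(values) && length(dim(values)) == 3 &&
        all(dim(values)[2:3] == 2)))
    stop("values must be an n x 2 x 2 array or an equivalent long ",
         "data frame")
  if (any(!is.finite(values))) stop("missing or non-finite cells")
  ns <- dim(values)[1]
  if (ns < 2) stop("need at least 2 subjects")
  contrast_f <- function(d) {
    # F = t^2 for the one-sample t on the per-subject contrast; a
    # contrast that vanishes identically has zero effect SS, F = 0
    v <- stats::var(d)
    f <- if (v == 0) {
      if (mean(d) == 0) 0 else Inf
    } else ns * mean(d)^2 / v
    c(F = f, p = stats::pf(f, 1, ns - 1, lower.tail = FALSE))
  }
  # paired differences first, so identical cells cancel exactly
  d_treat <- ((values[, 2, 1] - values[, 1, 1]) +
              (values[, 2, 2] - values[, 1, 2])) / 2
  d_meth  <- ((values[, 1, 2] - values[, 1, 1]) +
              (values[, 2, 2] - values[, 2, 1])) / 2
  d_int   <- ((values[, 2, 2] - values[, 1, 2]) -
              (values[, 2, 1] - values[, 1, 1])) / 2
  res <- rbind(contrast_f(d_treat), contrast_f(d_meth),
               contrast_f(d_int))
  data.frame(effect = c("treatment", "method", "interaction"),
             F = res[, "F"], df1 = 1L, df2 = ns - 1L, p = res[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.cells_from_long <- function(df) {
  need <- c("subject", "treatment", "method", "value")
  if (!all(need %in% names(df)))
    stop("long data frame needs columns ", paste(need, collapse = ", "))
  subj <- sort(unique(df$subject))
  tr <- sort(unique(df$treatment))
  me <- sort(unique(df$method))
  if (length(tr) != 2 || length(me) != 2)
    stop("treatment and method must each have exactly 2 levels")
  arr <- array(NA_real_, dim = c(length(subj), 2, 2),
               dimnames = list(subj, tr, me))
  for (r in seq_len(nrow(df)))
    arr[as.character(df$subject[r]), as.character(df$treatment[r]),
        as.character(df$method[r])] <- df$value[r]
  if (any(is.na(arr))) stop("incomplete design: missing cells")
  arr
}

#' Point-biserial correlation
#'
#' Pearson correlation between a continuous predictor and a binary
#' class label coded 0/1; measures how well the predictor separates
#' the classes.
#'
#' @param predictor Numeric vector.
#' @param labels Logical, 0/1 numeric, or two-level factor/character.
#' @return The correlation coefficient.
#' @export
pointbiserial <- function(predictor, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(factor(labels)) - 1L
  labels <- as.numeric(labels)
  if (length(predictor) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) != 2)
    stop("both classes must be present")
  stats::cor(predictor, labels)
}

#' F test comparing two predictors' explained variance
#'
#' For two correlations with the same binary outcome,
#' \deqn{F = \frac{r_b^2 - r_w^2}{(1 - r_b^2) / df},}
#' with degrees of freedom (1, `df_den`): the gain in explained
#' variance of the better predictor against its residual variance. A
#' negative F (when the supposedly better predictor is worse) is
#' returned as computed and flagged.
#'
#' @param r_better,r_worse Correlations of the two predictors with
#'   the outcome.
#' @param df_den Denominator degrees of freedom, `>= 1`.
#' @return A list with `F`, `df1`, `df2`, `p` and `flag` (`"ok"`,
#'   `"negative"` or `"degenerate"`).
#' @export
compare_explained_variance <- function(r_better, r_worse, df_den) {
  if (df_den < 1) stop("df_den must be >= 1")
  if (abs(r_better) >= 1)
    return(list(F = Inf, df1 = 1L, df2 = as.integer(df_den), p = 0,
                flag = "degenerate"))
  f <- (r_better^2 - r_worse^2) / ((1 - r_better^2) / df_den)
  list(F = f, df1 = 1L, df2 = as.integer(df_den),
       p = stats::pf(f, 1, df_den, lower.tail = FALSE),
       flag = if (f < 0) "negative" else "ok")
}

#' Run the full validation battery on a study
#'
#' End-to-end composition: per-epoch AUC; fluctuation detection and
#' the conventional n x abar index; a shared response function
#' estimated from the detected peaks by FIR deconvolution (normalised
#' to unit peak so per-event amplitudes stay in uS, commensurate with
#' trough-to-peak scoring) unless a kernel is supplied; per-peak
#' amplitude estimation under that kernel to measure overall variance
#' explained; the AUC-vs-n x abar regression; the 2 x 2 ANOVA on
#' per-subject condition means of AUC and c * n * abar, plus
#' simple-effect treatment F values within each method; and the
#' point-biserial classification comparison with its explained-
#' variance F test.
#'
#' @param study A `sim_study`, or a list of `sc_record` epochs each
#'   carrying subject/epoch/condition metadata.
#' @param rf Optional fixed `response_function`; if `NULL` the
#'   response function is estimated from the data.
#' @param detection A [detection_config()].
#' @param fir_window Lag window (s) for response-function estimation.
#' @return A list of class `validation_report`; see fields in the
#'   returned object, including `epochs` (the per-epoch table) and
#'   `anova`.
#' @export
run_validation <- function(study, rf = NULL,
                           detection = detection_config(),
                           fir_window = c(-4, 8)) {
  records <- if (inherits(study, "sim_study"))
    lapply(study$epochs, `[[`, "record") else study
  if (!length(records)) stop("no epochs supplied")
  conds <- vapply(records, `[[`, "", "condition")
  if (!all(c("baseline", "anticipation") %in% conds))
    stop("study must contain both baseline and anticipation epochs")

  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop("validation stage '", what, "': ", conditionMessage(e),
         call. = FALSE))

  auc_tab <- stage("auc", auc_batch(records))
  events <- stage("detection", lapply(records, detect_sf, config = detection))
  summ <- lapply(events, summarize_sf)
  auc_tab$n <- vapply(summ, `[[`, 0, "n")
  auc_tab$abar <- vapply(summ, `[[`, 0, "abar")
  auc_tab$na <- vapply(summ, `[[`, 0, "n_times_abar")

  if (is.null(rf)) {
    fit <- stage("fir", estimate_rf(records, events, window = fir_window))
    rf_est <- fit$rf
    pk <- max(rf_est$values)
    if (pk <= 0) stop("estimated response function has no positive peak")
    rf_use <- response_function(rf_est$values / pk, rf_est$window,
                                rf_est$sample_interval,
                                peak_lag = rf_lags(rf_est)[
                                  which.max(rf_est$values)])
    fir_r2 <- fit$r2
  } else {
    rf_use <- rf
    fir_r2 <- NA_real_
  }
  c_constant <- rf_integral(rf_use)

  # per-peak amplitude refit under the shared kernel, pooled r2
  amp_fit <- stage("amplitudes", {
    obs <- c(); fitv <- c(); ctr <- c()
    for (i in seq_along(records)) {
      if (length(events[[i]]) == 0) next
      f <- estimate_amplitudes(records[[i]], events[[i]], rf_use)
      obs <- c(obs, records[[i]]$samples)
      fitv <- c(fitv, .fitted_from(records[[i]], events[[i]], rf_use, f))
      ctr <- c(ctr, rep(mean(records[[i]]$samples),
                        length(records[[i]]$samples)))
    }
    if (length(obs)) variance_explained(obs, fitv, ctr) else NA_real_
  })

  reg <- stage("regression", regress_auc_on_na(auc_tab$auc, auc_tab$na))
  auc_tab$na_scaled <- scale_conventional(auc_tab$na, c_constant)

  # per-subject condition means -> n x 2 x 2 (treatment x method)
  cells <- stage("anova", {
    subj <- sort(unique(auc_tab$subject))
    arr <- array(NA_real_, dim = c(length(subj), 2, 2),
                 dimnames = list(subj, c("baseline", "anticipation"),
                                 c("conventional", "auc")))
    for (s in seq_along(subj)) for (cond in dimnames(arr)[[2]]) {
      sel <- auc_tab$subject == subj[s] & auc_tab$condition == cond
      arr[s, cond, "conventional"] <- mean(auc_tab$na_scaled[sel])
      arr[s, cond, "auc"] <- mean(auc_tab$auc[sel])
    }
    arr
  })
  anova_tab <- rm_anova_2x2(cells)
  simple_f <- function(m) {
    d <- cells[, 2, m] - cells[, 1, m]
    f <- dim(cells)[1] * mean(d)^2 / stats::var(d)
    list(F = f, df1 = 1L, df2 = dim(cells)[1] - 1L,
         p = stats::pf(f, 1, dim(cells)[1] - 1, lower.tail = FALSE))
  }

  labels <- as.integer(auc_tab$condition == "anticipation")
  r_auc <- pointbiserial(auc_tab$auc, labels)
  r_conv <- pointbiserial(auc_tab$na_scaled, labels)
  better <- max(abs(r_auc), abs(r_conv))
  worse <- min(abs(r_auc), abs(r_conv))
  dr2 <- compare_explained_variance(better, worse,
                                    df_den = nrow(auc_tab) - 1L)

  structure(
    list(slope = reg$slope, intercept = reg$intercept,
         r2_auc_vs_na = reg$r2,
         c_constant = c_constant, fir_r2 = fir_r2,
         amplitude_model_r2 = amp_fit,
         rf = rf_use,
         anova = anova_tab,
         treatment_F_auc = simple_f("auc"),
         treatment_F_conventional = simple_f("conventional"),
         r_classification_auc = r_auc,
         r_classification_conventional = r_conv,
         delta_r2_F = dr2,
         epochs = auc_tab),
    class = "validation_report")
}

# Fitted values of the per-event amplitude model for one record.
.fitted_from <- function(record, events, rf, fit) {
  dt <- record$sample_interval
  n <- length(record$samples)
  lag0 <- as.integer(round(rf$window[1] / dt))
  yhat <- rep(fit$intercepts[1], n)
  for (i in seq_along(events$times)) {
    idx <- snap_index(events$times[i], dt) + lag0 + seq_along(rf$values) - 1L
    keep <- idx >= 1L & idx <= n
    yhat[idx[keep]] <- yhat[idx[keep]] + fit$amplitudes[i] * rf$values[keep]
  }
  yhat
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  slope = %.3f s (c = %.3f s), intercept = %.3f uS.s, r2 = %.3f\n",
              x$slope, x$c_constant, x$intercept, x$r2_auc_vs_na))
  if (!is.na(x$fir_r2))
    cat(sprintf("  FIR variance explained = %.1f%%, amplitude model = %.1f%%\n",
                100 * x$fir_r2, 100 * x$amplitude_model_r2))
  cat(sprintf("  treatment F: auc %.2f, conventional %.2f; interaction %.2f\n",
              x$treatment_F_auc$F, x$treatment_F_conventional$F,
              x$anova$F[x$anova$effect == "interaction"]))
  cat(sprintf("  classification r: auc %.3f vs conventional %.3f (dR2 F = %.2f, p = %.3g)\n",
              x$r_classification_auc, x$r_classification_conventional,
              x$delta_r2_F$F, x$delta_r2_F$p))
  invisible(x)
}
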