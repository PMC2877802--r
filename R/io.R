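#' Delimited-text interchange formats
#'
#' All on-disk formats are plain delimited text (comma or tab,
#' detected from the first non-comment line) with optional `# key: value`
#' comment headers for metadata. Time series use either a two-column
#' `time,value` dialect (time in seconds, bin left edges starting at
#' 0) or a one-column `value` dialect whose sampling interval comes
#' from a `# sample_interval: <s>` header. Values are conductances in
#' microsiemens. Numbers are written with `%.6g`, so writing a
#' re-read file reproduces it byte for byte. Readers reject rather
#' than guess: ragged rows, non-numeric cells and non-uniform time
#' spacing are specific errors with line numbers.
#'
#' @name io_formats
NULL

fmt_num <- function(x) sprintf("%.6g", x)

.read_delim_body <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  header <- list()
  for (ln in lines[grepl("^\\s*#", lines)]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) header[[trimws(m[2])]] <- trimws(m[3])
  }
  body_idx <- which(!is_comment)
  if (!length(body_idx)) stop(path, ": no data rows")
  sep <- if (grepl("\t", lines[body_idx[1]])) "\t" else ","
  rows <- strsplit(lines[body_idx], sep, fixed = TRUE)
  ncol <- length(rows[[1]])
  has_names <- suppressWarnings(any(is.na(as.numeric(rows[[1]]))))
  col_names <- NULL
  if (has_names) {
    col_names <- trimws(rows[[1]])
    rows <- rows[-1]
    body_idx <- body_idx[-1]
  }
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncol)
      stop(path, " line ", body_idx[i], ": expected ", ncol,
           " fields, found ", length(rows[[i]]))
  }
  list(rows = rows, lines = body_idx, sep = sep, header = header,
       col_names = col_names)
}

.numeric_col <- function(parsed, j, path) {
  vals <- suppressWarnings(
    as.numeric(vapply(parsed$rows, `[[`, "", j)))
  bad <- which(is.na(vals))
  if (length(bad))
    stop(path, " line ", parsed$lines[bad[1]], ": non-numeric value '",
         parsed$rows[[bad[1]]][j], "'")
  vals
}

#' Read a skin conductance time series
#'
#' @param path File path.
#' @param dialect `"auto"` (default: two columns imply `time_value`),
#'   `"time_value"` or `"value"`.
#' @return An `sc_record` with metadata taken from `# subject:`,
#'   `# epoch:` and `# condition:` header comments when present.
#' @export
read_sc <- function(path, dialect = c("auto", "time_value", "value")) {
  dialect <- match.arg(dialect)
  p <- .read_delim_body(path)
  ncol <- length(p$rows[[1]])
  if (dialect == "auto") dialect <- if (ncol >= 2) "time_value" else "value"
  meta <- function(key) if (is.null(p$header[[key]])) NA_character_
                        else p$header[[key]]
  if (dialect == "time_value") {
    if (ncol < 2) stop(path, ": time_value dialect needs two columns")
    tm <- .numeric_col(p, 1, path)
    val <- .numeric_col(p, 2, path)
    if (length(tm) < 2) stop(path, ": need at least 2 samples")
    dts <- diff(tm)
    if (any(dts <= 0))
      stop(path, " line ", p$lines[which(dts <= 0)[1] + 1],
           ": time column must be strictly increasing")
    dt <- stats::median(dts)
    if (max(abs(dts - dt)) > 1e-6 * dt)
      stop(path, ": non-uniform sampling (spacing varies by more than ",
           "1e-6 relative)")
    start <- tm[1]
  } else {
    val <- .numeric_col(p, 1, path)
    if (length(val) < 2) stop(path, ": need at least 2 samples")
    if (is.null(p$header$sample_interval))
      stop(path, ": one-column dialect requires a ",
           "'# sample_interval: <s>' header")
    dt <- as.numeric(p$header$sample_interval)
    start <- if (is.null(p$header$start_time)) 0
             else as.numeric(p$header$start_time)
  }
  sc_record(val, dt, start_time = start, subject_id = meta("subject"),
            epoch_label = meta("epoch"), condition = meta("condition"))
}

#' Write a skin conductance time series
#'
#' Deterministic byte output for a fixed record: metadata as `#`
#' comment headers, then `time,value` rows (or a single value column)
#' formatted with `%.6g`.
#'
#' @param record An `sc_record`.
#' @param path Output path.
#' @param dialect `"time_value"` (default) or `"value"`.
#' @return `path`, invisibly.
#' @export
write_sc <- function(record, path, dialect = c("time_value", "value")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(record, "sc_record"))
  hdr <- character()
  for (key in c("subject", "epoch", "condition")) {
    val <- record[[c(subject = "subject_id", epoch = "epoch_label",
                     condition = "condition")[[key]]]]
    if (!is.na(val)) hdr <- c(hdr, sprintf("# %s: %s", key, val))
  }
  if (dialect == "value") {
    hdr <- c(hdr, sprintf("# sample_interval: %s",
                          fmt_num(record$sample_interval)))
    if (record$start_time != 0)
      hdr <- c(hdr, sprintf("# start_time: %s", fmt_num(record$start_time)))
    body <- c("value", fmt_num(record$samples))
  } else {
    body <- c("time,value",
              paste(fmt_num(sc_times(record)), fmt_num(record$samples),
                    sep = ","))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an event list
#'
#' Expects columns `time` (or `onset_s` / `peak_s`) and `amplitude`
#' (or `amplitude_uS`); extra columns are ignored. The anchor is
#' taken from a `# anchor:` header, a `peak_s` column name, or the
#' `anchor` argument.
#'
#' @param path File path.
#' @param anchor Fallback anchor if the file does not declare one.
#' @return An `event_train`.
#' @export
read_events <- function(path, anchor = c("onset", "peak")) {
  anchor <- match.arg(anchor)
  p <- .read_delim_body(path)
  if (is.null(p$col_names)) stop(path, ": event files need a header row")
  tcol <- which(p$col_names %in% c("time", "time_s", "onset_s", "peak_s"))
  acol <- which(p$col_names %in% c("amplitude", "amplitude_uS"))
  if (!length(tcol) || !length(acol))
    stop(path, ": need a time column (time/onset_s/peak_s) and an ",
         "amplitude column")
  if (p$col_names[tcol[1]] == "peak_s") anchor <- "peak"
  if (p$col_names[tcol[1]] == "onset_s") anchor <- "onset"
  if (!is.null(p$header$anchor)) anchor <- p$header$anchor
  times <- .numeric_col(p, tcol[1], path)
  amps <- .numeric_col(p, acol[1], path)
  ord <- order(times)
  event_train(times[ord], amps[ord], anchor = anchor)
}

#' Write an event list
#'
#' @param events An `event_train`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_train"))
  tname <- if (events$anchor == "peak") "peak_s" else "onset_s"
  writeLines(c(sprintf("# anchor: %s", events$anchor),
               paste(tname, "amplitude_uS", sep = ","),
               paste(fmt_num(events$times), fmt_num(events$amplitudes),
                     sep = ",")),
             path)
  invisible(path)
}

#' Read and write response functions
#'
#' Kernels travel as two-column delimited text (`lag_s,value`) so the
#' simulator and the deconvolution modules can exchange them exactly.
#'
#' @param path File path.
#' @return `read_rf`: a `response_function`.
#' @export
read_rf <- function(path) {
  p <- .read_delim_body(path)
  lag <- .numeric_col(p, 1, path)
  val <- .numeric_col(p, 2, path)
  if (length(lag) < 2) stop(path, ": kernel needs at least 2 samples")
  dt <- stats::median(diff(lag))
  if (max(abs(diff(lag) - dt)) > 1e-6 * dt)
    stop(path, ": non-uniform lag spacing")
  peak_lag <- if (is.null(p$header$peak_lag)) NA_real_
              else as.numeric(p$header$peak_lag)
  response_function(val, c(lag[1], lag[length(lag)] + dt), dt,
                    peak_lag = peak_lag)
}

#' @rdname read_rf
#' @param rf A `response_function`.
#' @return `write_rf`: `path`, invisibly.
#' @export
write_rf <- function(rf, path) {
  stopifnot(inherits(rf, "response_function"))
  hdr <- character()
  if (!is.na(rf$peak_lag))
    hdr <- sprintf("# peak_lag: %s", fmt_num(rf$peak_lag))
  writeLines(c(hdr, "lag_s,value",
               paste(fmt_num(rf_lags(rf)), fmt_num(rf$values), sep = ",")),
             path)
  invisible(path)
}

#' Serialise and restore simulation settings
#'
#' Configurations round-trip through YAML (or JSON, by extension);
#' the kernel is stored as its samples, window and sampling interval.
#'
#' @param config A `sim_config`.
#' @param path Output path, `.yaml`/`.yml` or `.json`.
#' @return `path` / a `sim_config`, invisibly for the writer.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named vectors go out as maps so names survive YAML/JSON
  for (nm in c("burst_rate", "amplitude_meanlog", "amplitude_sdlog"))
    x[[nm]] <- as.list(x[[nm]])
  x$kernel <- list(values = config$kernel$values,
                   window = config$kernel$window,
                   sample_interval = config$kernel$sample_interval,
                   peak_lag = config$kernel$peak_lag)
  # 17 significant digits: exact double round-trip in both formats
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  else yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  kern <- if (is.null(x$kernel)) default_kernel(x$sample_interval)
  else response_function(unlist(x$kernel$values), unlist(x$kernel$window),
                         x$kernel$sample_interval,
                         peak_lag = if (is.null(x$kernel$peak_lag))
                           NA_real_ else x$kernel$peak_lag)
  sim_config(
    n_subjects = x$n_subjects,
    epoch_labels = unlist(x$epoch_labels),
    epoch_conditions = unlist(x$epoch_conditions),
    epoch_duration = x$epoch_duration,
    sample_interval = x$sample_interval,
    burst_rate = unlist(x$burst_rate),
    amplitude_meanlog = unlist(x$amplitude_meanlog),
    amplitude_sdlog = unlist(x$amplitude_sdlog),
    kernel = kern,
    baseline_level = x$baseline_level,
    baseline_subject_sd = x$baseline_subject_sd,
    drift_slope = x$drift_slope,
    noise_sd = x$noise_sd,
    allow_edge_events = isTRUE(x$allow_edge_events),
    seed = x$seed)
}

#' Serialise a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  x <- unclass(report)
  x$rf <- list(values = report$rf$values, window = report$rf$window,
               sample_interval = report$rf$sample_interval)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a simulated study as a directory of delimited-text files
#'
#' One `<subject>_<epoch>.csv` time series per epoch, a
#' `truth_events.csv` table (subject, epoch, onset_s, amplitude_uS),
#' the generating kernel as `kernel.csv`, the configuration as
#' `config.yaml` and a `manifest.json` listing every file with the
#' epoch metadata.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  man$file <- sprintf("%s_%s.csv", man$subject, man$epoch)
  ev_rows <- list()
  for (i in seq_along(study$epochs)) {
    ep <- study$epochs[[i]]
    write_sc(ep$record, file.path(dir, man$file[i]))
    if (length(ep$truth))
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        subject = man$subject[i], epoch = man$epoch[i],
        onset_s = ep$truth$times, amplitude_uS = ep$truth$amplitudes,
        stringsAsFactors = FALSE)
  }
  ev <- if (length(ev_rows)) do.call(rbind, ev_rows)
        else data.frame(subject = character(), epoch = character(),
                        onset_s = numeric(), amplitude_uS = numeric())
  writeLines(c("subject,epoch,onset_s,amplitude_uS",
               if (nrow(ev)) paste(ev$subject, ev$epoch,
                                   fmt_num(ev$onset_s),
                                   fmt_num(ev$amplitude_uS), sep = ",")),
             file.path(dir, "truth_events.csv"))
  write_rf(study$config$kernel, file.path(dir, "kernel.csv"))
  write_sim_config(study$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}

#' Read a study directory back into a list of records
#'
#' @param dir A directory written by [write_study()] (or laid out the
#'   same way: a `manifest.json` whose rows name per-epoch CSV files).
#' @return A list with `records` (list of `sc_record`) and `manifest`.
#' @export
read_study <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  records <- lapply(seq_len(nrow(man)), function(i)
    read_sc(file.path(dir, man$file[i])))
  list(records = records, manifest = man)
}
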