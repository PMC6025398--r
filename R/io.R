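## External representations. CSV is the canonical dialect; a minimal
## WFDB-style header+signal reader/writer is provided for interoperability.
## Times are seconds from record start; intervals are milliseconds.

#' Read an ECG record
#'
#' CSV dialect accepts either two columns (`time_s,ecg_mV`) or a single
#' voltage column (`ecg_mV`) with the sampling rate supplied via `fs`.
#' The WFDB-style dialect reads a `<record>.hea` header naming an ASCII
#' signal file (see [write_ecg()]).
#'
#' @param path Path to the CSV file or to the `.hea` header.
#' @param dialect `"csv"` or `"wfdb"`.
#' @param fs Sampling rate in Hz; required for single-column CSV, ignored
#'   when a time column or header provides it.
#' @param lead Lead label override.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, dialect = c("csv", "wfdb"), fs = NULL, lead = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  if (dialect == "wfdb") return(read_ecg_wfdb(path, lead = lead))

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  tcol <- which(nm %in% c("time_s", "time", "t_s", "t"))[1]
  vcol <- which(grepl("ecg|mv|volt|signal", nm))[1]
  if (is.na(vcol)) {
    if (ncol(df) == 1L) vcol <- 1L
    else if (!is.na(tcol) && ncol(df) == 2L) vcol <- setdiff(1:2, tcol)
    else stop_format("cannot identify the voltage column in ECG CSV")
  }
  v <- as.numeric(df[[vcol]])
  if (anyNA(v)) stop_format("non-numeric voltage values in ECG CSV")
  t0 <- 0
  if (!is.na(tcol)) {
    tt <- as.numeric(df[[tcol]])
    if (anyNA(tt)) stop_format("non-numeric time values in ECG CSV")
    dt <- diff(tt)
    if (any(dt <= 0)) stop_format("time column must be strictly increasing")
    fs_est <- 1 / stats::median(dt)
    if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
      stop_format("time column is not uniformly sampled")
    fs <- fs %||% fs_est
    t0 <- tt[1]
  }
  if (is.null(fs))
    stop_format("ECG CSV has no time column and no fs was declared")
  ecg_record(v, fs = fs, t0 = t0, lead = lead %||% "I")
}

#' Write an ECG record
#'
#' @param ecg An [ecg_record()].
#' @param path Output path: CSV file, or the `.hea` header path for
#'   `dialect = "wfdb"` (the signal goes to the matching `.sig` ASCII file).
#' @param dialect `"csv"` (with time column) or `"wfdb"`.
#' @export
write_ecg <- function(ecg, path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ecg, "ecg_record"))
  if (dialect == "csv") {
    tt <- ecg$t0 + (seq_along(ecg$samples) - 1) / ecg$fs
    utils::write.csv(
      data.frame(time_s = sprintf("%.9g", tt),
                 ecg_mV = sprintf("%.9g", ecg$samples)),
      path, row.names = FALSE, quote = FALSE)
  } else {
    record <- sub("\\.hea$", "", basename(path))
    sig <- file.path(dirname(path), paste0(record, ".sig"))
    gain <- 1000  # ADC units per mV
    adc <- round(ecg$samples * gain)
    writeLines(c(
      sprintf("%s 1 %.9g %d", record, ecg$fs, length(ecg$samples)),
      sprintf("%s.sig ascii %d 0 mV %s", record, gain, ecg$lead)
    ), path)
    writeLines(format(adc, scientific = FALSE, trim = TRUE), sig)
  }
  invisible(path)
}

read_ecg_wfdb <- function(path, lead = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop_format("WFDB-style header needs record and signal lines")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3L) stop_format("malformed WFDB-style record line")
  fs <- as.numeric(hdr[3])
  if (is.na(fs) || fs <= 0) stop_format("missing or invalid fs in WFDB-style header")
  sigspec <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  sigfile <- file.path(dirname(path), sigspec[1])
  if (!file.exists(sigfile)) stop_format(paste("signal file missing:", sigfile))
  fmt <- if (length(sigspec) >= 2) sigspec[2] else "ascii"
  if (fmt != "ascii") stop_format(paste("unsupported WFDB-style format:", fmt))
  gain <- if (length(sigspec) >= 3) as.numeric(sigspec[3]) else 200
  baseline <- if (length(sigspec) >= 4) as.numeric(sigspec[4]) else 0
  lab <- if (length(sigspec) >= 6) sigspec[6] else "I"
  adc <- scan(sigfile, what = double(), quiet = TRUE)
  ecg_record((adc - baseline) / gain, fs = fs, lead = lead %||% lab)
}

#' Read / write an RR interval series
#'
#' Accepts a bare text file with one interval (ms) per line, or a CSV with an
#' interval column (named `rr_ms`, `interval_ms`, `rr` or `interval`) and an
#' optional terminal beat-time column (`beat_time_s` / `time_s`).
#'
#' @param path File path.
#' @return An [rr_series()] (validity unknown).
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("[A-Za-z]", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    nm <- tolower(names(df))
    icol <- which(nm %in% c("rr_ms", "interval_ms", "rr", "interval"))[1]
    if (is.na(icol)) stop_format("RR CSV has no interval column")
    tcol <- which(nm %in% c("beat_time_s", "time_s"))[1]
    iv <- suppressWarnings(as.numeric(df[[icol]]))
    if (anyNA(iv)) stop_format("non-numeric RR interval")
    if (any(iv <= 0)) stop_format("non-positive RR interval")
    bt <- if (!is.na(tcol)) as.numeric(df[[tcol]]) else NULL
    rr_series(iv, beat_times = bt)
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    iv <- suppressWarnings(as.numeric(txt))
    if (anyNA(iv)) stop_format("non-numeric RR interval")
    if (any(iv <= 0)) stop_format("non-positive RR interval")
    rr_series(iv)
  }
}

#' @rdname read_rr
#' @param rr An [rr_series()].
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(rr$beat_times)) {
    writeLines(sprintf("%.9g", rr$intervals), path)
  } else {
    utils::write.csv(
      data.frame(beat_time_s = sprintf("%.9g", rr$beat_times),
                 rr_ms = sprintf("%.9g", rr$intervals)),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write protocol event annotations
#'
#' Events CSV: `label,onset_s[,duration_s]`, onsets non-decreasing.
#'
#' @param path File path.
#' @return An [event_annotations()] data.frame ordered by onset.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  lcol <- which(nm %in% c("label", "condition", "event"))[1]
  ocol <- which(nm %in% c("onset_s", "onset", "start_s", "start"))[1]
  if (is.na(lcol) || is.na(ocol)) stop_format("events CSV needs label and onset columns")
  dcol <- which(nm %in% c("duration_s", "duration"))[1]
  onset <- suppressWarnings(as.numeric(df[[ocol]]))
  if (anyNA(onset)) stop_format("non-numeric event onset")
  dur <- if (!is.na(dcol)) suppressWarnings(as.numeric(df[[dcol]])) else NA_real_
  event_annotations(df[[lcol]], onset, dur)
}

#' @rdname read_events
#' @param events An [event_annotations()] data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(
    data.frame(label = events$label,
               onset_s = sprintf("%.9g", events$onset),
               duration_s = ifelse(is.na(events$duration), "",
                                   sprintf("%.9g", events$duration))),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

CRTT_OUTCOMES <- c("correct", "incorrect", "missed")

#' Read / write a choice-reaction-time task trial log
#'
#' CSV columns: `trial,stimulus,onset_s,display_ms,response_key,rt_ms,outcome`.
#' `stimulus` is `congruent`/`incongruent`; `response_key` is `1`, `3` or
#' empty (missed); `outcome` one of `correct`, `incorrect`, `missed` (if
#' absent it is derived from the key mapping via [classify_response()]).
#'
#' @param path File path.
#' @return A data.frame of class `crtt_log`.
#' @export
read_crtt_log <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "stimulus", "onset_s", "display_ms", "response_key", "rt_ms")
  if (!all(need %in% names(df)))
    stop_format(paste("CRTT CSV missing columns:",
                      paste(setdiff(need, names(df)), collapse = ", ")))
  df$response_key <- as.character(df$response_key)
  if (!all(df$stimulus %in% c("congruent", "incongruent")))
    stop_format("unknown stimulus token in CRTT log")
  df$response_key[df$response_key %in% c("", "none", "NA")] <- NA_character_
  df$rt_ms <- suppressWarnings(as.numeric(df$rt_ms))
  if ("outcome" %in% names(df)) {
    if (!all(df$outcome %in% CRTT_OUTCOMES))
      stop_format("unknown outcome token in CRTT log")
  } else {
    df$outcome <- classify_response(df$stimulus, df$response_key)
  }
  if (any(!is.na(df$rt_ms) & is.na(df$response_key)))
    stop_format("rt_ms present without a response key")
  class(df) <- c("crtt_log", "data.frame")
  df
}

#' @rdname read_crtt_log
#' @param log A `crtt_log` data.frame.
#' @export
write_crtt_log <- function(log, path) {
  out <- as.data.frame(log)
  out$response_key[is.na(out$response_key)] <- ""
  out$rt_ms <- ifelse(is.na(out$rt_ms), "", sprintf("%.9g", out$rt_ms))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write detected beat times
#'
#' Beats CSV: single column `beat_time_s`.
#' @param path File path.
#' @return A [beat_annotations()].
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- which(tolower(names(df)) %in% c("beat_time_s", "time_s"))[1]
  if (is.na(col)) stop_format("beats CSV needs a beat_time_s column")
  beat_annotations(as.numeric(df[[col]]))
}

#' @rdname read_beats
#' @param beats A [beat_annotations()].
#' @export
write_beats <- function(beats, path) {
  utils::write.csv(data.frame(beat_time_s = sprintf("%.9g", beats$beat_times)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
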