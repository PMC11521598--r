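#' Construct a physiological signal recording
#'
#' A `signal_recording` holds one uniformly sampled channel of physiology
#' (ECG, respiration belt, or skin conductance) together with its sampling
#' rate and units. All preprocessing functions consume and return this
#' container.
#'
#' @param samples Numeric vector of samples; must be finite and non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel One of `"ECG"`, `"RSP"`, `"SC"`.
#' @param units Units string: `"mV"` (ECG), `"mcV"` (respiration belt
#'   microvolts), or `"uS"` (skin conductance microsiemens). Defaults to the
#'   conventional unit of the channel.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(samples, fs, channel = c("ECG", "RSP", "SC"),
                             units = NULL, t0 = 0) {
  channel <- match.arg(channel)
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) stop("`samples` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (is.null(units)) {
    units <- c(ECG = "mV", RSP = "mcV", SC = "uS")[[channel]]
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, channel = channel,
         units = units, t0 = t0),
    class = "signal_recording"
  )
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %s: %d samples @ %g Hz (%s), %.1f s\n",
              x$channel, length(x$samples), x$fs, x$units,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Sample times of a recording
#' @param x A `signal_recording`.
#' @return Numeric vector of sample times in seconds.
#' @export
recording_times <- function(x) {
  stopifnot(inherits(x, "signal_recording"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' Duration of a recording in seconds
#' @param x A `signal_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(x) {
  stopifnot(inherits(x, "signal_recording"))
  length(x$samples) / x$fs
}

#' Write a recording to the package CSV dialect
#'
#' The on-disk dialect is a UTF-8 comma-separated file whose first line is a
#' comment header `# fs=<Hz> units=<mV|mcV|uS>` followed by a
#' `time_s,value` column header and data rows.
#'
#' @param x A `signal_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "signal_recording"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g units=%s", x$fs, x$units), con)
  writeLines("time_s,value", con)
  t <- x$t0 + (seq_along(x$samples) - 1L) / x$fs
  writeLines(paste(formatC(t, format = "fg", digits = 10),
                   formatC(x$samples, format = "g", digits = 9), sep = ","),
             con)
  invisible(path)
}

#' Read a recording from the package CSV dialect
#'
#' @param path File written by [write_signal_csv()].
#' @param channel Channel label to attach (`"ECG"`, `"RSP"`, `"SC"`).
#' @return A `signal_recording`.
#' @export
read_signal_csv <- function(path, channel = c("ECG", "RSP", "SC")) {
  channel <- match.arg(channel)
  header <- readLines(path, n = 1L)
  if (!grepl("^#\\s*fs=", header)) {
    stop("missing `# fs=... units=...` header in ", path)
  }
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", header))
  units <- sub(".*units=(\\S+).*", "\\1", header)
  dat <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "value") %in% names(dat))) {
    stop("expected columns time_s,value in ", path)
  }
  signal_recording(dat$value, fs = fs, channel = channel, units = units,
                   t0 = dat$time_s[1L])
}
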