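#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the requested order and applies it
#' forward-backward (`signal::filtfilt`), so peak timing is preserved
#' across channels; the effective magnitude order doubles. This is the
#' single filtering primitive behind the per-channel chains: 1-100 Hz
#' (order 4) for ECG, 0.04-0.4 Hz (order 4) for the interpolated IBI
#' series, and 0.05-5 Hz (order 1) for phasic skin conductance.
#'
#' @param x A `signal_recording`.
#' @param low,high Passband edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return A filtered `signal_recording` of the same length.
#' @export
bandpass <- function(x, low, high, order = 4) {
  stopifnot(inherits(x, "signal_recording"))
  nyq <- x$fs / 2
  if (low <= 0) stop("`low` cutoff must be positive (got ", low, ")")
  if (high <= low) stop("`high` cutoff must exceed `low`")
  if (high >= nyq) {
    stop(sprintf("`high` cutoff %g Hz is at or above Nyquist (%g Hz)", high, nyq))
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # odd-reflection padding suppresses the start-up transients of
  # forward-backward filtering (six time constants of the low cutoff)
  s <- x$samples
  n <- length(s)
  p <- min(n - 1L, ceiling(6 * x$fs / low))
  left <- 2 * s[1L] - s[(p + 1L):2L]
  right <- 2 * s[n] - s[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(left, s, right))
  out <- x
  out$samples <- as.numeric(y[(p + 1L):(p + n)])
  out
}

# Local maxima strictly above both neighbours.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Enforce a refractory period: greedily keep the largest candidate, then
# drop any candidate within `min_sep` samples of an accepted one.
enforce_refractory <- function(idx, values, min_sep) {
  if (length(idx) == 0) return(idx)
  ord <- order(values[idx], decreasing = TRUE)
  keep <- logical(length(idx))
  taken <- numeric(0)
  for (j in ord) {
    if (length(taken) == 0 || all(abs(idx[j] - taken) >= min_sep)) {
      keep[j] <- TRUE
      taken <- c(taken, idx[j])
    }
  }
  sort(idx[keep])
}

#' Detect ECG R-peaks by template convolution
#'
#' Builds a QRS template as the median beat around the strongest local
#' maxima of the (already 1-100 Hz band-passed) ECG, cross-correlates the
#' template with the signal, z-scores the result, and accepts peaks of the
#' normalized correlation exceeding `threshold_sd` standard deviations,
#' with a 250 ms refractory period against double detections. Each
#' accepted peak is refined to the local ECG maximum within a small
#' window.
#'
#' @param ecg A `signal_recording` (channel ECG), band-passed 1-100 Hz,
#'   at least 5 s long.
#' @param threshold_sd Detection threshold in SD units of the normalized
#'   correlation (default 0.6).
#' @param refractory_s Minimum separation between accepted peaks
#'   (default 0.25 s).
#' @param template_n Number of strongest beats used for the template
#'   (default 30).
#' @return Numeric vector of strictly increasing peak times (s), with the
#'   template attached as attribute `template`.
#' @export
detect_r_peaks <- function(ecg, threshold_sd = 0.6, refractory_s = 0.25,
                           template_n = 30) {
  stopifnot(inherits(ecg, "signal_recording"))
  if (recording_duration(ecg) < 5) stop("ECG shorter than 5 s")
  x <- ecg$samples
  fs <- ecg$fs
  if (stats::sd(x) < 1e-12) {
    stop("no QRS template: signal is flat (SD below machine-precision floor)")
  }
  half <- round(0.08 * fs)
  # candidate beats: local maxima above 2 SD, 250 ms apart
  cand <- local_maxima(x)
  cand <- cand[x[cand] > 2 * stats::sd(x)]
  cand <- enforce_refractory(cand, x, round(refractory_s * fs))
  cand <- cand[cand > half & cand <= length(x) - half]
  if (length(cand) < 3) {
    # fall back to the largest excursions regardless of threshold
    cand <- local_maxima(x)
    cand <- enforce_refractory(cand, x, round(refractory_s * fs))
    cand <- cand[cand > half & cand <= length(x) - half]
    if (length(cand) < 3) stop("no QRS template: too few candidate beats")
  }
  top <- cand[order(x[cand], decreasing = TRUE)][seq_len(min(template_n, length(cand)))]
  beats <- vapply(top, function(i) x[(i - half):(i + half)],
                  numeric(2 * half + 1))
  template <- apply(beats, 1, stats::median)
  template <- template - mean(template)
  # cross-correlation via FFT (template centred), z-scored
  n <- length(x)
  npad <- 2^ceiling(log2(n + length(template)))
  ft <- stats::fft(c(template, numeric(npad - length(template))))
  fx <- stats::fft(c(x, numeric(npad - n)))
  cc <- Re(stats::fft(fx * Conj(ft), inverse = TRUE)) / npad
  # lag alignment: correlation value for template centred at sample i
  cc <- c(cc[(npad - half + 1):npad], cc[seq_len(n - half)])
  z <- (cc - mean(cc)) / stats::sd(cc)
  peaks <- local_maxima(z)
  peaks <- peaks[z[peaks] > threshold_sd]
  peaks <- enforce_refractory(peaks, z, round(refractory_s * fs))
  if (length(peaks) == 0) stop("no R-peaks detected above the threshold")
  # deterministic stand-in for the visual correction of misidentified
  # peaks: candidates far weaker than the strong beats are noise crossings
  # of the 0.6 SD threshold (reference = upper decile, robust to a
  # majority of spurious candidates)
  z_ref <- stats::quantile(z[peaks], 0.9, names = FALSE)
  peaks <- peaks[z[peaks] >= 0.4 * z_ref]
  if (length(peaks) == 0) stop("no R-peaks detected above the threshold")
  # refine to the ECG maximum near each correlation peak
  w <- round(0.02 * fs)
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  out <- ecg$t0 + (peaks - 1) / fs
  attr(out, "template") <- template
  out
}

#' Build an inter-beat-interval series from R-peak times
#'
#' IBIs are the differences between consecutive R-peaks in milliseconds.
#' The IBI sequence is interpolated with a cubic spline, resampled at
#' 20 Hz over `[first_peak, last_peak]`, and band-pass filtered between
#' 0.04 and 0.4 Hz (Butterworth, order 4, zero phase) to isolate the
#' low- and high-frequency heart-rate-variability bands. The mean IBI is
#' recorded before band-passing, as an inverse index of heart rate.
#'
#' @param peaks Strictly increasing R-peak times in seconds (>= 3).
#' @param interp_fs Resampling rate in Hz (default 20).
#' @return A list of class `ibi_series`: `peak_times` (s), `ibis_ms`,
#'   `mean_ibi_ms`, `interp_fs`, `interp_times` (s), `interp_trace`
#'   (band-passed, ms).
#' @export
build_ibi <- function(peaks, interp_fs = 20) {
  peaks <- as.numeric(peaks)
  if (length(peaks) < 3) stop("need at least 3 R-peaks to build an IBI series")
  if (any(diff(peaks) <= 0)) stop("R-peak times must be strictly increasing")
  ibis <- diff(peaks) * 1000
  # assign each interval to its ending beat time
  tt <- peaks[-1L]
  sf <- stats::splinefun(tt, ibis, method = "natural")
  times <- seq(peaks[1L], peaks[length(peaks)], by = 1 / interp_fs)
  trace <- sf(times)
  rec <- signal_recording(trace, fs = interp_fs, channel = "ECG", units = "ms",
                          t0 = times[1L])
  filtered <- bandpass(rec, 0.04, 0.4, order = 4)
  structure(
    list(peak_times = peaks, ibis_ms = ibis, mean_ibi_ms = mean(ibis),
         interp_fs = interp_fs, interp_times = times,
         interp_trace = filtered$samples),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats, mean IBI %.1f ms (%.1f bpm), %d-sample 20 Hz trace\n",
              length(x$peak_times), x$mean_ibi_ms, 60000 / x$mean_ibi_ms,
              length(x$interp_trace)))
  invisible(x)
}

#' Detect expiration onsets and respiratory rate
#'
#' Expiration onsets are local maxima of the chest-circumference signal
#' (peak lung inflation); a minimum inter-onset separation of 1 s and a
#' prominence requirement (peaks above the signal mean) suppress noise
#' peaks. The respiratory rate is the number of onsets per minute.
#'
#' @param rsp A `signal_recording` (channel RSP), at least 30 s long.
#' @param min_sep_s Minimum separation between onsets (default 1 s).
#' @return A list with `onset_times` (s) and `rate_per_min`.
#' @export
detect_expirations <- function(rsp, min_sep_s = 1) {
  stopifnot(inherits(rsp, "signal_recording"))
  dur <- recording_duration(rsp)
  if (dur < 30) stop("respiration recording shorter than 30 s")
  x <- rsp$samples
  if (stats::sd(x) < 1e-12) stop("flat respiration signal: no detectable cycles")
  idx <- local_maxima(x)
  idx <- idx[x[idx] > mean(x)]
  idx <- enforce_refractory(idx, x, round(min_sep_s * rsp$fs))
  if (length(idx) == 0) stop("no expiration onsets detected")
  onsets <- rsp$t0 + (idx - 1) / rsp$fs
  list(onset_times = onsets, rate_per_min = length(onsets) / (dur / 60))
}

#' Extract the phasic skin conductance component
#'
#' Band-pass filters the skin conductance signal between 0.05 and 5 Hz
#' (Butterworth, first order, zero phase), removing the tonic level and
#' slow drift so that only the fast, event-like component remains.
#'
#' @param sc A `signal_recording` (channel SC).
#' @return A `signal_recording` of the phasic component (uS).
#' @export
extract_phasic_sc <- function(sc) {
  stopifnot(inherits(sc, "signal_recording"))
  if (sc$channel != "SC") stop("`extract_phasic_sc` expects an SC recording")
  bandpass(sc, 0.05, 5, order = 1)
}

#' Count skin conductance responses in a phasic trace
#'
#' An SCR is counted at each upward crossing of the phasic amplitude
#' threshold (default 0.01 uS) separated by at least 1 s.
#'
#' @param phasic A phasic `signal_recording` (see [extract_phasic_sc()]).
#' @param threshold_us Amplitude threshold in uS (default 0.01).
#' @param min_sep_s Minimum separation between counted responses.
#' @return Numeric vector of SCR onset times (s).
#' @export
count_scrs <- function(phasic, threshold_us = 0.01, min_sep_s = 1) {
  stopifnot(inherits(phasic, "signal_recording"))
  x <- phasic$samples
  up <- which(x[-1L] >= threshold_us & x[-length(x)] < threshold_us) + 1L
  if (length(up) > 1) {
    keep <- c(TRUE, diff(up) >= min_sep_s * phasic$fs)
    up <- up[keep]
  }
  phasic$t0 + (up - 1) / phasic$fs
}

# longest run of (near-)zero values, in samples
longest_null_run <- function(x, tol = 0) {
  isnull <- abs(x) <= tol
  if (!any(isnull)) return(0L)
  r <- rle(isnull)
  max(r$lengths[r$values])
}

#' Flag respiration artifacts across a participant sample
#'
#' A participant is excluded when, for at least one video, (a) the longest
#' run of consecutive null samples exceeds 5% of the video duration
#' (constant signal from a loose belt), or (b) the recording's variance
#' exceeds the sample mean of variances by more than three sample SDs of
#' the variances (noisy signal from a dysfunctional belt). The variance
#' rule is sample-relative and therefore needs at least 2 participants.
#'
#' @param recordings A list, one element per participant, each a list of
#'   `signal_recording`s (one per video).
#' @param null_frac Null-run threshold as a fraction of video duration
#'   (default 0.05).
#' @param null_tol Absolute tolerance below which a sample counts as null
#'   (default 0).
#' @param variance_rule `"variance"` (default: compare variances in
#'   variance units) or `"sd"` (compare in SD units).
#' @return A data frame of class `artifact_report`: one row per
#'   participant with `participant`, `rule` (`"rsp_null_run"`,
#'   `"rsp_variance"`, or `"none"`), per-video flag columns and `excluded`.
#' @export
flag_rsp_artifacts <- function(recordings, null_frac = 0.05, null_tol = 0,
                               variance_rule = c("variance", "sd")) {
  variance_rule <- match.arg(variance_rule)
  np <- length(recordings)
  if (np < 2) stop("the variance rule is sample-relative: need >= 2 participants")
  stat_fun <- if (variance_rule == "variance") stats::var else stats::sd
  vhat <- lapply(recordings, function(vids) {
    vapply(vids, function(r) stat_fun(r$samples), numeric(1))
  })
  allv <- unlist(vhat)
  vbar <- mean(allv)
  vsd <- stats::sd(allv)
  rows <- lapply(seq_len(np), function(i) {
    vids <- recordings[[i]]
    nullrun <- vapply(vids, function(r) {
      longest_null_run(r$samples, tol = null_tol) / length(r$samples) > null_frac
    }, logical(1))
    noisy <- vhat[[i]] > vbar + 3 * vsd
    fired <- if (any(nullrun)) "rsp_null_run" else if (any(noisy)) "rsp_variance" else "none"
    data.frame(participant = i, rule = fired,
               video1 = nullrun[1] || noisy[1],
               video2 = if (length(vids) > 1) nullrun[2] || noisy[2] else FALSE,
               video3 = if (length(vids) > 2) nullrun[3] || noisy[3] else FALSE,
               excluded = any(nullrun) || any(noisy))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("artifact_report", class(out))
  out
}

#' Flag skin conductance artifacts
#'
#' A participant is excluded when (a) no skin conductance response is
#' detected in any of the three videos (unresponsive participant), or (b)
#' implausible slopes (absolute value above 2 uS per second, evaluated on
#' 1 s windows) cover more than 5% of the duration of at least one video.
#'
#' @param recordings A list, one element per participant, each a list of
#'   raw SC `signal_recording`s (one per video).
#' @param slope_limit_us_per_s Slope magnitude limit (default 2 uS/s).
#' @param slope_frac Duration fraction above which the slope rule fires
#'   (default 0.05).
#' @param scr_threshold_us Phasic threshold for SCR counting
#'   (default 0.01 uS).
#' @return An `artifact_report` data frame with rules `"sc_unresponsive"`,
#'   `"sc_slope"`, or `"none"`.
#' @export
flag_sc_artifacts <- function(recordings, slope_limit_us_per_s = 2,
                              slope_frac = 0.05, scr_threshold_us = 0.01) {
  rows <- lapply(seq_along(recordings), function(i) {
    vids <- recordings[[i]]
    nscr <- vapply(vids, function(r) {
      length(count_scrs(extract_phasic_sc(r), threshold_us = scr_threshold_us))
    }, numeric(1))
    slope_bad <- vapply(vids, function(r) {
      w <- max(1L, round(r$fs))  # 1 s windows
      nwin <- floor(length(r$samples) / w)
      if (nwin < 1) return(FALSE)
      sl <- vapply(seq_len(nwin), function(k) {
        seg <- r$samples[((k - 1) * w + 1):(k * w)]
        (seg[length(seg)] - seg[1]) / (w / r$fs)
      }, numeric(1))
      mean(abs(sl) > slope_limit_us_per_s) > slope_frac
    }, logical(1))
    unresponsive <- length(vids) >= 3 && all(nscr == 0)
    fired <- if (unresponsive) "sc_unresponsive" else if (any(slope_bad)) "sc_slope" else "none"
    data.frame(participant = i, rule = fired,
               video1 = slope_bad[1],
               video2 = if (length(vids) > 1) slope_bad[2] else FALSE,
               video3 = if (length(vids) > 2) slope_bad[3] else FALSE,
               excluded = unresponsive || any(slope_bad))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("artifact_report", class(out))
  out
}

#' Flag statistical outliers by the 3 x IQR rule
#'
#' A value is an outlier when it lies below `Q1 - 3 * IQR` or above
#' `Q3 + 3 * IQR`, with quartiles computed by linear interpolation
#' (quantile type 7). For normal data these fences sit near +/- 4.7 SD, so
#' the expected flag rate is essentially zero.
#'
#' @param values Numeric vector with at least 4 values.
#' @return Logical mask, `TRUE` for outliers.
#' @export
flag_statistical_outliers <- function(values) {
  if (length(values) < 4) stop("need at least 4 values for the IQR rule")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 3 * iqr | values > q[2] + 3 * iqr
}
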