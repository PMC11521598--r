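#' Wavelet-transform-coherence configuration
#'
#' Parameters of the Morlet continuous wavelet transform and of the
#' smoothing used by wavelet transform coherence (WTC). Defaults follow the
#' Grinsted-style analysis conventions for bio-behavioural time series:
#' Morlet centre frequency 6, 12 voices per octave, smallest scale `2/fs`,
#' largest scale a quarter of the record length, Gaussian time smoothing
#' with SD `scale/sqrt(2)`, and a boxcar over 0.6 octaves in scale.
#'
#' @param omega0 Morlet centre frequency (unitless, default 6).
#' @param voices_per_octave Number of scales per octave (>= 4, default 12).
#' @param min_scale Smallest scale in seconds; default `2/fs` at transform
#'   time.
#' @param max_scale Largest scale in seconds; default one quarter of the
#'   record duration.
#' @param scale_smooth_octaves Width of the scale-smoothing boxcar in
#'   octaves (default 0.6).
#' @param coi_efold Cone-of-influence e-folding factor: cells closer than
#'   `coi_efold * scale` seconds to either record edge are excluded from
#'   averages (default `sqrt(2)`).
#' @param sqrt_coherence If `TRUE`, report the square root of the
#'   magnitude-squared coherence (an absolute-correlation-style value);
#'   default `FALSE` (magnitude-squared coherence).
#' @return A list of class `wtc_config`.
#' @export
wtc_config <- function(omega0 = 6, voices_per_octave = 12,
                       min_scale = NULL, max_scale = NULL,
                       scale_smooth_octaves = 0.6,
                       coi_efold = sqrt(2),
                       sqrt_coherence = FALSE) {
  if (voices_per_octave < 4) stop("`voices_per_octave` must be >= 4")
  if (omega0 <= 0) stop("`omega0` must be positive")
  structure(
    list(omega0 = omega0, voices_per_octave = voices_per_octave,
         min_scale = min_scale, max_scale = max_scale,
         scale_smooth_octaves = scale_smooth_octaves,
         coi_efold = coi_efold, sqrt_coherence = sqrt_coherence),
    class = "wtc_config"
  )
}

# Logarithmic scale grid for a record of n samples at rate fs.
wtc_scales <- function(n, fs, cfg) {
  dt <- 1 / fs
  s0 <- if (is.null(cfg$min_scale)) 2 * dt else cfg$min_scale
  if (s0 < 2 * dt) stop("`min_scale` must be >= 2/fs")
  smax <- if (is.null(cfg$max_scale)) n * dt / 4 else cfg$max_scale
  if (smax <= s0) stop("`max_scale` must exceed the smallest scale")
  J <- floor(cfg$voices_per_octave * log2(smax / s0))
  s0 * 2^((0:J) / cfg$voices_per_octave)
}

# Equivalent Fourier frequency of a Morlet wavelet at a given scale.
morlet_fourier_freq <- function(scales, omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * scales)
}

# Padded Morlet CWT. Returns the transform over the zero-padded domain
# (npad columns) so that WTC smoothing can reuse the padded grid; `n` gives
# the unpadded length.
cwt_morlet_padded <- function(x, fs, cfg) {
  n <- length(x)
  if (n < 64) stop("input too short for a wavelet transform (need >= 64 samples)")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  dt <- 1 / fs
  scales <- wtc_scales(n, fs, cfg)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), numeric(npad - n))
  fx <- stats::fft(xp)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  # Wavelet filter bank in the frequency domain: rows = frequencies,
  # columns = scales; heaviside cut keeps the analytic (positive-frequency)
  # part of the Morlet wavelet.
  W <- matrix(0+0i, nrow = npad, ncol = length(scales))
  pos <- omega > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- pi^(-0.25) * exp(-0.5 * (s * omega[pos] - cfg$omega0)^2) *
      sqrt(2 * pi * s / dt)
    W[, j] <- fx * psi
  }
  W <- stats::mvfft(W, inverse = TRUE) / npad
  list(coef = W, scales = scales,
       freqs = morlet_fourier_freq(scales, cfg$omega0),
       n = n, npad = npad, fs = fs, cfg = cfg)
}

#' Continuous Morlet wavelet transform over logarithmic scales
#'
#' @param x Numeric vector (>= 64 finite samples).
#' @param fs Sampling rate in Hz.
#' @param cfg A [wtc_config()].
#' @return A list with complex `coef` (scales x time), `scales` (s),
#'   `freqs` (Hz, the equivalent Fourier frequency of each scale), `times`
#'   (s), and `coi_mask` (logical scales x time, `TRUE` = inside the usable
#'   region, i.e. outside the cone of influence).
#' @export
cwt_morlet <- function(x, fs, cfg = wtc_config()) {
  w <- cwt_morlet_padded(x, fs, cfg)
  coef <- t(w$coef[seq_len(w$n), , drop = FALSE])
  list(coef = coef, scales = w$scales, freqs = w$freqs,
       times = (seq_len(w$n) - 1) / fs,
       coi_mask = coi_mask(w$n, fs, w$scales, cfg$coi_efold))
}

# Usable-region mask: TRUE where the distance to the nearer record edge
# exceeds the e-folding time of the wavelet at that scale.
coi_mask <- function(n, fs, scales, coi_efold = sqrt(2)) {
  t <- (seq_len(n) - 1) / fs
  edge_dist <- pmin(t, (n - 1) / fs - t)
  outer(coi_efold * scales, edge_dist, FUN = "<=")
}

# Smooth a (npad x nscales) complex field: Gaussian in time (SD =
# scale/sqrt(2), applied in the frequency domain over the padded record)
# then a boxcar across scales spanning `scale_smooth_octaves` octaves,
# applied after trimming to `n_keep` rows (scale smoothing is columnwise
# and unaffected by the trim).
wtc_smooth <- function(M, scales, fs, npad, cfg, n_keep = npad) {
  dt <- 1 / fs
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  Fm <- stats::mvfft(M)
  for (j in seq_along(scales)) {
    Fm[, j] <- Fm[, j] * exp(-0.25 * (scales[j] * omega)^2)
  }
  M <- stats::mvfft(Fm, inverse = TRUE) / npad
  M <- M[seq_len(n_keep), , drop = FALSE]
  # boxcar over scales
  w <- max(1L, round(cfg$scale_smooth_octaves * cfg$voices_per_octave))
  if (w > 1L) {
    ns <- length(scales)
    half <- (w - 1) / 2
    lo <- pmax(1L, ceiling(seq_len(ns) - half))
    hi <- pmin(ns, floor(seq_len(ns) + half))
    S <- matrix(0, ns, ns)
    for (j in seq_len(ns)) S[lo[j]:hi[j], j] <- 1 / (hi[j] - lo[j] + 1)
    M <- M %*% S
  }
  M
}

#' Wavelet transform coherence between two equally sampled signals
#'
#' Computes the magnitude-squared wavelet coherence
#' `|S(Wxy/s)|^2 / (S(|Wx|^2/s) * S(|Wy|^2/s))`, where `S` is the
#' time-then-scale smoothing operator and `s` the scale. Values are clamped
#' to the unit interval. The map is symmetric in its arguments and
#' invariant to separate affine rescaling of either signal.
#'
#' @param x,y Numeric vectors of equal length (>= 64).
#' @param fs Common sampling rate in Hz.
#' @param cfg A [wtc_config()].
#' @return A `wtc_map`: list with `times` (s), `freqs` (Hz), `scales` (s),
#'   `coherence` (scales x time matrix in `[0, 1]`), and `coi_mask`
#'   (logical, `TRUE` = usable cell inside the record, outside the cone of
#'   influence).
#' @export
wavelet_coherence <- function(x, y, fs, cfg = wtc_config()) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length (got ",
         length(x), " and ", length(y), ")")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("coherence undefined for a constant input (zero auto-spectrum)")
  }
  wx <- cwt_morlet_padded(x, fs, cfg)
  wy <- cwt_morlet_padded(y, fs, cfg)
  wtc_from_cwt(wx, wy, cfg)
}

# Core coherence computation from two padded CWTs (shared with the
# surrogate machinery, which caches per-individual transforms).
wtc_from_cwt <- function(wx, wy, cfg,
                         sx = NULL, sy = NULL) {
  scales <- wx$scales
  npad <- wx$npad
  fs <- wx$fs
  n <- wx$n
  inv_s <- matrix(1 / scales, nrow = npad, ncol = length(scales), byrow = TRUE)
  if (is.null(sx)) {
    sx <- Re(wtc_smooth(abs(wx$coef)^2 * inv_s, scales, fs, npad, cfg, n))
  }
  if (is.null(sy)) {
    sy <- Re(wtc_smooth(abs(wy$coef)^2 * inv_s, scales, fs, npad, cfg, n))
  }
  sxy <- wtc_smooth(wx$coef * Conj(wy$coef) * inv_s, scales, fs, npad, cfg, n)
  r2 <- Mod(sxy)^2 / (sx * sy)
  r2 <- pmin(pmax(r2, 0), 1)
  if (isTRUE(cfg$sqrt_coherence)) r2 <- sqrt(r2)
  structure(
    list(times = (seq_len(n) - 1) / fs,
         freqs = wx$freqs, scales = scales,
         coherence = t(r2),
         coi_mask = coi_mask(n, fs, scales, cfg$coi_efold),
         fs = fs, cfg = cfg),
    class = "wtc_map"
  )
}

#' @export
print.wtc_map <- function(x, ...) {
  cat(sprintf(
    "<wtc_map> %d scales (%.3g-%.3g Hz) x %d samples @ %g Hz; %.0f%% cells usable\n",
    length(x$scales), min(x$freqs), max(x$freqs), length(x$times), x$fs,
    100 * mean(x$coi_mask)))
  invisible(x)
}

#' Frequency limits of a named synchrony band
#'
#' `lf` and `hf` are the conventional low- (0.05-0.15 Hz) and
#' high-frequency (0.15-0.4 Hz) heart-rate-variability bands; `full` spans
#' the whole map.
#'
#' @param band `"full"`, `"lf"`, `"hf"`, or a numeric `c(low, high)` in Hz.
#' @param map Optional `wtc_map` used to resolve `"full"`.
#' @return Numeric vector `c(low, high)` in Hz.
#' @export
synchrony_band <- function(band, map = NULL) {
  if (is.numeric(band)) {
    stopifnot(length(band) == 2L, band[1] < band[2])
    return(band)
  }
  switch(match.arg(band, c("full", "lf", "hf")),
    lf = c(0.05, 0.15),
    hf = c(0.15, 0.4),
    full = {
      if (is.null(map)) stop("`full` band needs a map to resolve its range")
      range(map$freqs)
    })
}

#' Average a coherence map over time and frequency
#'
#' Averages coherence across all usable cells (inside the record, outside
#' the cone of influence) whose equivalent Fourier frequency falls in the
#' requested band, yielding a single synchrony scalar per dyad, channel and
#' video.
#'
#' @param map A `wtc_map`.
#' @param band `"full"`, `"lf"`, `"hf"`, or numeric `c(low, high)` Hz.
#' @return A list of class `synchrony_scalar` with `value` (a.u. in
#'   `[0, 1]`), `band`, `band_hz`, `n_cells`, and `method = "wtc"`.
#' @export
average_synchrony <- function(map, band = "full") {
  stopifnot(inherits(map, "wtc_map"))
  bh <- synchrony_band(band, map)
  sel <- map$freqs >= bh[1] & map$freqs <= bh[2]
  if (!any(sel)) {
    stop(sprintf("band [%g, %g] Hz lies outside the map range [%g, %g] Hz",
                 bh[1], bh[2], min(map$freqs), max(map$freqs)))
  }
  use <- map$coi_mask[sel, , drop = FALSE]
  vals <- map$coherence[sel, , drop = FALSE][use]
  if (length(vals) == 0L) stop("no usable cells in the requested band")
  structure(
    list(value = mean(vals),
         band = if (is.character(band)) band else "custom",
         band_hz = bh, n_cells = length(vals), method = "wtc"),
    class = "synchrony_scalar"
  )
}

#' @export
print.synchrony_scalar <- function(x, ...) {
  cat(sprintf("<synchrony_scalar> %s band [%g, %g] Hz: %.4f a.u. (%s, %d cells)\n",
              x$band, x$band_hz[1], x$band_hz[2], x$value, x$method,
              x$n_cells))
  invisible(x)
}

#' Correlational synchrony between two signals
#'
#' Stationarity-assuming alternatives to wavelet coherence: the absolute
#' global Pearson correlation, or the mean absolute Pearson correlation
#' over non-overlapping windows.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"global_pearson"` or `"windowed_abs_r"`.
#' @param window_s Window length in seconds for the windowed method.
#' @param fs Sampling rate in Hz (needed for the windowed method).
#' @return A `synchrony_scalar` with `method = "correlation"`; for the
#'   windowed method, `n_skipped` counts zero-variance windows excluded
#'   from the mean.
#' @export
correlation_synchrony <- function(x, y,
                                  method = c("global_pearson", "windowed_abs_r"),
                                  window_s = 30, fs = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (method == "global_pearson") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("correlation undefined for a constant input")
    }
    val <- abs(stats::cor(x, y))
    return(structure(list(value = val, band = "full", band_hz = c(NA, NA),
                          n_cells = length(x), method = "correlation",
                          n_skipped = 0L),
                     class = "synchrony_scalar"))
  }
  if (is.null(fs)) stop("`fs` is required for windowed correlation")
  w <- floor(window_s * fs)
  if (w < 3) stop("`window_s` too short for the sampling rate")
  nw <- floor(length(x) / w)
  if (nw < 1) stop("signal shorter than one window")
  rs <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nw)) {
    idx <- ((i - 1) * w + 1):(i * w)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) {
      skipped <- skipped + 1L
    } else {
      rs <- c(rs, abs(stats::cor(x[idx], y[idx])))
    }
  }
  if (length(rs) == 0L) stop("all windows degenerate (zero variance)")
  structure(list(value = mean(rs), band = "full", band_hz = c(NA, NA),
                 n_cells = length(rs), method = "correlation",
                 n_skipped = skipped),
            class = "synchrony_scalar")
}
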