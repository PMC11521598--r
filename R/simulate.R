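#' Configuration for the synthetic dyad generator
#'
#' Defaults emulate 5-minute video epochs with resting cardiac, respiratory
#' and electrodermal levels typical of seated young adults: mean inter-beat
#' interval 800 ms (modulated by valence condition via
#' [apply_valence_effects()]), respiratory rate ~20 breaths/min, skin
#' conductance level ~5 uS, and a few spontaneous skin conductance
#' responses per minute. `coupling` in `[0, 1]` controls how much of each
#' member's latent arousal driver is shared within the dyad; the default 0
#' reproduces uncoupled members (no interpersonal alignment beyond the
#' common stimulus structure).
#'
#' @param duration_s Epoch duration in seconds (default 300).
#' @param fs_ecg,fs_rsp,fs_sc Sampling rates in Hz (ECG 1000 for
#'   millisecond R-peak accuracy; respiration and skin conductance 100,
#'   ample for sub-5-Hz content).
#' @param mean_ibi_ms Mean inter-beat interval in ms (default 800).
#' @param ibi_sd_ms SD of the inter-beat-interval fluctuation in ms
#'   (default 40); also the gain, in ms per unit driver, with which latent
#'   arousal shortens the IBI.
#' @param rsp_rate_bpm Respiratory rate in breaths/min (default 19.9).
#' @param sc_tonic_level_us Tonic skin conductance level in uS (default 4.8).
#' @param scr_rate_per_min Spontaneous skin-conductance-response rate per
#'   minute (default 4).
#' @param coupling Inter-member driver mixing weight in `[0, 1]` (default 0).
#' @param valence_condition `"negative"`, `"neutral"` or `"positive"`.
#' @param attention `"joint"` or `"disjoint"`.
#' @param seed Integer master seed; all channel and member substreams are
#'   derived deterministically from it.
#' @return A list of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(duration_s = 300,
                            fs_ecg = 1000, fs_rsp = 100, fs_sc = 100,
                            mean_ibi_ms = 800, ibi_sd_ms = 40,
                            rsp_rate_bpm = 19.9,
                            sc_tonic_level_us = 4.8,
                            scr_rate_per_min = 4,
                            coupling = 0,
                            valence_condition = c("neutral", "negative", "positive"),
                            attention = c("joint", "disjoint"),
                            seed = 1L) {
  valence_condition <- match.arg(valence_condition)
  attention <- match.arg(attention)
  if (coupling < 0 || coupling > 1) stop("`coupling` must lie in [0, 1]")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (mean_ibi_ms <= 0) stop("`mean_ibi_ms` must be positive")
  if (ibi_sd_ms < 0) stop("`ibi_sd_ms` must be non-negative")
  if (rsp_rate_bpm <= 5 || rsp_rate_bpm >= 60) {
    stop("`rsp_rate_bpm` must lie in (5, 60)")
  }
  if (sc_tonic_level_us <= 0) stop("`sc_tonic_level_us` must be positive")
  if (scr_rate_per_min < 0) stop("`scr_rate_per_min` must be >= 0")
  for (f in c(fs_ecg, fs_rsp, fs_sc)) {
    if (f <= 0) stop("sampling rates must be positive")
  }
  structure(
    list(duration_s = duration_s, fs_ecg = fs_ecg, fs_rsp = fs_rsp,
         fs_sc = fs_sc, mean_ibi_ms = mean_ibi_ms, ibi_sd_ms = ibi_sd_ms,
         rsp_rate_bpm = rsp_rate_bpm, sc_tonic_level_us = sc_tonic_level_us,
         scr_rate_per_min = scr_rate_per_min, coupling = coupling,
         valence_condition = valence_condition, attention = attention,
         seed = as.integer(seed)),
    class = "dyad_sim_config"
  )
}

#' Apply valence-condition offsets to a generator configuration
#'
#' Shifts the autonomic set points by the emotional condition: arousing
#' (positive/negative) videos lengthen the mean IBI slightly, raise the
#' respiratory rate, and raise the skin conductance level, in line with
#' typical group-level responses to emotion-eliciting film clips.
#'
#' @param config A [dyad_sim_config()].
#' @return The configuration with condition-adjusted physiological levels.
#' @export
apply_valence_effects <- function(config) {
  stopifnot(inherits(config, "dyad_sim_config"))
  off <- switch(config$valence_condition,
    neutral  = c(ibi = -12, rsp = 0,   sc = 0),
    negative = c(ibi = 8,   rsp = 1.0, sc = 1.9),
    positive = c(ibi = 5,   rsp = 2.1, sc = 3.4))
  config$mean_ibi_ms <- config$mean_ibi_ms + off[["ibi"]]
  config$rsp_rate_bpm <- config$rsp_rate_bpm + off[["rsp"]]
  config$sc_tonic_level_us <- config$sc_tonic_level_us + off[["sc"]]
  config
}

# Deterministic substream seed derived from a master seed and a key string;
# stays below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

#' Band-limited Gaussian latent arousal driver
#'
#' White Gaussian noise restricted to a frequency band by hard spectral
#' masking, standardized to zero mean and unit variance. One common driver
#' per dyad and video plus one idiosyncratic driver per member stand in for
#' the stimulus-locked emotional response; a member's driver is the mixture
#' `coupling * common + (1 - coupling) * idiosyncratic` (components
#' standardized before mixing), restandardized to unit variance.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz (default 4; the band of interest is below
#'   0.4 Hz).
#' @param band Passband in Hz (default `c(0.01, 0.4)`).
#' @param seed Integer seed.
#' @return A list with `t` (s), `a` (unit-variance driver), `fs`.
#' @export
make_driver <- function(duration_s, fs = 4, band = c(0.01, 0.4), seed = 1L) {
  set.seed(seed)
  n <- max(64L, ceiling(duration_s * fs) + 1L)
  z <- stats::rnorm(n)
  fz <- stats::fft(z)
  freq <- seq(0, n - 1) / n * fs
  freq <- pmin(freq, fs - freq)  # two-sided
  keep <- freq >= band[1] & freq <= band[2]
  fz[!keep] <- 0
  a <- Re(stats::fft(fz, inverse = TRUE)) / n
  a <- (a - mean(a)) / stats::sd(a)
  list(t = (seq_len(n) - 1) / fs, a = a, fs = fs)
}

# Mix a common and an idiosyncratic driver with weight `coupling`,
# restandardizing the mixture (correlation structure is unaffected).
mix_drivers <- function(common, idio, coupling) {
  a <- coupling * common$a + (1 - coupling) * idio$a
  s <- stats::sd(a)
  if (s > 0) a <- (a - mean(a)) / s
  list(t = common$t, a = a, fs = common$fs)
}

driver_at <- function(driver, t) {
  stats::approx(driver$t, driver$a, xout = t, rule = 2)$y
}

#' Simulate an inter-beat-interval process driven by latent arousal
#'
#' The instantaneous IBI is `mean_ibi_ms - ibi_sd_ms * a(t)`: higher
#' arousal shortens the interval (gain = `ibi_sd_ms` ms per unit driver).
#' Because the driver is band-limited to 0.01-0.4 Hz, the IBI fluctuation
#' power falls almost entirely inside the analysed 0.04-0.4 Hz band. Beats
#' are laid down sequentially from time 0.
#'
#' @param config A [dyad_sim_config()].
#' @param driver A driver as returned by [make_driver()] (or a mixture);
#'   if `NULL`, one is derived from `config$seed`.
#' @return An `ibi_series` (see [build_ibi()]) with the generating truth
#'   attached as attribute `truth` (instantaneous IBI at each beat).
#' @export
simulate_ibi_process <- function(config, driver = NULL) {
  stopifnot(inherits(config, "dyad_sim_config"))
  if (is.null(driver)) {
    driver <- make_driver(config$duration_s, seed = derive_seed(config$seed, "ibi"))
  }
  tmax <- config$duration_s
  peaks <- numeric(ceiling(tmax / (config$mean_ibi_ms / 1000)) + 8L)
  ibis <- numeric(length(peaks))
  # first beat half an interval in, so no QRS is clipped at the record edge
  t <- config$mean_ibi_ms / 2000
  k <- 0L
  while (t <= tmax) {
    k <- k + 1L
    peaks[k] <- t
    ibi <- config$mean_ibi_ms - config$ibi_sd_ms * driver_at(driver, t)
    if (ibi <= 0) {
      stop("non-positive instantaneous IBI; reduce `ibi_sd_ms` relative to `mean_ibi_ms`")
    }
    ibis[k] <- ibi
    t <- t + ibi / 1000
  }
  peaks <- peaks[seq_len(k)]
  out <- build_ibi(peaks)
  attr(out, "truth") <- list(instantaneous_ibi_ms = ibis[seq_len(k)],
                             driver = driver)
  out
}

#' Synthesize an ECG waveform with known R-peak times
#'
#' Places a biphasic Mexican-hat-like QRS pulse (80 ms support, 1 mV peak)
#' at each beat time and adds white measurement noise, so that R-peak
#' detection can be scored against exact ground truth.
#'
#' @param ibi An `ibi_series` (its `peak_times` are the ground truth) or a
#'   numeric vector of peak times in seconds.
#' @param fs Sampling rate in Hz (>= 100, so the 80 ms pulse is resolved).
#' @param noise_sd Noise SD in mV (default 0).
#' @param seed Integer seed for the noise.
#' @param duration_s Optional total duration; defaults to the last peak
#'   plus one second.
#' @return A `signal_recording` (channel ECG) with attribute
#'   `truth$peak_times`.
#' @export
simulate_ecg <- function(ibi, fs = 1000, noise_sd = 0, seed = 1L,
                         duration_s = NULL) {
  peaks <- if (inherits(ibi, "ibi_series")) ibi$peak_times else as.numeric(ibi)
  if (fs < 100) {
    stop("`fs` must be >= 100 Hz to represent the 80 ms QRS template")
  }
  if (is.null(duration_s)) duration_s <- max(peaks) + 1
  n <- ceiling(duration_s * fs) + 1L
  x <- numeric(n)
  # Ricker (Mexican-hat) pulse, 80 ms total support
  sig <- 0.012
  tt <- seq(-0.04, 0.04, by = 1 / fs)
  template <- (1 - (tt / sig)^2) * exp(-tt^2 / (2 * sig^2))
  half <- (length(template) - 1L) %/% 2L
  for (p in peaks) {
    c0 <- round(p * fs) + 1L
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  out <- signal_recording(x, fs = fs, channel = "ECG")
  attr(out, "truth") <- list(peak_times = peaks)
  out
}

#' Simulate a respiration-belt trace with known expiration onsets
#'
#' A tidal-volume-like oscillation whose instantaneous rate is the
#' configured rate plus a small arousal modulation (1 breath/min per unit
#' driver). Expiration onsets (local maxima of chest circumference) are
#' returned as ground truth.
#'
#' @param config A [dyad_sim_config()].
#' @param driver Optional latent driver; derived from `config$seed` if
#'   `NULL`.
#' @param rate_gain_bpm Arousal-to-rate gain in breaths/min per unit driver
#'   (default 1).
#' @param amplitude_mcv Oscillation amplitude in microvolts (default 200).
#' @param noise_sd_mcv Measurement noise SD (default 5).
#' @return A `signal_recording` (channel RSP) with attribute
#'   `truth$expiration_onsets` (s).
#' @export
simulate_respiration <- function(config, driver = NULL, rate_gain_bpm = 1,
                                 amplitude_mcv = 200, noise_sd_mcv = 5) {
  stopifnot(inherits(config, "dyad_sim_config"))
  if (is.null(driver)) {
    driver <- make_driver(config$duration_s, seed = derive_seed(config$seed, "rsp"))
  }
  fs <- config$fs_rsp
  n <- ceiling(config$duration_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  rate_hz <- (config$rsp_rate_bpm + rate_gain_bpm * driver_at(driver, t)) / 60
  rate_hz <- pmax(rate_hz, 1e-3)
  phase <- cumsum(rate_hz) / fs  # cycles
  x <- amplitude_mcv * sin(2 * pi * phase)
  set.seed(derive_seed(config$seed, "rspnoise"))
  x <- x + stats::rnorm(n, sd = noise_sd_mcv)
  # ground-truth onsets: phase = 0.25 + k (maxima of the sine)
  kmax <- floor(max(phase) - 0.25)
  onsets <- if (kmax >= 0) {
    vapply(0:kmax, function(k) {
      i <- which(phase >= 0.25 + k)[1]
      if (i == 1L) return(t[1])
      # linear interpolation of the crossing time
      t[i - 1] + (0.25 + k - phase[i - 1]) / (phase[i] - phase[i - 1]) / fs
    }, numeric(1))
  } else numeric(0)
  out <- signal_recording(x, fs = fs, channel = "RSP")
  attr(out, "truth") <- list(expiration_onsets = onsets,
                             rate_per_min = length(onsets) / (config$duration_s / 60))
  out
}

# Two-exponential skin-conductance-response kernel (rise 0.75 s, decay 2 s),
# normalized to unit peak.
scr_kernel <- function(fs, rise = 0.75, decay = 2, support_s = 12) {
  tt <- seq(0, support_s, by = 1 / fs)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

#' Simulate a skin conductance trace with known SCR events
#'
#' Tonic level plus slow drift, plus discrete skin conductance responses
#' drawn from an arousal-modulated Poisson process and convolved with a
#' two-exponential kernel (rise 0.75 s, decay 2 s).
#'
#' @param config A [dyad_sim_config()].
#' @param driver Optional latent driver; derived from `config$seed` if
#'   `NULL`.
#' @param seed Seed for event placement and noise; defaults to the config
#'   master seed.
#' @param scr_amp_us Mean SCR amplitude in uS (default 0.4).
#' @param drift_amp_us Amplitude of the slow tonic drift (default 0.15).
#' @return A `signal_recording` (channel SC, uS) with attribute
#'   `truth$scr_times` (s).
#' @export
simulate_sc <- function(config, driver = NULL, seed = NULL,
                        scr_amp_us = 0.4, drift_amp_us = 0.15) {
  stopifnot(inherits(config, "dyad_sim_config"))
  if (is.null(driver)) {
    driver <- make_driver(config$duration_s, seed = derive_seed(config$seed, "sc"))
  }
  if (is.null(seed)) seed <- derive_seed(config$seed, "scevents")
  fs <- config$fs_sc
  n <- ceiling(config$duration_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  tonic <- config$sc_tonic_level_us +
    drift_amp_us * sin(2 * pi * 0.003 * t + 1)
  set.seed(seed)
  base_rate <- config$scr_rate_per_min / 60  # events/s
  events <- numeric(0)
  if (base_rate > 0) {
    # inhomogeneous Poisson by thinning; arousal raises the event rate
    lam_max <- base_rate * exp(1.5)
    tc <- 0
    while (TRUE) {
      tc <- tc + stats::rexp(1, lam_max)
      if (tc > config$duration_s) break
      lam <- base_rate * exp(pmin(1.5, 0.5 * driver_at(driver, tc)))
      if (stats::runif(1) < lam / lam_max) events <- c(events, tc)
    }
  }
  x <- tonic
  if (length(events) > 0) {
    kern <- scr_kernel(fs)
    amps <- scr_amp_us * stats::rlnorm(length(events), 0, 0.3)
    for (i in seq_along(events)) {
      i0 <- round(events[i] * fs) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      x[idx] <- x[idx] + amps[i] * kern[seq_along(idx)]
    }
  }
  out <- signal_recording(x, fs = fs, channel = "SC")
  attr(out, "truth") <- list(scr_times = events)
  out
}

#' Default rating-model parameters
#'
#' Latent means per valence condition for the 9-point SAM valence and
#' arousal scales and the 7-point connectedness items, noise SDs, and the
#' structural coefficient linking latent arousal to connectedness under
#' joint attention.
#'
#' @param connect_arousal_slope Latent connectedness gain per unit of
#'   (centred) latent arousal under joint attention (default 0.6; 0 under
#'   disjoint attention).
#' @return A list of rating-model parameters.
#' @export
rating_effect_params <- function(connect_arousal_slope = 0.6) {
  list(
    valence_means = c(negative = 2.2, neutral = 5.2, positive = 7.9),
    arousal_means = c(negative = 6.1, neutral = 3.0, positive = 7.3),
    connect_means = c(negative = 3.9, neutral = 3.0, positive = 3.9),
    ident_t0_mean = 2.5, desire_t0_mean = 4.2,
    bonding_gain = 0.4,
    connect_arousal_slope = connect_arousal_slope,
    connect_arousal_slope_disjoint = 0,
    noise_sd = c(valence = 0.8, arousal = 1.2, connect = 0.7,
                 item = 0.4, ident = 0.8, desire = 0.8)
  )
}

clip_likert <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Generate Likert ratings for one dyad session
#'
#' Latent Gaussian variables are rounded and clipped to their scale bounds:
#' 9-point valence/arousal per member and video, four 7-point connectedness
#' items per member and video (averaged into the member's connectedness
#' score), one 7-point identification item and seven 7-point desire items
#' at t0 and t1. Latent connectedness increases with centred latent arousal
#' under joint attention (slope `connect_arousal_slope`), and t1 social
#' attitudes increase with the member's mean connectedness (gain
#' `bonding_gain`). All latent values and generating coefficients are
#' retained in `truth` for recovery tests.
#'
#' @param valences Character vector (length 3) of video valence conditions
#'   in presentation order.
#' @param attention `"joint"` or `"disjoint"`.
#' @param effect_params See [rating_effect_params()].
#' @param seed Integer seed.
#' @return A list with `ratings` (data frame: member, video, valence,
#'   valence_rating, arousal_rating, connectedness), `attitudes` (data
#'   frame: member, time, identification, desire), and `truth`.
#' @export
simulate_ratings <- function(valences, attention = "joint",
                             effect_params = rating_effect_params(),
                             seed = 1L) {
  stopifnot(length(valences) == 3L,
            all(valences %in% c("negative", "neutral", "positive")))
  p <- effect_params
  set.seed(seed)
  joint <- attention == "joint"
  slope <- if (joint) p$connect_arousal_slope else p$connect_arousal_slope_disjoint
  arousal_center <- mean(p$arousal_means)
  rows <- list()
  connect_latents <- matrix(0, nrow = 2, ncol = 3)
  for (m in 1:2) {
    for (v in 1:3) {
      cond <- valences[v]
      val_lat <- p$valence_means[[cond]] + stats::rnorm(1, sd = p$noise_sd[["valence"]])
      aro_lat <- p$arousal_means[[cond]] + stats::rnorm(1, sd = p$noise_sd[["arousal"]])
      con_lat <- p$connect_means[[cond]] +
        slope * (aro_lat - arousal_center) +
        stats::rnorm(1, sd = p$noise_sd[["connect"]])
      items <- clip_likert(con_lat + stats::rnorm(4, sd = p$noise_sd[["item"]]), 1, 7)
      connect_latents[m, v] <- con_lat
      rows[[length(rows) + 1L]] <- data.frame(
        member = m, video = v, valence = cond,
        valence_rating = clip_likert(val_lat, 1, 9),
        arousal_rating = clip_likert(aro_lat, 1, 9),
        connectedness = mean(items),
        arousal_latent = aro_lat, connect_latent = con_lat)
    }
  }
  ratings <- do.call(rbind, rows)
  att <- list()
  for (m in 1:2) {
    ident0_lat <- p$ident_t0_mean + stats::rnorm(1, sd = p$noise_sd[["ident"]])
    desire0_lat <- p$desire_t0_mean + stats::rnorm(1, sd = p$noise_sd[["desire"]])
    bond <- p$bonding_gain * (mean(connect_latents[m, ]) - p$connect_means[["neutral"]])
    ident1_lat <- ident0_lat + bond + stats::rnorm(1, sd = 0.3)
    desire1_lat <- desire0_lat + bond + stats::rnorm(1, sd = 0.3)
    att[[length(att) + 1L]] <- data.frame(
      member = m, time = c("t0", "t1"),
      identification = c(clip_likert(ident0_lat, 1, 7),
                         clip_likert(ident1_lat, 1, 7)),
      desire = c(mean(clip_likert(desire0_lat + stats::rnorm(7, sd = p$noise_sd[["item"]]), 1, 7)),
                 mean(clip_likert(desire1_lat + stats::rnorm(7, sd = p$noise_sd[["item"]]), 1, 7))))
  }
  list(ratings = ratings, attitudes = do.call(rbind, att),
       truth = list(effect_params = p, attention = attention,
                    connect_latents = connect_latents))
}

#' Simulate a complete dyad session
#'
#' Two members watch three videos (one per valence condition, order
#' determined by the seed). Per video, one common latent arousal driver is
#' mixed with each member's idiosyncratic driver according to `coupling`;
#' the mixed driver modulates that member's IBI process, respiration rate
#' and SCR rate. Ratings are generated by [simulate_ratings()]. All ground
#' truth (drivers, R-peak times, expiration onsets, SCR events, latent
#' rating coefficients) is retained.
#'
#' @param config A [dyad_sim_config()]; its `valence_condition` field is
#'   ignored here (all three conditions are presented).
#' @param effect_params Rating-model parameters
#'   ([rating_effect_params()]).
#' @param channels Character subset of `c("ecg", "rsp", "sc")` to
#'   synthesize (all by default); trimming channels speeds up large
#'   Monte-Carlo designs.
#' @return A list of class `dyad_session`: `config`, `video_order`
#'   (valences in presentation order), `members` (per member, per video:
#'   recordings, `ibi`, driver), `ratings`, `attitudes`, `truth`.
#' @export
simulate_dyad_session <- function(config = dyad_sim_config(),
                                  effect_params = rating_effect_params(),
                                  channels = c("ecg", "rsp", "sc")) {
  stopifnot(inherits(config, "dyad_sim_config"))
  channels <- match.arg(channels, several.ok = TRUE)
  set.seed(derive_seed(config$seed, "order"))
  video_order <- sample(c("negative", "neutral", "positive"))
  members <- list(list(videos = list()), list(videos = list()))
  drivers <- list()
  for (v in 1:3) {
    vc <- video_order[v]
    common <- make_driver(config$duration_s,
                          seed = derive_seed(config$seed, "common", v))
    for (m in 1:2) {
      idio <- make_driver(config$duration_s,
                          seed = derive_seed(config$seed, "idio", m, v))
      drv <- mix_drivers(common, idio, config$coupling)
      vcfg <- config
      vcfg$valence_condition <- vc
      vcfg <- apply_valence_effects(vcfg)
      vid <- list(valence = vc, driver = drv)
      if ("ecg" %in% channels) {
        ibi <- simulate_ibi_process(vcfg, drv)
        vid$ibi <- ibi
        vid$ecg <- simulate_ecg(ibi, fs = config$fs_ecg, noise_sd = 0.02,
                                seed = derive_seed(config$seed, "ecgnoise", m, v),
                                duration_s = config$duration_s)
      }
      if ("rsp" %in% channels) {
        rcfg <- vcfg
        rcfg$seed <- derive_seed(config$seed, "rspseed", m, v)
        vid$rsp <- simulate_respiration(rcfg, drv)
      }
      if ("sc" %in% channels) {
        vid$sc <- simulate_sc(vcfg, drv,
                              seed = derive_seed(config$seed, "scseed", m, v))
      }
      members[[m]]$videos[[v]] <- vid
    }
    drivers[[v]] <- common
  }
  rat <- simulate_ratings(video_order, attention = config$attention,
                          effect_params = effect_params,
                          seed = derive_seed(config$seed, "ratings"))
  structure(
    list(config = config, video_order = video_order, members = members,
         ratings = rat$ratings, attitudes = rat$attitudes,
         truth = list(common_drivers = drivers, rating = rat$truth)),
    class = "dyad_session"
  )
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session> coupling=%.2f, %s attention, videos: %s\n",
              x$config$coupling, x$config$attention,
              paste(x$video_order, collapse = ", ")))
  invisible(x)
}

#' Write a dyad session to a directory
#'
#' Writes `member{1,2}_video{1,2,3}_{ecg|rsp|sc}.csv` in the package CSV
#' dialect, `ratings.csv`, and `session.json` (metadata including
#' condition, order and ground-truth event times).
#'
#' @param session A `dyad_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "dyad_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (m in 1:2) {
    for (v in 1:3) {
      vid <- session$members[[m]]$videos[[v]]
      key <- sprintf("member%d_video%d", m, v)
      for (ch in c("ecg", "rsp", "sc")) {
        if (!is.null(vid[[ch]])) {
          write_signal_csv(vid[[ch]], file.path(dir, sprintf("%s_%s.csv", key, ch)))
        }
      }
      truth[[key]] <- list(
        valence = vid$valence,
        r_peaks_s = if (!is.null(vid$ibi)) vid$ibi$peak_times,
        expiration_onsets_s = if (!is.null(vid$rsp)) attr(vid$rsp, "truth")$expiration_onsets,
        scr_times_s = if (!is.null(vid$sc)) attr(vid$sc, "truth")$scr_times)
    }
  }
  utils::write.csv(session$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  utils::write.csv(session$attitudes, file.path(dir, "attitudes.csv"),
                   row.names = FALSE)
  meta <- list(
    attention = session$config$attention,
    coupling = session$config$coupling,
    seed = session$config$seed,
    duration_s = session$config$duration_s,
    video_order = session$video_order,
    fs = list(ecg = session$config$fs_ecg, rsp = session$config$fs_rsp,
              sc = session$config$fs_sc),
    truth = truth)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
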