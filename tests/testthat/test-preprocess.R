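test_that("band-pass filter rejects DC and passes/stops the right bands", {
  fs <- 1000
  rec <- signal_recording(rep(1, 20 * fs), fs, "ECG")
  out <- bandpass(rec, 1, 100, order = 4)
  expect_lt(abs(mean(out$samples)), 1e-6)

  fs <- 20
  t <- seq(0, 600, by = 1 / fs)
  inband <- signal_recording(sin(2 * pi * 0.2 * t), fs, "ECG", units = "ms")
  amp <- sine_amplitude(bandpass(inband, 0.04, 0.4, 4)$samples, 0.2, fs,
                        trim_s = 60)
  expect_gt(amp, 0.95)

  outband <- signal_recording(sin(2 * pi * 5 * t), fs, "ECG", units = "ms")
  amp5 <- sine_amplitude(bandpass(outband, 0.04, 0.4, 4)$samples, 5, fs,
                         trim_s = 60)
  expect_lt(amp5, 0.01)

  expect_error(bandpass(inband, 0.1, 15, 4), "Nyquist")
  expect_error(bandpass(inband, 0, 1, 4), "positive")
})

test_that("filtering a passband-confined signal barely changes its RMS", {
  fs <- 20
  t <- seq(0, 600, by = 1 / fs)
  x <- sin(2 * pi * 0.1 * t) + 0.5 * sin(2 * pi * 0.25 * t + 1)
  rec <- signal_recording(x, fs, "ECG", units = "ms")
  y <- bandpass(rec, 0.04, 0.4, 4)$samples
  mid <- (60 * fs):(length(x) - 60 * fs)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(y[mid]) / rms(x[mid]) - 1), 0.05)
})

test_that("R-peak detection recovers noiseless synthetic beats exactly", {
  cfg <- dyad_sim_config(duration_s = 60, mean_ibi_ms = 800, ibi_sd_ms = 40,
                         seed = 3)
  ibi <- simulate_ibi_process(cfg)
  ecg <- simulate_ecg(ibi, fs = 1000, noise_sd = 0)
  truth <- attr(ecg, "truth")$peak_times
  pk <- detect_r_peaks(bandpass(ecg, 1, 100, 4))
  expect_length(pk, length(truth))
  expect_lt(max(abs(sort(pk) - sort(truth))), 0.002)
  # detected IBIs match generating IBIs beat for beat
  det <- build_ibi(pk)
  expect_lt(max(abs(det$ibis_ms - ibi$ibis_ms)), 2)
})

test_that("R-peak detection stays accurate under heavy noise", {
  cfg <- dyad_sim_config(duration_s = 60, seed = 3)
  ibi <- simulate_ibi_process(cfg)
  truth <- attr(simulate_ecg(ibi, fs = 1000), "truth")$peak_times
  # 10 dB peak signal-to-noise: noise SD = 1 mV / 10^(10/20)
  ecg <- simulate_ecg(ibi, fs = 1000, noise_sd = 10^(-0.5), seed = 21)
  pk <- detect_r_peaks(bandpass(ecg, 1, 100, 4))
  hits <- sapply(truth, function(p) min(abs(pk - p)) < 0.010)
  claimed <- sapply(pk, function(p) min(abs(truth - p)) < 0.010)
  expect_gte(mean(hits), 0.97)
  expect_gte(mean(claimed), 0.97)
})

test_that("degenerate ECG inputs raise explicit errors", {
  flat <- signal_recording(rep(0, 10000), 1000, "ECG")
  expect_error(detect_r_peaks(flat), "no QRS template")
  short <- signal_recording(rnorm(1000), 1000, "ECG")
  expect_error(detect_r_peaks(short), "5 s")
})

test_that("IBI construction reproduces intervals and spectral content", {
  ibi <- build_ibi(c(0, 0.8, 1.6, 2.4))
  expect_equal(ibi$ibis_ms, c(800, 800, 800))
  expect_equal(ibi$mean_ibi_ms, 800)
  expect_equal(60000 / ibi$mean_ibi_ms, 75)  # 75 bpm heart rate
  expect_error(build_ibi(c(0, 0.8)), "3 R-peaks")
  expect_error(build_ibi(c(0, 0.8, 0.7)), "increasing")

  # sinusoidal IBI modulation at 0.1 Hz dominates the 20 Hz trace spectrum
  t <- 0
  peaks <- numeric(0)
  while (t < 120) { peaks <- c(peaks, t); t <- t + (0.8 + 0.05 * sin(2 * pi * 0.1 * t)) }
  tr <- build_ibi(peaks)
  spec <- stats::spec.pgram(stats::ts(tr$interp_trace, frequency = 20),
                            plot = FALSE, taper = 0)
  fpeak <- spec$freq[which.max(spec$spec)]
  expect_lt(abs(fpeak - 0.1), 0.01)
})

test_that("expiration detection counts one onset per breathing cycle", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  rsp <- signal_recording(sin(2 * pi * 0.35 * t), fs, "RSP")
  det <- detect_expirations(rsp)
  expect_lte(abs(length(det$onset_times) - 21), 1)
  expect_error(detect_expirations(signal_recording(rep(1, 60 * fs), fs, "RSP")),
               "flat")
  expect_error(detect_expirations(signal_recording(sin(t[1:500]), fs, "RSP")),
               "30 s")
})

test_that("generator respiratory rate is recovered within half a breath", {
  for (s in 1:5) {
    cfg <- dyad_sim_config(duration_s = 120, rsp_rate_bpm = 20, seed = s)
    rsp <- simulate_respiration(cfg)
    det <- detect_expirations(rsp)
    expect_lt(abs(det$rate_per_min - 20), 0.5)
  }
})

test_that("phasic extraction removes slow drift and keeps SCR timing", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  drift <- signal_recording(5 + 2 * t / max(t), fs, "SC")
  ph <- extract_phasic_sc(drift)
  expect_lt(abs(mean(ph$samples)), 0.01 * 2)  # < 1% of the drift span
  expect_error(extract_phasic_sc(signal_recording(t, fs, "RSP")), "SC")

  zero <- extract_phasic_sc(signal_recording(rep(0, length(t)), fs, "SC"))
  expect_lt(max(abs(zero$samples)), 1e-12)

  kern <- dyadsync:::scr_kernel(fs)
  x <- rep(0, length(t))
  i0 <- 10 * fs + 1
  x[i0:(i0 + length(kern) - 1)] <- 0.5 * kern
  ph <- extract_phasic_sc(signal_recording(5 + x, fs, "SC"))
  tpeak_true <- (i0 - 1 + which.max(kern) - 1) / fs
  tpeak_est <- (which.max(ph$samples) - 1) / fs
  expect_lt(abs(tpeak_est - tpeak_true), 0.5)
})

test_that("respiration artifact rules fire exactly at their boundaries", {
  fs <- 10
  n <- 300 * fs
  clean <- function(seed) {
    set.seed(seed)
    signal_recording(sin(2 * pi * 0.33 * (1:n) / fs) + rnorm(n, sd = 0.1),
                     fs, "RSP")
  }
  with_null_run <- function(seed, run_s) {
    r <- clean(seed)
    r$samples[1000:(1000 + run_s * fs - 1)] <- 0
    r
  }
  recs <- list(
    lapply(1:3, function(v) clean(v)),
    lapply(1:3, function(v) if (v == 2) with_null_run(10 + v, 16) else clean(10 + v)),
    lapply(1:3, function(v) if (v == 1) with_null_run(20 + v, 14) else clean(20 + v)),
    lapply(1:3, function(v) clean(30 + v))
  )
  rep <- flag_rsp_artifacts(recs)
  expect_equal(rep$rule, c("none", "rsp_null_run", "none", "none"))
  expect_equal(rep$excluded, c(FALSE, TRUE, FALSE, FALSE))

  # variance rule: one recording far noisier than the sample
  noisy <- lapply(1:3, function(v) {
    set.seed(100 + v)
    sd_v <- if (v == 2) 3 else 0.1
    signal_recording(sin(2 * pi * 0.33 * (1:n) / fs) + rnorm(n, sd = sd_v),
                     fs, "RSP")
  })
  recs2 <- c(lapply(1:6, function(p) lapply(1:3, function(v) clean(p * 10 + v))),
             list(noisy))
  rep2 <- flag_rsp_artifacts(recs2)
  expect_equal(rep2$rule[7], "rsp_variance")
  expect_true(all(rep2$rule[1:6] == "none"))

  expect_error(flag_rsp_artifacts(recs[1]), "2 participants")
})

test_that("skin conductance artifact rules respect their definitions", {
  fs <- 20
  n <- 300 * fs
  flat <- function() signal_recording(rep(5, n), fs, "SC")
  with_scrs <- function(seed) {
    cfg <- dyad_sim_config(duration_s = 300, fs_sc = fs,
                           scr_rate_per_min = 3, seed = seed)
    simulate_sc(cfg)
  }
  with_slope <- function(frac) {
    x <- rep(5, n)
    bad <- ceiling(frac * n)
    x[1:bad] <- 5 + 3 * (1:bad) / fs  # 3 uS/s ramp
    signal_recording(x, fs, "SC")
  }
  recs <- list(
    list(flat(), flat(), with_scrs(1)),        # responses in one video only
    list(flat(), flat(), flat()),              # fully unresponsive
    list(with_slope(0.06), with_scrs(2), with_scrs(3)),  # 6% bad slope
    list(with_scrs(4), with_scrs(5), with_scrs(6))       # clean
  )
  rep <- flag_sc_artifacts(recs)
  expect_equal(rep$rule, c("none", "sc_unresponsive", "sc_slope", "none"))
  expect_equal(rep$excluded, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("the 3 x IQR outlier rule matches its longhand definition", {
  # quartiles 10 and 20 -> fences at -20 and 50
  v <- c(10, 10, 10, 20, 20, 20, 49, 55, -19, -21)
  fence <- iqr_fence_oracle(v)
  mask <- flag_statistical_outliers(v)
  expect_equal(mask, v < fence[["lower"]] | v > fence[["upper"]])

  expect_equal(flag_statistical_outliers(c(5, 5, 5, 5)), rep(FALSE, 4))
  expect_equal(flag_statistical_outliers(c(5, 5, 5, 5, 7)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(flag_statistical_outliers(c(1, 2, 3)), "4 values")

  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(50) * runif(1, 0.5, 20) + runif(1, -10, 10)
    fence <- iqr_fence_oracle(x)
    expect_equal(flag_statistical_outliers(x),
                 x < fence[["lower"]] | x > fence[["upper"]])
  }
})

test_that("the outlier rule is affine-equivariant and near-silent on normal data", {
  set.seed(42)
  x <- rnorm(200)
  m <- flag_statistical_outliers(x)
  expect_identical(flag_statistical_outliers(3.7 * x - 11), m)
  expect_identical(flag_statistical_outliers(-2 * x + 5), m)
  expect_identical(flag_statistical_outliers(rev(x)), rev(m))

  set.seed(7)
  big <- rnorm(20000)
  expect_lt(mean(flag_statistical_outliers(big)), 0.001)
})
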