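test_that("identical config and seed give a bit-identical session", {
  cfg <- dyad_sim_config(duration_s = 40, seed = 11, coupling = 0.4)
  s1 <- simulate_dyad_session(cfg, channels = c("ecg", "rsp", "sc"))
  s2 <- simulate_dyad_session(cfg, channels = c("ecg", "rsp", "sc"))
  expect_identical(s1$video_order, s2$video_order)
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(s1$members[[1]]$videos[[2]]$ecg$samples,
                   s2$members[[1]]$videos[[2]]$ecg$samples)
  expect_identical(s1$members[[2]]$videos[[3]]$sc$samples,
                   s2$members[[2]]$videos[[3]]$sc$samples)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(dyad_sim_config(coupling = 1.2), "coupling")
  expect_error(dyad_sim_config(mean_ibi_ms = 0), "mean_ibi_ms")
  expect_error(dyad_sim_config(duration_s = -1), "duration_s")
  expect_error(dyad_sim_config(rsp_rate_bpm = 70), "rsp_rate_bpm")
})

test_that("zero-variance IBI process produces exactly constant intervals", {
  cfg <- dyad_sim_config(duration_s = 60, mean_ibi_ms = 800, ibi_sd_ms = 0,
                         seed = 5)
  ibi <- simulate_ibi_process(cfg)
  expect_true(all(abs(ibi$ibis_ms - 800) < 1e-9))
  expect_equal(length(ibi$peak_times), 75)
})

test_that("generated mean IBI matches the configured mean over seeds", {
  grand <- sapply(1:10, function(s) {
    cfg <- dyad_sim_config(duration_s = 120, mean_ibi_ms = 800,
                           ibi_sd_ms = 40, seed = s)
    simulate_ibi_process(cfg)$mean_ibi_ms
  })
  expect_gt(mean(grand), 790)
  expect_lt(mean(grand), 810)
})

test_that("default generator levels fall in realistic resting ranges", {
  # condition-adjusted defaults: mean IBI within 788-808 ms, respiratory
  # rate within 19.9-22.0 per min, positive-condition SC within 4.8-8.5 uS
  for (cond in c("negative", "neutral", "positive")) {
    cfg <- apply_valence_effects(dyad_sim_config(valence_condition = cond,
                                                 duration_s = 120, seed = 2))
    ibi <- simulate_ibi_process(cfg)
    expect_gte(ibi$mean_ibi_ms, 780)
    expect_lte(ibi$mean_ibi_ms, 815)
    rate <- attr(simulate_respiration(cfg), "truth")$rate_per_min
    expect_gte(rate, 19.4)
    expect_lte(rate, 22.5)
  }
  pos <- apply_valence_effects(dyad_sim_config(valence_condition = "positive",
                                               duration_s = 300, seed = 3))
  sc <- simulate_sc(pos)
  expect_gte(mean(sc$samples), 4.8)
  expect_lte(mean(sc$samples), 8.5)
})

test_that("noiseless ECG places one QRS apex per beat at the true time", {
  peaks <- c(0.5, 1.3, 2.1)
  ecg <- simulate_ecg(peaks, fs = 1000, noise_sd = 0)
  for (p in peaks) {
    i0 <- round(p * 1000) + 1
    win <- (i0 - 100):(i0 + 100)
    expect_lte(abs(win[which.max(ecg$samples[win])] - i0), 1)
  }
  expect_error(simulate_ecg(peaks, fs = 50), "fs")
})

test_that("a 60 s record at mean IBI 800 ms holds 75 +/- 1 beats", {
  cfg <- dyad_sim_config(duration_s = 60, mean_ibi_ms = 800, ibi_sd_ms = 40,
                         seed = 4)
  ibi <- simulate_ibi_process(cfg)
  expect_lte(abs(length(ibi$peak_times) - 75), 1)
})

test_that("respiration onset count tracks the configured rate", {
  for (s in 1:5) {
    cfg <- dyad_sim_config(duration_s = 120, rsp_rate_bpm = 20, seed = s)
    tr <- attr(simulate_respiration(cfg), "truth")
    expect_lte(abs(tr$rate_per_min - 20), 1)
  }
})

test_that("zero SCR rate yields an essentially flat phasic trace", {
  cfg <- dyad_sim_config(duration_s = 120, scr_rate_per_min = 0, seed = 6)
  sc <- simulate_sc(cfg, drift_amp_us = 0)
  expect_length(attr(sc, "truth")$scr_times, 0)
  phasic <- extract_phasic_sc(sc)
  expect_lt(max(abs(phasic$samples)), 1e-6)
})

test_that("SCR events are recoverable from the phasic trace", {
  cfg <- dyad_sim_config(duration_s = 300, scr_rate_per_min = 4, seed = 8)
  sc <- simulate_sc(cfg)
  truth <- attr(sc, "truth")$scr_times
  counted <- count_scrs(extract_phasic_sc(sc), min_sep_s = 2)
  expect_lte(abs(length(counted) - length(truth)),
             ceiling(0.2 * length(truth)))
})

test_that("coupling = 1 with a shared common driver makes members identical", {
  common <- dyadsync:::make_driver(120, seed = 1)
  idio1 <- dyadsync:::make_driver(120, seed = 2)
  idio2 <- dyadsync:::make_driver(120, seed = 3)
  d1 <- dyadsync:::mix_drivers(common, idio1, 1)
  d2 <- dyadsync:::mix_drivers(common, idio2, 1)
  expect_equal(d1$a, d2$a, tolerance = 1e-12)
})

test_that("coupling = 0 gives uncorrelated member drivers", {
  rs <- sapply(1:20, function(s) {
    ses <- simulate_dyad_session(dyad_sim_config(duration_s = 120,
                                                 coupling = 0, seed = s),
                                 channels = "rsp")
    cor(ses$members[[1]]$videos[[1]]$driver$a,
        ses$members[[2]]$videos[[1]]$driver$a)
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cross-member driver correlation is non-decreasing in coupling", {
  mean_r <- sapply(c(0, 0.3, 0.6, 0.9), function(cp) {
    mean(sapply(1:15, function(s) {
      common <- dyadsync:::make_driver(120, seed = s)
      i1 <- dyadsync:::make_driver(120, seed = 1000 + s)
      i2 <- dyadsync:::make_driver(120, seed = 2000 + s)
      cor(dyadsync:::mix_drivers(common, i1, cp)$a,
          dyadsync:::mix_drivers(common, i2, cp)$a)
    }))
  })
  expect_true(all(diff(mean_r) > 0))
})

test_that("ratings with zero noise hit the latent means exactly", {
  p <- rating_effect_params()
  p$noise_sd[] <- 0
  p$connect_arousal_slope <- 0
  rat <- simulate_ratings(c("neutral", "negative", "positive"),
                          attention = "joint", effect_params = p, seed = 1)
  neu <- rat$ratings[rat$ratings$valence == "neutral", ]
  expect_true(all(neu$valence_rating == round(p$valence_means[["neutral"]])))
  expect_true(all(neu$arousal_rating == round(p$arousal_means[["neutral"]])))
})

test_that("generated Likert ratings are integers within scale bounds", {
  for (s in 1:5) {
    rat <- simulate_ratings(sample(c("negative", "neutral", "positive")),
                            attention = sample(c("joint", "disjoint"), 1),
                            seed = s)
    r <- rat$ratings
    expect_true(all(r$valence_rating == round(r$valence_rating)))
    expect_true(all(r$valence_rating >= 1 & r$valence_rating <= 9))
    expect_true(all(r$arousal_rating >= 1 & r$arousal_rating <= 9))
    expect_true(all(r$connectedness >= 1 & r$connectedness <= 7))
  }
})

test_that("dyadic mean valence reproduces the latent condition ordering", {
  vals <- list(negative = c(), neutral = c(), positive = c())
  for (s in 1:25) {
    rat <- simulate_ratings(c("negative", "neutral", "positive"), seed = s)
    for (cond in names(vals)) {
      rr <- rat$ratings[rat$ratings$valence == cond, ]
      vals[[cond]] <- c(vals[[cond]],
                        dyadic_mean(rr$valence_rating[1], rr$valence_rating[2]))
    }
  }
  expect_lt(mean(vals$negative), mean(vals$neutral))
  expect_lt(mean(vals$neutral), mean(vals$positive))
})

test_that("session directories round-trip through the CSV dialect", {
  cfg <- dyad_sim_config(duration_s = 40, seed = 12)
  ses <- simulate_dyad_session(cfg)
  dir <- tempfile("ses_")
  write_session(ses, dir)
  rep <- validate_session_dir(dir)
  expect_true(rep$valid)
  back <- read_signal_csv(file.path(dir, "member1_video1_rsp.csv"), "RSP")
  expect_equal(back$fs, cfg$fs_rsp)
  expect_equal(back$samples, ses$members[[1]]$videos[[1]]$rsp$samples,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
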