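# Cached per-individual wavelet material for fast all-pairs coherence:
# the padded CWT and the smoothed, scale-normalized auto-spectrum.
wtc_individual_cache <- function(x, fs, cfg) {
  w <- cwt_morlet_padded(x, fs, cfg)
  inv_s <- matrix(1 / w$scales, nrow = w$npad, ncol = length(w$scales),
                  byrow = TRUE)
  sauto <- Re(wtc_smooth(abs(w$coef)^2 * inv_s, w$scales, fs, w$npad, cfg,
                         w$n))
  list(w = w, sauto = sauto, inv_s = inv_s)
}

# Band-averaged coherence between two cached individuals.
wtc_pair_value <- function(ca, cb, cfg, band) {
  wx <- ca$w; wy <- cb$w
  sxy <- wtc_smooth(wx$coef * Conj(wy$coef) * ca$inv_s, wx$scales, wx$fs,
                    wx$npad, cfg, wx$n)
  r2 <- Mod(sxy)^2 / (ca$sauto * cb$sauto)
  r2 <- pmin(pmax(r2, 0), 1)
  if (isTRUE(cfg$sqrt_coherence)) r2 <- sqrt(r2)
  mask <- t(coi_mask(wx$n, wx$fs, wx$scales, cfg$coi_efold))
  bh <- if (is.numeric(band)) band else switch(band,
    lf = c(0.05, 0.15), hf = c(0.15, 0.4), full = range(wx$freqs))
  sel <- wx$freqs >= bh[1] & wx$freqs <= bh[2]
  if (!any(sel)) stop("band outside the coherence map's frequency range")
  mean(r2[, sel, drop = FALSE][mask[, sel, drop = FALSE]])
}

#' Surrogate-dyad bootstrap null for interpersonal synchrony
#'
#' Tests whether real (co-present) dyads are more synchronized than
#' surrogate dyads - pairings of individuals who did not share a session.
#' All individuals must come from the same attention condition and video,
#' so every cross-dyad pairing is a valid surrogate. The test statistic is
#' `mean(real synchrony) - mean(surrogate synchrony)`; its null
#' distribution is obtained by resampling (with replacement) as many
#' values as there are real dyads from the surrogate pool, `n_boot`
#' times, and the two-sided p-value is the fraction of null differences
#' at least as extreme as the observed one (with the usual +1
#' correction).
#'
#' @param traces List of equal-length numeric vectors, one per
#'   individual, in dyad order (members of dyad k at positions
#'   `2k - 1, 2k`): the preprocessed signal to correlate (e.g. the
#'   band-passed 20 Hz IBI trace).
#' @param fs Sampling rate of the traces in Hz.
#' @param band `"full"`, `"lf"`, `"hf"`, or numeric `c(low, high)` Hz.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param cfg A [wtc_config()].
#' @return A list of class `surrogate_null`: `p`, `observed` (mean real
#'   minus mean surrogate synchrony), `real_values`, `surrogate_values`,
#'   `null` (bootstrap differences), `n_dyads`, `n_surrogate_pairs`,
#'   `seed`.
#' @export
surrogate_null <- function(traces, fs, band = "full", n_boot = 1000,
                           seed = 1L, cfg = wtc_config()) {
  n_ind <- length(traces)
  if (n_ind %% 2 != 0) stop("`traces` must hold two members per dyad")
  n_dyads <- n_ind / 2
  if (n_dyads < 3) {
    stop("need at least 3 dyads to build a surrogate pool (got ", n_dyads, ")")
  }
  lens <- lengths(traces)
  if (length(unique(lens)) != 1) {
    n <- min(lens)
    traces <- lapply(traces, function(x) x[seq_len(n)])
  }
  caches <- lapply(traces, wtc_individual_cache, fs = fs, cfg = cfg)
  dyad_of <- rep(seq_len(n_dyads), each = 2)
  real <- vapply(seq_len(n_dyads), function(k) {
    wtc_pair_value(caches[[2 * k - 1]], caches[[2 * k]], cfg, band)
  }, numeric(1))
  pairs <- utils::combn(n_ind, 2)
  cross <- dyad_of[pairs[1, ]] != dyad_of[pairs[2, ]]
  pairs <- pairs[, cross, drop = FALSE]
  surro <- vapply(seq_len(ncol(pairs)), function(j) {
    wtc_pair_value(caches[[pairs[1, j]]], caches[[pairs[2, j]]], cfg, band)
  }, numeric(1))
  observed <- mean(real) - mean(surro)
  set.seed(seed)
  null <- vapply(seq_len(n_boot), function(b) {
    mean(sample(surro, n_dyads, replace = TRUE)) - mean(surro)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_boot + 1)
  structure(
    list(p = p, observed = observed, real_values = real,
         surrogate_values = surro, null = null, n_dyads = n_dyads,
         n_surrogate_pairs = length(surro), n_boot = n_boot, seed = seed,
         band = band),
    class = "surrogate_null"
  )
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "<surrogate_null> %d real dyads vs %d surrogate pairs; mean diff %.4f, p = %.3f (%d boots)\n",
    x$n_dyads, x$n_surrogate_pairs, x$observed, x$p, x$n_boot))
  invisible(x)
}

#' Surrogate null from simulated sessions
#'
#' Convenience wrapper extracting one channel and video from a list of
#' [simulate_dyad_session()] outputs (all sharing attention condition and
#' video identity) and running [surrogate_null()] on the members' traces:
#' the 20 Hz band-passed IBI trace for `"ibi"`, the raw belt trace for
#' `"rsp"`, the phasic trace for `"sc"`.
#'
#' @param sessions List of `dyad_session` objects.
#' @param channel `"ibi"`, `"rsp"`, or `"sc"`.
#' @param video Video index (1-3).
#' @param ... Passed to [surrogate_null()].
#' @return A `surrogate_null` object.
#' @export
surrogate_null_sessions <- function(sessions, channel = c("ibi", "rsp", "sc"),
                                    video = 1, ...) {
  channel <- match.arg(channel)
  atts <- vapply(sessions, function(s) s$config$attention, character(1))
  if (length(unique(atts)) != 1) {
    stop("surrogate pairs must share the attention condition")
  }
  traces <- list()
  fs <- NULL
  for (s in sessions) {
    for (m in 1:2) {
      vid <- s$members[[m]]$videos[[video]]
      tr <- switch(channel,
        ibi = { fs <- vid$ibi$interp_fs; vid$ibi$interp_trace },
        rsp = { fs <- vid$rsp$fs; vid$rsp$samples },
        sc  = { fs <- vid$sc$fs; extract_phasic_sc(vid$sc)$samples })
      traces[[length(traces) + 1L]] <- tr
    }
  }
  surrogate_null(traces, fs = fs, ...)
}
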