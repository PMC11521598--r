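# Independent brute-force oracles used across the suite.

# Step-down Holm adjustment written out longhand.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Spearman's rho from first principles (midranks, Pearson on ranks).
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney U (number of pairs where group-1 value exceeds group-2,
# ties counted half), by exhaustive enumeration.
mwu_oracle <- function(v1, v2) {
  u <- 0
  for (a in v1) for (b in v2) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# 3 x IQR fences with type-7 quartiles written out longhand.
iqr_fence_oracle <- function(values) {
  srt <- sort(values)
  n <- length(srt)
  q_at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  q1 <- q_at(0.25); q3 <- q_at(0.75)
  c(lower = q1 - 3 * (q3 - q1), upper = q3 + 3 * (q3 - q1))
}

# Amplitude of a sinusoid of known frequency in a (possibly filtered)
# signal, by least-squares projection on sin/cos.
sine_amplitude <- function(x, f, fs, trim_s = 30) {
  n <- length(x)
  i <- seq_len(n)
  keep <- i > trim_s * fs & i <= n - trim_s * fs
  t <- (i[keep] - 1) / fs
  xk <- x[keep]
  a <- 2 * mean(xk * sin(2 * pi * f * t))
  b <- 2 * mean(xk * cos(2 * pi * f * t))
  sqrt(a^2 + b^2)
}

# Simulated random-intercept data with known fixed effects.
make_lmm_data <- function(n_groups, n_per, beta, tau, sigma2, seed,
                          n_pred = length(beta)) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  X <- matrix(rnorm(n_groups * n_per * n_pred), ncol = n_pred)
  b <- rnorm(n_groups, sd = sqrt(tau))
  y <- as.numeric(X %*% beta) + b[g] + rnorm(length(g), sd = sqrt(sigma2))
  dat <- as.data.frame(X)
  names(dat) <- paste0("x", seq_len(n_pred))
  dat$g <- factor(g)
  dat$y <- y
  dat
}

# Member 20 Hz IBI traces for one simulated dyad at a given coupling,
# produced by the generator's own driver-mixing machinery.
dyad_ibi_traces <- function(seed, coupling, duration_s = 120) {
  common <- dyadsync:::make_driver(duration_s,
                                   seed = dyadsync:::derive_seed(seed, "c"))
  lapply(1:2, function(m) {
    idio <- dyadsync:::make_driver(duration_s,
                                   seed = dyadsync:::derive_seed(seed, "i", m))
    drv <- dyadsync:::mix_drivers(common, idio, coupling)
    cfg <- dyad_sim_config(duration_s = duration_s, seed = seed)
    simulate_ibi_process(cfg, drv)$interp_trace
  })
}
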