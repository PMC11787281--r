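# Independent oracles and fixture builders used across the suite.

# Brute-force centered moving percentile (truncated windows), the oracle for
# the C++ running-quantile kernel.
brute_percentile <- function(x, window_samples, q) {
  n <- length(x)
  h <- floor(window_samples / 2)
  vapply(seq_len(n), function(i) {
    quantile(x[max(1, i - h):min(n, i + h)], q, names = FALSE)
  }, numeric(1))
}

# Dense Riemann-sum FSI oracle: samples the band-power fraction R at the
# midpoints of a fine uniform grid in the half-width u and integrates over
# the induced interval widths. Independent of the package's knot-based
# integration.
fsi_riemann <- function(freq, power, band, cells = 2^18) {
  inband <- freq >= band[1] & freq <= band[2]
  f <- freq[inband]
  p <- power[inband]
  s_l <- sum(p)
  fm <- f[which.max(p)]
  u_max <- max(fm - band[1], band[2] - fm)
  d <- abs(f - fm)
  ord <- order(d)
  ds <- d[ord]
  cp <- cumsum(p[ord])
  edges <- seq(0, u_max, length.out = cells + 1)
  mids <- (edges[-1] + edges[-(cells + 1)]) / 2
  s_mid <- cp[pmax(1L, findInterval(mids, ds))]
  s_mid[mids < ds[1]] <- 0
  omega_edges <- pmin(fm + edges, band[2]) - pmax(band[1], fm - edges)
  sum((s_mid / s_l) * diff(omega_edges)) / (band[2] - band[1])
}

# Random test spectra: uniform or heavy-tailed bin powers on a random band.
random_spectrum <- function(n_bins, heavy = FALSE) {
  f1 <- runif(1, 0.1, 2)
  f2 <- f1 + runif(1, 0.5, 10)
  freq <- seq(f1, f2, length.out = n_bins)
  power <- if (heavy) rexp(n_bins)^3 else runif(n_bins)
  tibble::tibble(freq = freq, power = power)
}

# Synthetic respiratory scalar with an injected amplitude suppression:
# constant-amplitude rectified carrier, suppression deepening linearly from
# 50% to 90% (mean 70%) over [t0, t0 + width), a 2.5x recovery breath, and
# a small one-sided noise floor.
suppressed_rms <- function(width, t0 = 60, duration = 140, fs = 60,
                           resp_freq = 0.25) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  gate <- rep(1, length(t))
  inev <- t >= t0 & t < t0 + width
  depth <- 0.5 + 0.4 * (t[inev] - t0) / width
  gate[inev] <- 1 - depth
  rec <- t >= t0 + width & t < t0 + width + 4
  gate[rec] <- 2.5 * exp(-(t[rec] - (t0 + width)) / 2)
  gate * abs(sin(2 * pi * resp_freq * t)) + abs(rnorm(length(t), 0, 0.01))
}

# Minimal component-set builder for unit tests that bypass decompose().
make_components <- function(fs, n, ...) {
  cols <- list(...)
  base <- tibble::tibble(t = (seq_len(n) - 1) / fs)
  for (nm in c("scg", "gcg", "rm_ax", "rm_ay", "rm_az",
               "rm_gx", "rm_gy", "rm_gz", "rms_acc", "rms_gyr", "bm")) {
    base[[nm]] <- cols[[nm]] %||% numeric(n)
  }
  structure(base,
            class = c("imu_components", class(tibble::tibble())),
            sample_rate = fs, subject_id = "test",
            edge_samples = c(mcg = 0, rm = 0, bm = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Epoch grid without a recording.
toy_grid <- function(n_epochs, epoch_length = 30) {
  structure(list(epoch_length = epoch_length, n_epochs = n_epochs, origin = 0),
            class = "epoch_grid")
}

# Small random recording for IO round-trips.
random_recording <- function(n = 600, fs = 60, seed = 1) {
  withr::with_seed(seed, {
    dat <- tibble::as_tibble(setNames(
      lapply(1:6, function(i) round(rnorm(n), 6)),
      c("ax", "ay", "az", "gx", "gy", "gz")))
    imu_recording(dat, subject_id = "rt", sample_rate = fs)
  })
}
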