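#' Periodogram of a signal segment
#'
#' Estimates the power spectrum of one analysis segment: the segment is
#' mean-removed, Hann-tapered and transformed once (no Welch averaging), so
#' the frequency resolution is `1/segment_length` Hz — the resolution the
#' 32 s / 64 s segment choices are built around. An all-zero segment yields
#' an all-zero spectrum flagged degenerate rather than an error, so
#' whole-night batch runs never abort.
#'
#' @param x Numeric segment.
#' @param sample_rate Sampling rate in Hz.
#' @param band Analysis band `c(F1, F2)` in Hz; the segment must be at least
#'   `2 / F1` seconds long.
#' @return Tibble of class `power_spectrum` with columns `freq`, `power`
#'   (positive frequencies only) and attributes `band`, `sample_rate`,
#'   `degenerate`.
#' @export
estimate_spectrum <- function(x, sample_rate, band) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  n <- length(x)
  if (n / sample_rate < 2 / band[1]) {
    abort(sprintf("Segment (%.1f s) shorter than 2/F1 = %.1f s.",
                  n / sample_rate, 2 / band[1]),
          class = "somnimu_data_error")
  }
  degenerate <- all(x == 0)
  xc <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann taper
  X <- fft(xc * w)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  power <- (2 / (sample_rate * sum(w^2))) * Mod(X[k + 1])^2
  structure(tibble::tibble(freq = k * sample_rate / n, power = power),
            class = c("power_spectrum", class(tibble::tibble())),
            band = band, sample_rate = sample_rate, degenerate = degenerate)
}

#' Frequency stability index of a power spectrum
#'
#' The FSI measures how concentrated a spectrum's power is around its
#' highest in-band peak. With `P(f)` the spectrum, `[F1, F2]` the analysis
#' band and `F_m` the in-band peak frequency, symmetric windows
#' `[max(F1, F_m - u), min(F_m + u, F2)]` sweep `u` from 0 to
#' `U = max(F_m - F1, F2 - F_m)`; `R_w` is the fraction of band power each
#' window captures, indexed by its width `w = f2 - f1`, and the FSI is the
#' mean of `R_w` over `w` in `[0, L]`, `L = F2 - F1`. It is 1 when all
#' power sits at a single frequency, about 0.5 for a flat spectrum, and
#' approaches 0 when power is dispersed far from the peak.
#'
#' Discrete spectra are treated as point masses at the bin frequencies:
#' `R_w` is then the right-continuous step function of bin inclusion
#' (`|f_k - F_m| <= u`), integrated exactly over the width grid the bins
#' induce. Peak ties break toward the lowest frequency. A spectrum with no
#' in-band power returns a degenerate result (`fsi = NA`, flagged), which
#' per-epoch wrappers treat as 0.
#'
#' @param spectrum A `power_spectrum` tibble (columns `freq`, `power`), or
#'   any data frame with those columns.
#' @param band Analysis band `c(F1, F2)`; defaults to the spectrum's `band`
#'   attribute.
#' @return An `fsi_result`: list with `fsi`, `peak_freq`, `band_power`,
#'   `curve` (tibble of `omega`, `r`) and `degenerate`.
#' @export
compute_fsi <- function(spectrum, band = attr(spectrum, "band")) {
  if (is.null(band)) abort("No analysis band supplied.")
  stopifnot(length(band) == 2, band[1] < band[2])
  f_all <- spectrum$freq
  p_all <- spectrum$power
  if (any(p_all < 0)) abort("Spectrum power must be nonnegative.")
  inband <- f_all >= band[1] & f_all <= band[2]
  f <- f_all[inband]
  p <- p_all[inband]
  s_l <- sum(p)
  if (length(f) == 0 || s_l <= 0) {
    return(structure(list(fsi = NA_real_, peak_freq = NA_real_, band_power = 0,
                          curve = tibble::tibble(omega = numeric(), r = numeric()),
                          band = band, degenerate = TRUE),
                     class = "fsi_result"))
  }
  f1 <- band[1]; f2 <- band[2]
  l <- f2 - f1
  m <- which.max(p)              # first maximum: tie -> lowest frequency
  fm <- f[m]
  d <- abs(f - fm)
  u_max <- max(fm - f1, f2 - fm)
  us <- sort(unique(c(0, d, u_max)))
  us <- us[us <= u_max]
  s_u <- vapply(us, function(u) sum(p[d <= u]), numeric(1))
  r <- s_u / s_l
  omega <- pmin(fm + us, f2) - pmax(f1, fm - us)
  # exact area under the right-continuous step R(omega)
  k <- length(us)
  area <- if (k > 1) sum(r[-k] * diff(omega)) else 0
  area <- area + r[k] * (l - omega[k])  # beyond the last knot R = 1 (omega[k] = l)
  structure(list(fsi = area / l, peak_freq = fm, band_power = s_l,
                 curve = tibble::tibble(omega = omega, r = r),
                 band = band, degenerate = FALSE),
            class = "fsi_result")
}

#' @export
print.fsi_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<fsi_result> degenerate (no in-band power)\n")
  } else {
    cat(sprintf("<fsi_result> FSI = %.4f, peak at %.3f Hz, band [%g, %g] Hz\n",
                x$fsi, x$peak_freq, x$band[1], x$band[2]))
  }
  invisible(x)
}

#' FSI of a raw signal segment
#'
#' Convenience wrapper: [estimate_spectrum()] followed by [compute_fsi()].
#'
#' @inheritParams estimate_spectrum
#' @return An `fsi_result`.
#' @export
fsi <- function(x, sample_rate, band) {
  compute_fsi(estimate_spectrum(x, sample_rate, band))
}

# Segment of a series centred on an epoch, extended by `pad` seconds on each
# side and clipped at the recording edges.
epoch_segment <- function(series, epoch, grid, fs, pad) {
  start <- (epoch - 1) * grid$epoch_length - pad
  end <- epoch * grid$epoch_length + pad
  i0 <- max(1L, round(start * fs) + 1L)
  i1 <- min(length(series), round(end * fs))
  series[i0:i1]
}

fsi_or_na <- function(x, fs, band) {
  res <- fsi(x, fs, band)
  if (isTRUE(res$degenerate)) NA_real_ else res$fsi
}

#' Per-epoch mechanocardiogram FSI
#'
#' For each 30-s epoch the FSI of the cardiac scalars is computed on a 32-s
#' segment centred on the epoch (1 s overlap at each end; clipped at the
#' recording edges) in the 4-11 Hz band, separately for the accelerometer
#' (`scg`) and gyroscope (`gcg`) scalars; the larger of the two is the
#' epoch's `mcg_fsi`. If both spectra are degenerate the value is 0 and the
#' epoch is flagged.
#'
#' @param components An `imu_components` tibble from [decompose()].
#' @param grid Epoch grid from [make_epoch_grid()].
#' @param pad Half-overlap in seconds (1 for the 32-s cardiac segment).
#' @param band Analysis band; defaults to the component's pass band.
#' @return Tibble with columns `epoch`, `mcg_fsi`, `degenerate`.
#' @export
epoch_mcg_fsi <- function(components, grid, pad = 1, band = band_edges("mcg")) {
  fs <- attr(components, "sample_rate")
  res <- lapply(seq_len(grid$n_epochs), function(e) {
    v1 <- fsi_or_na(epoch_segment(components$scg, e, grid, fs, pad), fs, band)
    v2 <- fsi_or_na(epoch_segment(components$gcg, e, grid, fs, pad), fs, band)
    both_na <- is.na(v1) && is.na(v2)
    list(fsi = if (both_na) 0 else max(v1, v2, na.rm = TRUE), degenerate = both_na)
  })
  tibble::tibble(epoch = seq_len(grid$n_epochs),
                 mcg_fsi = vapply(res, `[[`, numeric(1), "fsi"),
                 degenerate = vapply(res, `[[`, logical(1), "degenerate"))
}

#' Per-epoch respiratory wrist-motion FSI
#'
#' For each 30-s epoch the respiratory axis with the widest interquartile
#' range within the epoch is selected per sensor ([select_rm_axis()]), its
#' FSI is computed on a 64-s segment centred on the epoch (17 s overlap at
#' each end; clipped at the edges) in the 0.13-0.70 Hz band, and the larger
#' of the accelerometer and gyroscope values is the epoch's `rm_fsi`.
#'
#' @inheritParams epoch_mcg_fsi
#' @param pad Half-overlap in seconds (17 for the 64-s respiratory segment).
#' @return Tibble with columns `epoch`, `rm_fsi`, `degenerate`.
#' @export
epoch_rm_fsi <- function(components, grid, pad = 17, band = band_edges("rm")) {
  fs <- attr(components, "sample_rate")
  res <- lapply(seq_len(grid$n_epochs), function(e) {
    acc <- select_rm_axis(components, e, grid, "acc")$series
    gyr <- select_rm_axis(components, e, grid, "gyr")$series
    v1 <- fsi_or_na(epoch_segment(acc, e, grid, fs, pad), fs, band)
    v2 <- fsi_or_na(epoch_segment(gyr, e, grid, fs, pad), fs, band)
    both_na <- is.na(v1) && is.na(v2)
    list(fsi = if (both_na) 0 else max(v1, v2, na.rm = TRUE), degenerate = both_na)
  })
  tibble::tibble(epoch = seq_len(grid$n_epochs),
                 rm_fsi = vapply(res, `[[`, numeric(1), "fsi"),
                 degenerate = vapply(res, `[[`, logical(1), "degenerate"))
}
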