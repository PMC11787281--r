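#' Default analysis bands
#'
#' Pass bands (Hz) of the three components extracted from wrist IMU signals:
#' mechanocardiogram (`mcg`, cardiac micro-vibrations, 4-11 Hz), respiratory
#' wrist motion (`rm`, 0.13-0.70 Hz) and gross body movement (`bm`,
#' 2.0-3.0 Hz).
#'
#' @return Tibble with columns `label`, `low`, `high`.
#' @export
imu_bands <- function() {
  tibble::tibble(label = c("mcg", "rm", "bm"),
                 low = c(4, 0.13, 2.0),
                 high = c(11, 0.70, 3.0))
}

band_edges <- function(label, bands = imu_bands()) {
  row <- bands[bands$label == label, ]
  c(row$low, row$high)
}

# Linear-phase FIR band-pass (Hamming window). The order is chosen so the
# transition width is about half the band's low edge; even order gives an
# odd, symmetric tap vector whose group delay is an integer sample count.
design_bandpass <- function(low, high, fs, taps = NULL) {
  stopifnot(low > 0, low < high, high < fs / 2)
  if (is.null(taps)) {
    transition <- 0.5 * low
    order <- ceiling(3.3 * fs / transition)
    if (order %% 2 == 1) order <- order + 1
  } else {
    order <- taps - 1
    if (order %% 2 == 1) abort("`taps` must be odd (symmetric linear-phase filter).")
  }
  signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a linear-phase Hamming-window FIR band-pass and compensates its
#' group delay, so the output has no lag relative to the input (the
#' cross-correlation peak of a band-limited input with its output is at lag
#' 0). Passband gain is within 5% of unity and stopband attenuation exceeds
#' 20 dB one octave outside the band. The first and last half-filter-length
#' samples carry edge effects; [decompose()] records that margin.
#'
#' @param x Numeric series.
#' @param low,high Band edges in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param taps Optional odd tap count overriding the default order rule.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_fir <- function(x, low, high, sample_rate, taps = NULL) {
  h <- design_bandpass(low, high, sample_rate, taps = taps)
  n <- length(x)
  if (n <= length(h)) {
    abort(sprintf("Signal (%d samples) is not longer than the %d-tap filter.",
                  n, length(h)),
          class = "somnimu_data_error")
  }
  fft_convolve(x, h)
}

# FFT overlap-free convolution, centre-aligned to cancel the FIR group delay
fft_convolve <- function(x, h) {
  n <- length(x)
  nh <- length(h)
  nfft <- nextn(n + nh - 1, 2)
  X <- fft(c(x, numeric(nfft - n)))
  H <- fft(c(h, numeric(nfft - nh)))
  y <- Re(fft(X * H, inverse = TRUE)) / nfft
  gd <- (nh - 1) / 2
  y[(gd + 1):(gd + n)]
}

#' Pointwise Euclidean norm of a triaxial series
#'
#' Combines three axis series into one nonnegative scalar series
#' `sqrt(x^2 + y^2 + z^2)`; invariant to axis permutation and sign flips.
#'
#' @param x,y,z Equal-length numeric series.
#' @return Nonnegative series of the same length.
#' @export
combine_scalar <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z)) {
    abort("Axis series must have equal length.", class = "somnimu_data_error")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Decompose a recording into its band-limited components
#'
#' Filters each of the six IMU axes into the three analysis bands and
#' assembles: the cardiac scalars `scg` (accelerometer) and `gcg`
#' (gyroscope) as the Euclidean norm of the 4-11 Hz axes; the per-axis
#' respiratory components `rm_ax..rm_gz` (0.13-0.70 Hz) and their per-sensor
#' scalars `rms_acc`, `rms_gyr`; and the single movement scalar `bm`
#' combining all six 2.0-3.0 Hz axes, with each sensor's trio z-scaled by
#' its whole-recording robust SD so G and dps mix scale-free.
#'
#' @param recording An [imu_recording()].
#' @param bands Band table as from [imu_bands()].
#' @return Tibble of class `imu_components` with one row per sample, and
#'   attributes `sample_rate`, `subject_id` and `edge_samples` (per-band
#'   half-filter-length margins).
#' @export
decompose <- function(recording, bands = imu_bands()) {
  fs <- attr(recording, "sample_rate")
  filt_band <- function(label) {
    edges <- band_edges(label, bands)
    lapply(imu_axis_cols, function(col) {
      bandpass_fir(recording[[col]], edges[1], edges[2], fs)
    })
  }
  mcg <- filt_band("mcg")
  rm_ <- filt_band("rm")
  bm_ <- filt_band("bm")

  robust_sd <- function(v) {
    s <- mad(v, center = 0)
    if (s <= 0) s <- sd(v)
    if (is.na(s) || s <= 0) s <- 1
    s
  }
  s_acc <- robust_sd(c(bm_[[1]], bm_[[2]], bm_[[3]]))
  s_gyr <- robust_sd(c(bm_[[4]], bm_[[5]], bm_[[6]]))
  bm_scalar <- sqrt((bm_[[1]] / s_acc)^2 + (bm_[[2]] / s_acc)^2 + (bm_[[3]] / s_acc)^2 +
                    (bm_[[4]] / s_gyr)^2 + (bm_[[5]] / s_gyr)^2 + (bm_[[6]] / s_gyr)^2)

  out <- tibble::tibble(
    t = recording$t,
    scg = combine_scalar(mcg[[1]], mcg[[2]], mcg[[3]]),
    gcg = combine_scalar(mcg[[4]], mcg[[5]], mcg[[6]]),
    rm_ax = rm_[[1]], rm_ay = rm_[[2]], rm_az = rm_[[3]],
    rm_gx = rm_[[4]], rm_gy = rm_[[5]], rm_gz = rm_[[6]],
    rms_acc = combine_scalar(rm_[[1]], rm_[[2]], rm_[[3]]),
    rms_gyr = combine_scalar(rm_[[4]], rm_[[5]], rm_[[6]]),
    bm = bm_scalar
  )
  edge <- vapply(bands$label, function(lb) {
    edges <- band_edges(lb, bands)
    (length(design_bandpass(edges[1], edges[2], fs)) - 1) / 2
  }, numeric(1))
  structure(out,
            class = c("imu_components", class(tibble::tibble())),
            sample_rate = fs,
            subject_id = attr(recording, "subject_id"),
            edge_samples = setNames(edge, bands$label))
}

#' Select the respiratory axis with the widest interquartile range
#'
#' Within one 30-s epoch, picks whichever of the X/Y/Z respiratory
#' components has the largest interquartile range (75th minus 25th
#' percentile); ties break toward X, then Y, then Z.
#'
#' @param components An `imu_components` tibble from [decompose()].
#' @param epoch 1-based epoch index.
#' @param grid Epoch grid from [make_epoch_grid()].
#' @param sensor `"acc"` or `"gyr"`.
#' @return List with `axis` (`"x"`, `"y"` or `"z"`) and `series` (the full
#'   respiratory series of the selected axis).
#' @export
select_rm_axis <- function(components, epoch, grid, sensor = c("acc", "gyr")) {
  sensor <- match.arg(sensor)
  cols <- if (sensor == "acc") c("rm_ax", "rm_ay", "rm_az") else c("rm_gx", "rm_gy", "rm_gz")
  fs <- attr(components, "sample_rate")
  idx <- epoch_samples(epoch, grid, fs)
  iqrs <- vapply(cols, function(col) {
    qs <- quantile(components[[col]][idx], c(0.25, 0.75), names = FALSE)
    qs[2] - qs[1]
  }, numeric(1))
  k <- which.max(iqrs)  # first maximum: ties fall to X, then Y, then Z
  list(axis = c("x", "y", "z")[k], series = components[[cols[k]]])
}

#' Per-epoch gross body-movement feature
#'
#' The BM feature of an epoch is the maximum of the combined 2.0-3.0 Hz
#' movement scalar within that epoch.
#'
#' @inheritParams select_rm_axis
#' @return A single nonnegative value.
#' @export
bm_feature <- function(components, epoch, grid) {
  fs <- attr(components, "sample_rate")
  max(components$bm[epoch_samples(epoch, grid, fs)])
}

#' BM feature for every epoch of a grid
#' @inheritParams select_rm_axis
#' @return Tibble with columns `epoch`, `bm`.
#' @export
epoch_bm <- function(components, grid) {
  tibble::tibble(
    epoch = seq_len(grid$n_epochs),
    bm = vapply(seq_len(grid$n_epochs), function(e) bm_feature(components, e, grid),
                numeric(1))
  )
}
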