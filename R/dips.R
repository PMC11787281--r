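#' Centered sliding percentile of a series
#'
#' Moving q-th percentile in a centered window, truncated at the series
#' edges (the window shrinks rather than padding). Percentiles use R's
#' default (type 7) interpolation, so each output value equals
#' `quantile(window, q)`.
#'
#' @param x Numeric series.
#' @param window Window width in seconds.
#' @param q Percentile in `[0, 1]` (default 0.95).
#' @param sample_rate Sampling rate in Hz.
#' @return Series of the same length as `x`.
#' @export
sliding_percentile <- function(x, window, q = 0.95, sample_rate) {
  w <- round(window * sample_rate)
  if (w < 3) abort("Window must span at least 3 samples.", class = "somnimu_data_error")
  if (w > length(x)) {
    abort("Window is longer than the signal.", class = "somnimu_data_error")
  }
  run_quantile_cpp(x, floor(w / 2), q)
}

#' Fast and slow upper envelopes of the respiratory scalar
#'
#' The fast and slow envelopes are the 95th-percentile values of the
#' respiratory scalar (RMS) in centered moving windows of 3 s and 20 s.
#' The fast envelope tracks transient amplitude reductions; the slow one
#' holds the recent typical amplitude, so apneic dips open a gap between
#' them.
#'
#' @param rms Nonnegative respiratory scalar series (`rms_acc` or `rms_gyr`
#'   from [decompose()]).
#' @param sample_rate Sampling rate in Hz.
#' @param fast_window,slow_window Window widths in seconds (3 and 20).
#' @param q Percentile (0.95).
#' @return Tibble of class `envelope_pair` with columns `t`, `rms`, `fast`,
#'   `slow`.
#' @export
rm_envelopes <- function(rms, sample_rate, fast_window = 3, slow_window = 20,
                         q = 0.95) {
  structure(
    tibble::tibble(
      t = (seq_along(rms) - 1) / sample_rate,
      rms = rms,
      fast = sliding_percentile(rms, fast_window, q, sample_rate),
      slow = sliding_percentile(rms, slow_window, q, sample_rate)
    ),
    class = c("envelope_pair", class(tibble::tibble())),
    sample_rate = sample_rate
  )
}

#' Detect RMS dips from an envelope pair
#'
#' A dip is a maximal contiguous run of samples where the fast envelope is
#' strictly below the slow one. Each run becomes one dip whose `start` is
#' the time of its first sample and whose `end` is one sample period past
#' its last sample (half-open, so a run over `t` in `[10, 20)` yields
#' `start = 10`, `end = 20`). Touches (`fast == slow`) are not dips. Dips
#' whose run reaches the first or last sample are flagged `edge`.
#'
#' @param env An `envelope_pair` from [rm_envelopes()].
#' @return Tibble with columns `start`, `end`, `i0`, `i1` (sample indices of
#'   the run) and `edge`; zero rows when the fast envelope never drops below
#'   the slow one.
#' @export
detect_dips <- function(env) {
  fs <- attr(env, "sample_rate")
  below <- env$fast < env$slow
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  i0 <- starts[keep]
  i1 <- ends[keep]
  tibble::tibble(
    start = env$t[i0],
    end = env$t[i1] + 1 / fs,
    i0 = i0,
    i1 = i1,
    edge = i0 == 1L | i1 == nrow(env)
  )
}

.trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Geometric features of detected dips
#'
#' Populates each dip with the feature set used per epoch:
#' * `w` — dip width `end - start` in seconds;
#' * `abe` — absolute area between the slow and fast envelopes over the dip
#'   (trapezoid on the sample grid);
#' * `rabe` — `abe` relative to the area under the slow envelope over the
#'   dip;
#' * `h1`, `h2` — slow-envelope heights at the dip's start and end samples,
#'   and `h_max = max(h1, h2)`, `h_ratio = min(h1, h2) / max(h1, h2)`
#'   (1 when both are 0);
#' * `ad` — maximum depth `max(slow - fast)` over the dip, and `rd` — that
#'   depth relative to the slow envelope at the same sample (0 where the
#'   slow envelope is 0).
#'
#' The relative features (`w`, `rabe`, `h_ratio`, `rd`) are invariant to
#' rescaling the RMS, which is what makes them robust to individual and
#' positioning differences in absolute signal strength.
#'
#' @param dips Dip boundaries from [detect_dips()].
#' @param env The `envelope_pair` the dips came from.
#' @return The `dips` tibble with feature columns added.
#' @export
dip_features <- function(dips, env) {
  n <- nrow(env)
  feats <- purrr::pmap(list(dips$i0, dips$i1), function(i0, i1) {
    idx <- i0:i1
    tt <- env$t[idx]
    gap <- env$slow[idx] - env$fast[idx]
    abe <- .trapz(tt, gap)
    slow_area <- .trapz(tt, env$slow[idx])
    h1 <- env$slow[i0]
    h2 <- env$slow[min(i1 + 1L, n)]
    h_max <- max(h1, h2)
    h_ratio <- if (h_max > 0) min(h1, h2) / h_max else 1
    j <- idx[which.max(gap)]
    ad <- env$slow[j] - env$fast[j]
    rd <- if (env$slow[j] > 0) ad / env$slow[j] else 0
    tibble::tibble(abe = abe,
                   rabe = if (slow_area > 0) abe / slow_area else 0,
                   h1 = h1, h2 = h2, h_max = h_max, h_ratio = h_ratio,
                   ad = ad, rd = rd)
  })
  dplyr::bind_cols(
    dplyr::mutate(dips, w = .data$end - .data$start, .after = "end"),
    dplyr::bind_rows(feats)
  )
}

#' Detect and featurise RMS dips in one call
#'
#' @inheritParams rm_envelopes
#' @param ... Passed to [rm_envelopes()] (window widths, percentile).
#' @return Tibble of fully featurised dips (possibly zero rows).
#' @export
find_dips <- function(rms, sample_rate, ...) {
  env <- rm_envelopes(rms, sample_rate, ...)
  dips <- detect_dips(env)
  if (nrow(dips) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(), w = numeric(),
                          i0 = integer(), i1 = integer(), edge = logical(),
                          abe = numeric(), rabe = numeric(),
                          h1 = numeric(), h2 = numeric(), h_max = numeric(),
                          h_ratio = numeric(), ad = numeric(), rd = numeric()))
  }
  dip_features(dips, env)
}
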