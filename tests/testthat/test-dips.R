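fs <- 60

make_env <- function(fast, slow, rms = fast) {
  structure(tibble::tibble(t = (seq_along(fast) - 1) / fs,
                           rms = rms, fast = fast, slow = slow),
            class = c("envelope_pair", class(tibble::tibble())),
            sample_rate = fs)
}

test_that("sliding percentile matches the brute-force oracle", {
  withr::local_seed(11)
  x <- rnorm(400)
  for (w_sec in c(0.1, 0.5, 1.5)) {
    w <- round(w_sec * fs)
    expect_equal(sliding_percentile(x, w_sec, 0.95, fs),
                 brute_percentile(x, w, 0.95), tolerance = 1e-12)
  }
  # constant signal -> constant output
  expect_equal(sliding_percentile(rep(3.2, 200), 0.5, 0.95, fs), rep(3.2, 200))
  # unit impulse with a 3-s window influences only +/- 1.5 s
  imp <- numeric(10 * fs); imp[5 * fs] <- 1
  out <- sliding_percentile(imp, 3, 0.95, fs)
  nz <- which(out > 1e-12)
  expect_true(all(abs(nz - 5 * fs) <= round(1.5 * fs) + 1))
  # monotone ramp agrees with the oracle
  ramp <- seq(0, 1, length.out = 300)
  expect_equal(sliding_percentile(ramp, 1, 0.95, fs),
               brute_percentile(ramp, round(1 * fs), 0.95), tolerance = 1e-12)
  # degenerate windows rejected
  expect_error(sliding_percentile(x, 0.02, 0.95, fs), class = "somnimu_data_error")
  expect_error(sliding_percentile(rnorm(10), 3, 0.95, fs),
               class = "somnimu_data_error")
})

test_that("dips are strict fast-below-slow runs with half-open boundaries", {
  n <- 60 * fs
  # fast never below slow -> none; equality everywhere -> none
  expect_equal(nrow(detect_dips(make_env(rep(2, n), rep(1, n)))), 0)
  expect_equal(nrow(detect_dips(make_env(rep(2, n), rep(2, n)))), 0)
  # rectangle dip on t in [10, 20)
  t <- (seq_len(n) - 1) / fs
  fast <- rep(2, n); fast[t >= 10 & t < 20] <- 1
  d <- detect_dips(make_env(fast, rep(2, n)))
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 10)
  expect_equal(d$end, 20)
  expect_false(d$edge)
})

test_that("dip features reproduce closed-form geometry", {
  n <- 60 * fs
  t <- (seq_len(n) - 1) / fs
  # rectangle: slow 2, fast drops to 1 for 10 s
  fast <- rep(2, n); fast[t >= 10 & t < 20] <- 1
  env <- make_env(fast, rep(2, n))
  d <- dip_features(detect_dips(env), env)
  expect_equal(d$w, 10)
  expect_equal(d$rabe, 0.5, tolerance = 1e-12)
  expect_equal(d$h1, 2); expect_equal(d$h2, 2)
  expect_equal(d$h_max, 2); expect_equal(d$h_ratio, 1)
  expect_equal(d$ad, 1); expect_equal(d$rd, 0.5)
  expect_equal(d$abe, 10, tolerance = 0.02)

  # triangle to zero at the centre under slow = 1, width 10
  fast2 <- pmin(1, abs(t - 15) / 5)
  env2 <- make_env(fast2, rep(1, n))
  d2 <- dip_features(detect_dips(env2), env2)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$ad, 1, tolerance = 1e-9)
  expect_equal(d2$rd, 1, tolerance = 1e-9)
  expect_equal(d2$rabe, 0.5, tolerance = 1e-2)

  # vanishing depth: features tend to zero
  fast3 <- rep(1, n); fast3[t >= 30 & t < 31] <- 1 - 1e-9
  env3 <- make_env(fast3, rep(1, n))
  d3 <- dip_features(detect_dips(env3), env3)
  expect_lte(d3$rabe, 1e-8)
  expect_lte(d3$ad, 1e-8)
  expect_lte(d3$rd, 1e-8)
})

test_that("relative dip features are invariant to rescaling the RMS", {
  rms <- withr::with_seed(3, suppressed_rms(20))
  base <- find_dips(rms, fs)
  for (c_scale in c(0.1, 10)) {
    scaled <- find_dips(c_scale * rms, fs)
    expect_equal(nrow(scaled), nrow(base))
    expect_equal(scaled$w, base$w)
    expect_equal(scaled$rabe, base$rabe, tolerance = 1e-9)
    expect_equal(scaled$rd, base$rd, tolerance = 1e-9)
    expect_equal(scaled$h_ratio, base$h_ratio, tolerance = 1e-9)
    expect_equal(scaled$abe, c_scale * base$abe, tolerance = 1e-9)
    expect_equal(scaled$ad, c_scale * base$ad, tolerance = 1e-9)
    expect_equal(scaled$h_max, c_scale * base$h_max, tolerance = 1e-9)
  }
})

test_that("detected dips are disjoint, sorted, and strict inside", {
  withr::local_seed(17)
  rms <- abs(sin(2 * pi * 0.25 * (0:(90 * fs - 1)) / fs)) *
    exp(rnorm(90 * fs, 0, 0.2)) + abs(rnorm(90 * fs, 0, 0.02))
  env <- rm_envelopes(rms, fs)
  d <- detect_dips(env)
  if (nrow(d) > 1) {
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  for (k in seq_len(nrow(d))) {
    expect_true(all(env$fast[d$i0[k]:d$i1[k]] < env$slow[d$i0[k]:d$i1[k]]))
    if (d$i0[k] > 1) expect_gte(env$fast[d$i0[k] - 1], env$slow[d$i0[k] - 1])
    if (d$i1[k] < nrow(env)) expect_gte(env$fast[d$i1[k] + 1], env$slow[d$i1[k] + 1])
  }
})

test_that("an injected suppression is recovered at its true boundaries", {
  widths <- c(10, 20, 40)
  for (w in widths) {
    rms <- withr::with_seed(100 + w, suppressed_rms(w))
    d <- find_dips(rms, fs)
    hit <- any(abs(d$start - 60) <= 3 & abs(d$end - (60 + w)) <= 3)
    expect_true(hit, label = sprintf("width %d recovered", w))
    best <- d[which.min(abs(d$start - 60) + abs(d$end - 60 - w)), ]
    expect_lte(abs(best$w - w), 3 + 3)
  }
})
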