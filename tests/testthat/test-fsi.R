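test_that("the periodogram localises a pure tone and flags zero segments", {
  fs <- 60
  t <- seq(0, 32 - 1 / fs, by = 1 / fs)
  sp <- estimate_spectrum(sin(2 * pi * 8 * t), fs, band = c(4, 11))
  expect_equal(sp$freq[which.max(sp$power)], 8, tolerance = 1 / 32 + 1e-9)
  expect_false(attr(sp, "degenerate"))

  spz <- estimate_spectrum(numeric(length(t)), fs, band = c(4, 11))
  expect_true(attr(spz, "degenerate"))
  expect_equal(max(spz$power), 0)

  expect_error(estimate_spectrum(rnorm(60), fs, band = c(0.13, 0.7)),
               class = "somnimu_data_error")
})

test_that("FSI analytic values: single bin, flat spectrum, two-bin case", {
  # all power in one bin -> exactly 1
  sp <- tibble::tibble(freq = seq(1, 5, length.out = 101), power = 0)
  sp$power[37] <- 2.7
  expect_identical(compute_fsi(sp, band = c(1, 5))$fsi, 1)

  # flat spectrum -> 0.5 (within discretisation at modest bin counts)
  for (nb in c(64, 256, 1024)) {
    spf <- tibble::tibble(freq = seq(1, 5, length.out = nb), power = 1)
    expect_equal(compute_fsi(spf, band = c(1, 5))$fsi, 0.5, tolerance = 0.02)
  }

  # two point masses 0.6 @ 0.25 Hz and 0.4 @ 0.75 Hz on band [0, 1]:
  # R = 0.6 until the far bin enters at width 0.75, then 1
  res <- compute_fsi(tibble::tibble(freq = c(0.25, 0.75), power = c(0.6, 0.4)),
                     band = c(0, 1))
  expect_equal(res$fsi, 0.6 * 0.75 + 1 * 0.25, tolerance = 1e-12)
  expect_equal(res$peak_freq, 0.25)

  # no in-band power -> degenerate, not an error
  deg <- compute_fsi(tibble::tibble(freq = c(2, 3), power = c(0, 0)),
                     band = c(1, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$fsi))
})

test_that("FSI properties hold over random spectra", {
  withr::local_seed(421)
  for (i in 1:200) {
    sp <- random_spectrum(sample(8:512, 1), heavy = runif(1) < 0.5)
    band <- range(sp$freq)
    res <- compute_fsi(sp, band = band)
    expect_gte(res$fsi, 0)
    expect_lte(res$fsi, 1)
    # scale invariance
    sp2 <- sp; sp2$power <- sp2$power * runif(1, 1e-3, 1e3)
    expect_equal(compute_fsi(sp2, band = band)$fsi, res$fsi, tolerance = 1e-12)
    # R nondecreasing, reaching 1
    expect_true(all(diff(res$curve$r) >= -1e-12))
    expect_equal(res$curve$r[nrow(res$curve)], 1)
  }
})

test_that("knot-based FSI matches the dense Riemann-sum oracle", {
  withr::local_seed(99)
  for (i in 1:20) {
    sp <- random_spectrum(512, heavy = i %% 2 == 0)
    band <- range(sp$freq)
    expect_equal(compute_fsi(sp, band = band)$fsi,
                 fsi_riemann(sp$freq, sp$power, band),
                 tolerance = 1e-6)
  }
})

test_that("concentrating power toward the peak never decreases FSI", {
  withr::local_seed(7)
  freq <- seq(1, 5, length.out = 101)
  power <- runif(101)
  band <- c(1, 5)
  fm_idx <- which.max(power)
  prev <- compute_fsi(tibble::tibble(freq = freq, power = power), band)$fsi
  # repeatedly move the farthest bin's power onto the peak bin
  for (step in 1:20) {
    d <- abs(freq - freq[fm_idx])
    far <- which(power > 0 & d == max(d[power > 0]))[1]
    if (far == fm_idx) break
    power[fm_idx] <- power[fm_idx] + power[far]
    power[far] <- 0
    cur <- compute_fsi(tibble::tibble(freq = freq, power = power), band)$fsi
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("per-epoch FSI takes the larger sensor and flags double degeneracy", {
  fs <- 60
  n <- 90 * fs
  t <- (seq_len(n) - 1) / fs
  grid <- toy_grid(3)
  steady <- sin(2 * pi * 7 * t)
  noisy <- withr::with_seed(1, rnorm(n))
  comp <- make_components(fs, n, scg = steady, gcg = noisy)
  v_steady <- epoch_mcg_fsi(make_components(fs, n, scg = steady, gcg = steady), grid)
  v_mixed <- epoch_mcg_fsi(comp, grid)
  # the stable tone dominates the noisy sensor via the max rule
  expect_equal(v_mixed$mcg_fsi, v_steady$mcg_fsi, tolerance = 1e-9)

  zero <- epoch_mcg_fsi(make_components(fs, n), grid)
  expect_equal(zero$mcg_fsi, rep(0, 3))
  expect_true(all(zero$degenerate))
})

test_that("steady breathing scores a higher respiratory FSI than jittered", {
  fs <- 60
  n <- 120 * fs
  t <- (seq_len(n) - 1) / fs
  grid <- toy_grid(4)
  steady <- sin(2 * pi * 0.25 * t)
  jit <- withr::with_seed(5, {
    freq <- 0.25 + cumsum(rnorm(n, 0, 0.1 / sqrt(fs)))
    freq <- pmin(pmax(freq, 0.15), 0.6)
    sin(2 * pi * cumsum(freq) / fs)
  })
  fsi_steady <- epoch_rm_fsi(make_components(fs, n, rm_ax = steady, rm_gx = steady), grid)
  fsi_jit <- epoch_rm_fsi(make_components(fs, n, rm_ax = jit, rm_gx = jit), grid)
  expect_gte(median(fsi_steady$rm_fsi), 0.9)
  expect_lt(median(fsi_jit$rm_fsi), median(fsi_steady$rm_fsi))
  # max rule across sensors
  both <- epoch_rm_fsi(make_components(fs, n, rm_ax = steady, rm_gx = jit), grid)
  expect_equal(both$rm_fsi, pmax(fsi_steady$rm_fsi, fsi_jit$rm_fsi),
               tolerance = 1e-9)
})
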