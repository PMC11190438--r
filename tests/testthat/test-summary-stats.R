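test_that("population CV matches arithmetic and is scale invariant", {
  expect_equal(population_cv(c(5, 5, 5)), 0)
  expect_equal(population_cv(c(1, 2, 3)), 0.5)
  x <- rlnorm(50)
  expect_equal(population_cv(7.3 * x), population_cv(x))
  expect_error(population_cv(c(1)), "at least 2")
  expect_error(population_cv(c(-2, 0, 2)), "mean must be > 0")
  expect_equal(population_cv(c(1, 2, 3), denominator = "n"),
               sqrt(2 / 3) / 2)
})

test_that("time-series CV works per cell and honours the burn-in convention", {
  tr <- dplyr::bind_rows(one_track(c(1, 2, 3), id = "a"),
                         one_track(rep(4, 3), id = "b"))
  out <- timeseries_cv(tr)
  expect_equal(out$cv_t[out$cell_id == "a"], 0.5)
  expect_equal(out$cv_t[out$cell_id == "b"], 0)
  # last_fraction keeps only the tail
  x <- c(rep(100, 50), rep(c(1, 2, 3), length.out = 50))
  expect_equal(timeseries_cv(x, last_fraction = 0.5),
               population_cv(x[51:100]))
})

test_that("relative trend ratio follows its closed forms", {
  expect_equal(relative_trend(rep(7, 10)), 1)
  expect_equal(relative_trend(seq(100, 50, length.out = 20)), 0.5)
  k <- 0.3; tt <- seq(0, 8, by = 0.1)
  expect_equal(relative_trend(exp(-k * tt) * 50), exp(-k * 8),
               tolerance = 1e-10)
  expect_error(relative_trend(c(0, 1, 2)), "> 0")
})

test_that("control normalisation divides channels and cancels shared artefacts", {
  t <- seq(0, 5, by = 0.1)
  sig <- 10 + sin(t)
  tr <- one_track(sig, control = 1)
  expect_equal(normalise_to_control(tr)$signal, sig)
  tr2 <- one_track(2 * (5 + cos(t)))
  tr2$control <- 5 + cos(t)
  expect_equal(normalise_to_control(tr2)$signal, rep(2, length(t)))
  # multiplicative acquisition artefact cancels exactly
  g <- 1 + 0.5 * sin(3 * t)
  tr3 <- tibble::tibble(cell_id = "c", time = t, signal = sig * g,
                        control = 2 * g)
  expect_equal(normalise_to_control(tr3)$signal, sig / 2)
  tr4 <- one_track(sig, control = 0)
  expect_error(normalise_to_control(tr4), "control")
})

test_that("detrending passes linear ramps, keeps ultradian sinusoids, is linear and exact", {
  t <- seq(0, 10, by = 0.1)
  ramp <- 5 + 3 * t
  d <- detrend(ramp, time = t)
  expect_equal(d$trend + d$detrended, ramp)
  mid <- 15:86
  expect_lt(max(abs(d$detrended[mid])), 0.01 * diff(range(ramp)))

  s <- sin(2 * pi * t / 1.9)
  ds <- detrend(s, time = t)
  expect_lt(max(abs(ds$trend[mid])), 0.1)
  expect_gt(max(ds$detrended[mid]), 0.9) # amplitude attenuation < 10%

  # linearity: trend(a + b) = trend(a) + trend(b)
  a <- rnorm(length(t)); b <- cumsum(rnorm(length(t))) / 10
  expect_equal(detrend(a + b, time = t)$trend,
               detrend(a, time = t)$trend + detrend(b, time = t)$trend,
               tolerance = 1e-10)

  expect_error(detrend(1:5, time = (0:4) * 0.1), "shorter")
})

test_that("Hilbert fold-change matches the closed form and flags missing pairs", {
  x <- sine_track(10, 2, 2, 10)
  expect_equal(hilbert_fold_change(x, x - mean(x)), 1.5, tolerance = 1e-3)
  expect_true(is.na(hilbert_fold_change(rep(5, 50), rep(0, 50))))
})

test_that("fold-change recovery on noisy oscillators is within 10% of truth", {
  errs <- sapply(1:60, function(s) {
    gen <- generate_tracks(track_spec(
      n_cells = 1, fraction_oscillatory = 1, osc_alpha = 0, period_h = 2,
      fold_change = 1.6, trend_ratio = 1, noise_cv = 0.03,
      control_noise_cv = 0, duration_h = 10, seed = s))
    tr <- detrend(normalise_to_control(gen$tracks))
    est <- hilbert_fold_change(tr$signal, tr$detrended)
    est / gen$labels$true_fold - 1
  })
  expect_lt(abs(median(errs)), 0.1)
})

test_that("coherence is high for sinusoids, low for white noise, scale free", {
  t <- seq(0, 30, by = 0.1)
  cs <- coherence(sin(2 * pi * t / 2), 0.1)
  expect_gt(cs$coherence, 0.9)
  expect_equal(cs$dominant_period, 2, tolerance = 0.05)

  wn <- sapply(1:10, function(s) {
    withr::with_seed(s, coherence(rnorm(301), 0.1)$coherence)
  })
  expect_lt(mean(wn), 0.2)

  x <- sin(2 * pi * t / 2) + 0.2 * rnorm(length(t))
  expect_equal(coherence(x, 0.1)$coherence, coherence(5 * x, 0.1)$coherence)
  expect_error(coherence(rep(0, 100), 0.1), "all-zero")
})

test_that("wavelet period recovers sinusoids and rejects permuted noise", {
  t <- seq(0, 10, by = 0.1)
  wp <- wavelet_period(sin(2 * pi * t / 2), 0.1, n_perm = 300, seed = 1)
  expect_equal(wp$mean_period, 2, tolerance = 0.15)

  # white noise: mostly no significant period across seeds
  nulls <- sapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(101))
    is.na(wavelet_period(x, 0.1, n_perm = 100, seed = s)$mean_period)
  })
  expect_gte(sum(nulls), 17)
})

test_that("chirp dominant period increases through time", {
  t <- seq(0, 12, by = 0.1)
  per <- 1.5 + (3 - 1.5) * t / max(t)
  phase <- 2 * pi * cumsum(0.1 / per)
  wp <- wavelet_period(sin(phase), 0.1, n_perm = 100, seed = 2)
  mid <- wp$by_time[20:101, ]
  expect_gt(cor(mid$time, mid$period, method = "spearman"), 0.8)
})

test_that("coherence and wavelet agree on clean sinusoids across 1-3 h periods", {
  t <- seq(0, 12, by = 0.1)
  for (P in c(1, 1.5, 2, 3)) {
    x <- sin(2 * pi * t / P)
    cs <- coherence(x, 0.1)
    wp <- wavelet_period(x, 0.1, n_perm = 100, seed = 5)
    expect_equal(cs$dominant_period, wp$mean_period, tolerance = 0.15 * P)
  }
})

test_that("half-life fit recovers decay parameters", {
  d <- generate_decay_chase(half_life_min = 11, noise_cv = 0)
  hf <- half_life_fit(d$time, d$signal)
  expect_equal(hf$half_life, 11, tolerance = 1e-6)

  expect_warning(hf0 <- half_life_fit(0:9 * 17, rep(100, 10)), "Inf")
  expect_identical(hf0$half_life, Inf)

  dpl <- generate_decay_chase(half_life_min = 20, plateau = 150,
                              y0 = 1000, noise_cv = 0.02, seed = 8)
  hfp <- half_life_fit(dpl$time, dpl$signal)
  expect_equal(hfp$plateau, 150, tolerance = 0.15 * 150)
  expect_equal(hfp$half_life, 20, tolerance = 0.1 * 20)

  # 5% multiplicative noise: median recovered half-life within 5% of truth
  hl <- sapply(1:100, function(s) {
    dd <- generate_decay_chase(half_life_min = 11, noise_cv = 0.05, seed = s)
    half_life_fit(dd$time, dd$signal)$half_life
  })
  expect_lt(abs(median(hl) / 11 - 1), 0.05)
})
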