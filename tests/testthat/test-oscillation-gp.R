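# draws one exact GP track on the imaging grid (oracle generator)
gp_track <- function(alpha, period = NA, n = 101, dt = 0.1, noise_var = 0,
                     seed = 1) {
  t <- (seq_len(n) - 1) * dt
  beta <- if (is.na(period)) 0 else 2 * pi / period
  tau <- abs(outer(t, t, "-"))
  K <- exp(-alpha * tau) * cos(beta * tau)
  diag(K) <- diag(K) + noise_var + 1e-9
  withr::with_seed(seed, as.vector(MASS::mvrnorm(1, numeric(n), K)))
}

test_that("OU bandwidth is recovered from OU data", {
  t <- seq(0, 12, by = 0.1)
  ahat <- sapply(1:100, function(s) {
    y <- gp_track(0.5, n = 121, seed = s)
    fit_gp(y, t, "ou", noise_var = 0)$alpha
  })
  expect_lt(abs(median(ahat) / 0.5 - 1), 0.25)
})

test_that("OUosc period is recovered from oscillatory data", {
  t <- seq(0, 10, by = 0.1)
  per <- sapply(1:40, function(s) {
    y <- gp_track(0.3, period = 2, n = 101, seed = 100 + s)
    f <- fit_gp(y, t, "ouosc", noise_var = 0)
    2 * pi / f$beta
  })
  expect_gte(median(per), 1.8)
  expect_lte(median(per), 2.2)
})

test_that("models are nested: LLR is non-negative up to optimiser tolerance", {
  t <- seq(0, 10, by = 0.1)
  for (s in 1:10) {
    y <- gp_track(1.5, n = 101, seed = 200 + s)
    ou <- fit_gp(y, t, "ou", noise_var = 0)
    osc <- fit_gp(y, t, "ouosc", noise_var = 0)
    expect_gte(llr_score(ou, osc), -1e-4)
  }
})

test_that("null LLR distribution concentrates near zero with a right tail", {
  t <- seq(0, 10, by = 0.1)
  llrs <- sapply(1:30, function(s) {
    y <- gp_track(1.5, n = 101, seed = 300 + s)
    llr_score(fit_gp(y, t, "ou", 0), fit_gp(y, t, "ouosc", 0))
  })
  expect_lt(median(llrs), 2)
  expect_gt(max(llrs), median(llrs))
  # strong clean oscillator scores far above the null
  yo <- gp_track(0.2, period = 2, n = 101, seed = 99)
  strong <- llr_score(fit_gp(yo, t, "ou", 0), fit_gp(yo, t, "ouosc", 0))
  expect_gt(strong, quantile(llrs, 0.95))
})

test_that("llr_score refuses fits of different tracks", {
  t <- seq(0, 10, by = 0.1)
  y1 <- gp_track(1, n = 101, seed = 1)
  y2 <- gp_track(1, n = 101, seed = 2)
  expect_error(llr_score(fit_gp(y1, t, "ou", 0), fit_gp(y2, t, "ouosc", 0)),
               "same track")
})

test_that("FDR calibration threshold behaves like a quantile", {
  t <- seq(0, 8, by = 0.1)
  y <- gp_track(1, n = 81, seed = 5)
  ou <- fit_gp(y, t, "ou", noise_var = 1e-3)
  cal <- calibrate_fdr(list(ou), n_synth = 120, target_fdr = 0.05,
                       restarts = 3, seed = 7)
  expect_equal(cal$threshold,
               unname(quantile(cal$null_llrs, 0.95)))
  cal0 <- calibrate_fdr(list(ou), n_synth = 120, target_fdr = 0,
                        restarts = 3, seed = 7)
  expect_equal(cal0$threshold, max(cal0$null_llrs))
  # threshold non-increasing in the target FDR (same null sample)
  expect_gte(cal0$threshold, cal$threshold)
  expect_error(calibrate_fdr(list(ou), n_synth = 50), ">= 100")
})

test_that("classification is invariant to rescaling all intensities", {
  gen <- generate_tracks(track_spec(n_cells = 8, fraction_oscillatory = 0.5,
                                    duration_h = 8, seed = 11))
  c1 <- classify_tracks(gen$tracks, gen$background, n_synth = 100,
                        restarts = 3, seed = 3)
  doubled <- gen$tracks
  doubled$signal <- doubled$signal * 2
  doubled$control <- doubled$control * 2
  bg2 <- gen$background
  bg2$signal <- bg2$signal * 2
  bg2$control <- bg2$control * 2
  c2 <- classify_tracks(doubled, bg2, n_synth = 100, restarts = 3, seed = 3)
  expect_identical(c1$calls$is_oscillatory, c2$calls$is_oscillatory)
  expect_equal(c1$calls$llr, c2$calls$llr, tolerance = 1e-6)
})

test_that("classification power rises with oscillation quality", {
  rate_at <- function(osc_alpha) {
    gen <- generate_tracks(track_spec(n_cells = 20, fraction_oscillatory = 1,
                                      osc_alpha = osc_alpha, duration_h = 8,
                                      trend_ratio = 1, seed = 21))
    cl <- classify_tracks(gen$tracks, gen$background, n_synth = 100,
                          restarts = 3, seed = 5)
    cl$percent_oscillatory
  }
  expect_gte(rate_at(0.15), rate_at(2))
})

test_that("degenerate and empty inputs raise errors", {
  t <- seq(0, 5, by = 0.1)
  expect_error(fit_gp(rep(1, 51), t, "ou", 0), "zero variance")
  gen <- generate_tracks(track_spec(n_cells = 2, duration_h = 4, seed = 1))
  short <- gen$tracks[gen$tracks$time < 2, ]
  expect_error(classify_tracks(short, gen$background), "3")
})
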