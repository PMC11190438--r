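test_that("Hill functions match closed forms and reject corrupt input", {
  expect_equal(hill_auto(0, 100, 4), 1)
  expect_equal(hill_auto(100, 100, 4), 0.5)
  expect_equal(hill_auto(200, 100, 4), 1 / 17)
  expect_equal(hill_li(0, 300, 2), 1)
  expect_equal(hill_li(300, 300, 2), 0.5)
  expect_equal(hill_li(3 * 300, 300, 2), 0.1)
  # strictly decreasing
  p <- seq(0, 1000, by = 50)
  expect_true(all(diff(hill_auto(p, 200, 3)) < 0))
  expect_error(hill_auto(-1, 100, 4), "finite")
  expect_error(hill_auto(NaN, 100, 4), "finite")
})

test_that("model_params enforces its invariants", {
  expect_error(model_params(alpha_m = -1), "> 0")
  expect_error(model_params(n_auto = 0.5), ">= 1")
  expect_error(model_params(dt = 0.2, tau_auto = 0.1), "smaller than")
  expect_error(model_params(t_end = 0), "> 0")
})

test_that("deterministic steady state solves the fixed-point system", {
  # repression off: all rates 1, huge threshold -> m* = p* = 1
  p0 <- model_params(alpha_m = 1, alpha_p = 1, mu_m = 1, mu_p = 1,
                     P0_auto = 1e12, tau_auto = 0.5, tau_LI = 0.5,
                     dt = 0.01)
  expect_equal(unname(deterministic_steady_state(p0)), c(1, 1),
               tolerance = 1e-6)

  # plug-back residual below 1e-9 for arbitrary valid parameter sets
  set.seed(4)
  for (i in 1:20) {
    pp <- model_params(alpha_m = runif(1, 10, 900), alpha_p = runif(1, 2, 90),
                       mu_m = runif(1, 0.5, 8), mu_p = runif(1, 1, 8),
                       P0_auto = runif(1, 100, 9000),
                       n_auto = runif(1, 2, 6),
                       P0_LI = runif(1, 100, 9000), n_LI = runif(1, 2, 6),
                       coupled = i %% 2 == 0)
    ss <- deterministic_steady_state(pp)
    h <- hill_auto(ss[["p"]], pp$P0_auto, pp$n_auto)
    if (pp$coupled) h <- h * hill_li(ss[["p"]], pp$P0_LI, pp$n_LI)
    res_m <- pp$alpha_m * h - pp$mu_m * ss[["m"]]
    res_p <- pp$alpha_p * ss[["m"]] - pp$mu_p * ss[["p"]]
    expect_lt(abs(res_m) / pp$alpha_m, 1e-9)
    expect_lt(abs(res_p) / (pp$alpha_p * ss[["m"]]), 1e-9)
  }

  # doubling protein degradation strictly decreases p*
  a <- deterministic_steady_state(model_params())
  b <- deterministic_steady_state(model_params(degradation_multiplier = 2))
  expect_lt(b[["p"]], a[["p"]])
})

test_that("langevin_noise has the propensity-scaled moments and exact zeros", {
  pp <- tiny_params(noise_on = FALSE)
  z <- langevin_noise(10, 10, 5, 5, pp)
  expect_identical(z$eta_m, 0)
  expect_identical(z$eta_p, 0)

  pp2 <- tiny_params()
  z0 <- langevin_noise(0, 0, 0, 0, pp2)
  expect_identical(z0$eta_m, 0)
  expect_error(langevin_noise(-1, 0, 0, 0, pp2), "negative")
  expect_error(langevin_noise(1, 1, -2, 0, pp2), "negative")
})

test_that("simulation is deterministic, non-negative and converges to the fixed point", {
  s1 <- simulate_her6(tiny_params())
  s2 <- simulate_her6(tiny_params())
  expect_identical(s1$m, s2$m)
  expect_identical(s1$p, s2$p)
  expect_true(min(s1$m) >= 0 && min(s1$p) >= 0)

  # a different seed changes the trajectories
  s3 <- simulate_her6(model_params(rows = 2, cols = 2, t_end = 10, seed = 2))
  expect_false(identical(s1$p, s3$p))

  # noise off, stable regime: endpoint agrees with the algebraic root
  pst <- model_params(alpha_m = 100, alpha_p = 10, mu_m = 2, mu_p = 2,
                      P0_auto = 500, n_auto = 2, tau_auto = 0.2,
                      rows = 1, cols = 1, t_end = 40, noise_on = FALSE,
                      seed = 1)
  sim <- simulate_her6(pst)
  ss <- deterministic_steady_state(pst)
  expect_lt(abs(sim$p[1, ncol(sim$p)] - ss[["p"]]) / ss[["p"]], 1e-3)
  expect_lt(abs(sim$m[1, ncol(sim$m)] - ss[["m"]]) / ss[["m"]], 1e-3)
})

test_that("strong delayed autoinhibition yields a limit cycle with period above 2 tau", {
  pp <- model_params(alpha_m = 300, alpha_p = 30, mu_m = 4, mu_p = 4,
                     P0_auto = 300, n_auto = 6, tau_auto = 1, tau_LI = 1,
                     rows = 1, cols = 1, t_end = 60, noise_on = FALSE,
                     seed = 1)
  sim <- simulate_her6(pp)
  x <- sim$p[1, sim$times > 30]
  tt <- sim$times[sim$times > 30]
  # brute-force peak detection
  pk <- which(diff(sign(diff(x))) == -2) + 1
  expect_gt(length(pk), 3)
  period <- mean(diff(tt[pk]))
  expect_gt(period, 2 * pp$tau_auto)
  # sustained, not decaying
  amp <- diff(range(x))
  expect_gt(amp / mean(x), 0.2)
})

test_that("a single coupled cell reduces exactly to the uncoupled model", {
  pc <- model_params(rows = 1, cols = 1, t_end = 10, coupled = TRUE, seed = 3)
  pu <- model_params(rows = 1, cols = 1, t_end = 10, coupled = FALSE, seed = 3)
  expect_identical(simulate_her6(pc)$p, simulate_her6(pu)$p)
})

test_that("halving dt leaves the stationary variance unchanged within Monte-Carlo error", {
  v_of <- function(dt, seed) {
    pp <- model_params(alpha_m = 200, alpha_p = 20, mu_m = 3, mu_p = 3,
                       P0_auto = 800, n_auto = 2, tau_auto = 0.2,
                       tau_LI = 0.2, rows = 4, cols = 4, t_end = 30,
                       dt = dt, seed = seed)
    sim <- simulate_her6(pp)
    x <- sim$p[, sim$times >= 15]
    mean(apply(x, 1, var))
  }
  v1 <- sapply(1:6, function(s) v_of(1 / 60, s))
  v2 <- sapply(1:6, function(s) v_of(1 / 120, 100 + s))
  expect_lt(abs(mean(v1) - mean(v2)) / mean(v1), 0.25)
})

test_that("track export is tidy and respects thinning and burn-in", {
  sim <- simulate_her6(tiny_params())
  tt <- as_track_table(sim, every = 6, from_time = 5)
  expect_named(tt, c("cell_id", "time", "signal", "mrna"))
  expect_true(all(tt$time >= 5))
  expect_equal(length(unique(tt$cell_id)), 4)
  expect_equal(diff(sort(unique(tt$time)))[1], 0.1, tolerance = 1e-9)
})
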