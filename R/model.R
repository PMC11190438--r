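#' Model parameters for the delayed stochastic Her6 model
#'
#' Collects every rate constant, Hill parameter, delay and integration
#' setting of the delayed negative-feedback model, in single-cell
#' (uncoupled, `coupled = FALSE`) or lattice (Notch-Delta lateral
#' inhibition, `coupled = TRUE`) form. Per cell, mRNA is produced at rate
#' `alpha_m * H_auto * H_LI` where `H_auto` is the delayed autoinhibition
#' Hill function of the cell's own protein and `H_LI` the delayed lateral
#' inhibition Hill function of the mean neighbour protein (identically 1
#' when uncoupled); protein is translated at `alpha_p` per mRNA. Both
#' species degrade linearly.
#'
#' @param alpha_m mRNA synthesis rate (molecules/h).
#' @param alpha_p Protein synthesis rate (1/h per mRNA).
#' @param mu_m mRNA degradation rate (1/h).
#' @param mu_p Protein degradation rate (1/h).
#' @param degradation_multiplier Dimensionless scale applied to `mu_p`
#'   only (1 = normal stability, 1.1 = destabilised protein).
#' @param P0_auto,n_auto Autoinhibition repression threshold (molecules)
#'   and Hill coefficient (>= 1).
#' @param tau_auto Autoinhibition delay (h).
#' @param P0_LI,n_LI,tau_LI Lateral-inhibition threshold, Hill
#'   coefficient and delay.
#' @param coupled Couple cells by lateral inhibition (Model 2) or not
#'   (Model 1).
#' @param rows,cols Lattice dimensions in cells.
#' @param periodic Wrap the lattice at its boundary.
#' @param dt Integration step (h); must be smaller than both delays.
#' @param t_end Simulated duration (h).
#' @param noise_on Include chemical Langevin noise.
#' @param seed Integer RNG seed (`NA` to draw one at simulation time).
#' @return An object of class `model_params` (a validated list).
#' @examples
#' p <- model_params(coupled = TRUE, rows = 4, cols = 4, t_end = 10)
#' deterministic_steady_state(p)
#' @export
model_params <- function(alpha_m = 600, alpha_p = 40, mu_m = 3.8,
                         mu_p = 3.8, degradation_multiplier = 1,
                         P0_auto = 1500, n_auto = 4, tau_auto = 0.6,
                         P0_LI = 1500, n_LI = 4, tau_LI = 0.6,
                         coupled = FALSE, rows = 10, cols = 6,
                         periodic = FALSE, dt = 1 / 60, t_end = 100,
                         noise_on = TRUE, seed = NA_integer_) {
  alpha_m <- unname(alpha_m); alpha_p <- unname(alpha_p)
  mu_m <- unname(mu_m); mu_p <- unname(mu_p)
  degradation_multiplier <- unname(degradation_multiplier)
  P0_auto <- unname(P0_auto); n_auto <- unname(n_auto)
  tau_auto <- unname(tau_auto)
  P0_LI <- unname(P0_LI); n_LI <- unname(n_LI); tau_LI <- unname(tau_LI)
  rates <- c(alpha_m = alpha_m, alpha_p = alpha_p, mu_m = mu_m, mu_p = mu_p,
             P0_auto = P0_auto, tau_auto = tau_auto, P0_LI = P0_LI,
             tau_LI = tau_LI, degradation_multiplier = degradation_multiplier)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates, thresholds, delays and multipliers must be finite and > 0")
  }
  if (n_auto < 1 || n_LI < 1) stop("Hill coefficients must be >= 1")
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0")
  if (dt >= min(tau_auto, tau_LI)) {
    stop("dt must be smaller than both delays")
  }
  if (rows * cols < 1) stop("lattice must contain at least one cell")

  structure(
    list(alpha_m = alpha_m, alpha_p = alpha_p, mu_m = mu_m, mu_p = mu_p,
         degradation_multiplier = degradation_multiplier,
         P0_auto = P0_auto, n_auto = n_auto, tau_auto = tau_auto,
         P0_LI = P0_LI, n_LI = n_LI, tau_LI = tau_LI,
         coupled = isTRUE(coupled), rows = as.integer(rows),
         cols = as.integer(cols), periodic = isTRUE(periodic),
         dt = dt, t_end = t_end, noise_on = isTRUE(noise_on),
         seed = if (is.na(seed)) NA_integer_ else as.integer(seed)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    paste0("<model_params %s, %dx%d grid>\n",
           "  alpha_m=%.3g alpha_p=%.3g mu_m=%.3g mu_p=%.3g (x%.2f)\n",
           "  auto: P0=%.3g n=%.3g tau=%.3g h | LI: P0=%.3g n=%.3g tau=%.3g h\n",
           "  dt=%.4g h, t_end=%.3g h, noise=%s, seed=%s\n"),
    if (x$coupled) "coupled (Model 2)" else "uncoupled (Model 1)",
    x$rows, x$cols, x$alpha_m, x$alpha_p, x$mu_m, x$mu_p,
    x$degradation_multiplier, x$P0_auto, x$n_auto, x$tau_auto,
    x$P0_LI, x$n_LI, x$tau_LI, x$dt, x$t_end, x$noise_on,
    ifelse(is.na(x$seed), "<unset>", x$seed)))
  invisible(x)
}

# effective protein degradation rate including the stability multiplier
mu_p_eff <- function(params) params$mu_p * params$degradation_multiplier

#' Repressive Hill functions
#'
#' `hill_auto()` is the delayed autoinhibition term
#' `1 / (1 + (p / P0)^n)` evaluated at the cell's own delayed protein;
#' `hill_li()` is the same form evaluated at the delayed mean neighbour
#' protein (lateral inhibition). Both are strictly decreasing, equal to 1
#' at zero protein and 1/2 at the repression threshold.
#'
#' @param p,p_bar Delayed protein abundance (own cell / neighbour mean);
#'   must be finite and non-negative.
#' @param P0 Repression threshold (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Repression factor in (0, 1].
#' @examples
#' hill_auto(200, 100, 4) # 1 / (1 + 2^4)
#' @export
hill_auto <- function(p, P0, n) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("protein abundance must be finite and >= 0 (corrupted state?)")
  }
  stopifnot(P0 > 0, n >= 1)
  1 / (1 + (p / P0)^n)
}

#' @rdname hill_auto
#' @export
hill_li <- function(p_bar, P0, n) hill_auto(p_bar, P0, n)

#' Chemical Langevin noise increments
#'
#' Draws one Euler-Maruyama noise increment per species: zero-mean
#' Gaussian with variance `(production + degradation) * dt`, the chemical
#' Langevin scaling by the number of reaction events per step. With
#' `noise_on = FALSE` (or all propensities zero) the increments are
#' exactly zero.
#'
#' @param m,p Current mRNA and protein abundance (>= 0).
#' @param production_m,production_p Production propensities (1/h), i.e.
#'   `alpha_m * H_auto * H_LI` and `alpha_p * m`.
#' @param params A [model_params()]; supplies `mu_m`, effective `mu_p`,
#'   `dt` and `noise_on`.
#' @return List with numeric `eta_m` and `eta_p` (same length as `m`).
#' @export
langevin_noise <- function(m, p, production_m, production_p, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(m < 0) || any(p < 0) || any(production_m < 0) ||
      any(production_p < 0)) {
    stop("negative abundance or propensity")
  }
  var_m <- (production_m + params$mu_m * m) * params$dt
  var_p <- (production_p + mu_p_eff(params) * p) * params$dt
  if (!params$noise_on) {
    return(list(eta_m = numeric(length(m)) , eta_p = numeric(length(p))))
  }
  list(eta_m = rnorm(length(m), 0, sqrt(var_m)),
       eta_p = rnorm(length(p), 0, sqrt(var_p)))
}

#' Deterministic fixed point of the model
#'
#' Solves the algebraic steady state of the noise-free equations:
#' `alpha_m * H_auto(p*) * H_LI(p*) = mu_m * m*` and
#' `alpha_p * m* = mu_p * p*`. For the uncoupled model `H_LI` is 1; for
#' the homogeneous coupled case the neighbour mean equals the cell's own
#' protein. The composite map is monotone, so the root is unique.
#'
#' @param params A [model_params()].
#' @param coupled Solve the homogeneous coupled system (`H_LI(p)`
#'   included) or the uncoupled one. Defaults to `params$coupled`.
#' @return Named numeric vector `c(m, p)`.
#' @export
deterministic_steady_state <- function(params, coupled = params$coupled) {
  stopifnot(inherits(params, "model_params"))
  mu_p <- mu_p_eff(params)
  A <- params$alpha_m * params$alpha_p / (params$mu_m * mu_p)
  f <- function(p) {
    h <- hill_auto(p, params$P0_auto, params$n_auto)
    if (coupled) h <- h * hill_li(p, params$P0_LI, params$n_LI)
    A * h - p
  }
  if (f(0) <= 0) return(c(m = 0, p = 0))
  root <- uniroot(f, c(0, A), tol = .Machine$double.eps^0.75)$root
  c(m = mu_p * root / params$alpha_p, p = root)
}

#' Simulate the delayed stochastic model
#'
#' Integrates the model with the Euler-Maruyama method, reading delayed
#' Hill terms from the stored trajectory (constant history before t = 0)
#' and clipping negative excursions to zero. The initial state defaults
#' to per-cell `uniform(0.5, 1.5)` multiples of the uncoupled
#' deterministic fixed point, which avoids artificial synchrony while
#' keeping burn-in short. The RNG state of the session is left untouched;
#' the seed actually used is recorded in the result.
#'
#' @param params A [model_params()].
#' @param history Optional list with numeric vectors `m0` and `p0` (one
#'   value per cell) giving the constant pre-simulation history.
#' @return Object of class `her6_sim`: `times` (h), matrices `m` and `p`
#'   (cells x time points), the `lattice`, `params`, `seed` and
#'   `n_clipped` (count of negative-state clips).
#' @examples
#' p <- model_params(rows = 2, cols = 2, t_end = 5, seed = 1)
#' s <- simulate_her6(p)
#' dim(s$p)
#' @export
simulate_her6 <- function(params, history = NULL) {
  stopifnot(inherits(params, "model_params"))
  lat <- hex_lattice(params$rows, params$cols, params$periodic)
  n_steps <- round(params$t_end / params$dt)
  if (n_steps < 1) stop("t_end too short for one step of dt")

  tau_a <- round(params$tau_auto / params$dt)
  tau_l <- round(params$tau_LI / params$dt)
  if (abs(tau_a * params$dt - params$tau_auto) > params$dt / 2 + 1e-12 ||
      abs(tau_l * params$dt - params$tau_LI) > params$dt / 2 + 1e-12) {
    stop("delay is not representable on the dt grid")
  }

  seed <- params$seed
  if (is.na(seed)) seed <- sample.int(.Machine$integer.max, 1)

  res <- withr::with_seed(seed, {
    if (is.null(history)) {
      ss <- deterministic_steady_state(params, coupled = FALSE)
      nc <- lat$n_cells
      history <- list(m0 = runif(nc, 0.5, 1.5) * ss[["m"]],
                      p0 = runif(nc, 0.5, 1.5) * ss[["p"]])
    }
    stopifnot(length(history$m0) == lat$n_cells,
              length(history$p0) == lat$n_cells)
    simulate_cpp(history$m0, history$p0,
                 lapply(lat$neighbours, function(v) v - 1L),
                 params$alpha_m, params$alpha_p, params$mu_m,
                 mu_p_eff(params), params$P0_auto, params$n_auto,
                 params$P0_LI, params$n_LI, tau_a, tau_l, params$coupled,
                 params$dt, n_steps, params$noise_on)
  })

  rownames(res$m) <- rownames(res$p) <- lat$cell_ids
  structure(
    list(times = seq(0, by = params$dt, length.out = n_steps + 1),
         m = res$m, p = res$p, lattice = lat, params = params,
         seed = seed, n_clipped = res$n_clipped),
    class = "her6_sim"
  )
}

#' @export
print.her6_sim <- function(x, ...) {
  cat(sprintf("<her6_sim %d cells x %d time points (0-%.3g h), seed %d>\n",
              nrow(x$p), ncol(x$p), max(x$times), x$seed))
  invisible(x)
}

#' Export a simulation as a tidy track table
#'
#' Converts per-cell trajectories into the long-format table the track
#' analysis pipeline reads: one row per cell per time point with the
#' protein level as `signal` and mRNA as `mrna`. Optionally thins time to
#' mimic an imaging cadence.
#'
#' @param sim A [simulate_her6()] result.
#' @param every Keep every `every`-th time point.
#' @param from_time Drop time points before this time (h); useful for
#'   discarding burn-in.
#' @return A tibble with columns `cell_id`, `time`, `signal`, `mrna`.
#' @export
as_track_table <- function(sim, every = 1L, from_time = 0) {
  stopifnot(inherits(sim, "her6_sim"))
  keep <- which(sim$times >= from_time)
  keep <- keep[seq(1L, length(keep), by = every)]
  tibble::tibble(
    cell_id = rep(sim$lattice$cell_ids, times = length(keep)),
    time = rep(sim$times[keep], each = nrow(sim$p)),
    signal = as.vector(sim$p[, keep]),
    mrna = as.vector(sim$m[, keep])
  )
}
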