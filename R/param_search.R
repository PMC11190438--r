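#' Search space for the parameter exploration
#'
#' Box bounds for the free model parameters explored by
#' [pattern_search()]. Rates and repression thresholds are searched on a
#' log10 scale (their plausible ranges span orders of magnitude), Hill
#' coefficients and delays on a linear scale. The default box is a
#' stand-in bracketing the biology of ultradian Her/Hes oscillators:
#' delays of 0.1-1 h keep 1-3 h periods reachable, protein degradation
#' of 1-8/h spans half-lives from minutes to tens of minutes, repression
#' thresholds span 1e2-1e4 molecules and Hill coefficients 2-6.
#'
#' @param lower,upper Named numeric vectors of bounds (same names).
#' @param log10_scale Named logical vector: search this parameter in
#'   log10 space.
#' @return Object of class `search_space`.
#' @export
search_space <- function(lower, upper, log10_scale) {
  stopifnot(identical(names(lower), names(upper)),
            identical(names(lower), names(log10_scale)),
            all(lower > 0), all(lower < upper))
  structure(list(lower = lower, upper = upper, log10_scale = log10_scale,
                 names = names(lower)),
            class = "search_space")
}

#' @rdname search_space
#' @export
default_search_space <- function() {
  search_space(
    lower = c(alpha_m = 10, alpha_p = 2, mu_m = 0.5, mu_p = 1,
              P0_auto = 1e2, n_auto = 2, tau_auto = 0.1,
              P0_LI = 1e2, n_LI = 2, tau_LI = 0.1),
    upper = c(alpha_m = 1000, alpha_p = 100, mu_m = 8, mu_p = 8,
              P0_auto = 1e4, n_auto = 6, tau_auto = 1,
              P0_LI = 1e4, n_LI = 6, tau_LI = 1),
    log10_scale = c(alpha_m = TRUE, alpha_p = TRUE, mu_m = TRUE, mu_p = TRUE,
                    P0_auto = TRUE, n_auto = FALSE, tau_auto = FALSE,
                    P0_LI = TRUE, n_LI = FALSE, tau_LI = FALSE)
  )
}

# map a point in the unit cube to parameter space and back
space_from_unit <- function(u, space) {
  lo <- ifelse(space$log10_scale, log10(space$lower), space$lower)
  hi <- ifelse(space$log10_scale, log10(space$upper), space$upper)
  v <- lo + u * (hi - lo)
  setNames(ifelse(space$log10_scale, 10^v, v), space$names)
}

#' Simulation settings for the objective function
#'
#' @param coupled Evaluate the lattice-coupled model (Model 2) or the
#'   uncoupled one (Model 1).
#' @param rows,cols Lattice dimensions.
#' @param t_end Simulation length (h).
#' @param dt Integration step (h).
#' @param burn_fraction Leading fraction of each simulation discarded
#'   before statistics.
#' @param multipliers The two protein-stability conditions compared.
#' @param shared_seed Use the same seed (same noise realisation and
#'   initial conditions) for both multipliers of an evaluation.
#' @param noise_on Simulate with chemical Langevin noise (the study
#'   condition); `FALSE` gives deterministic trajectories, useful for
#'   sanity checks of the objective.
#' @return A list of class `sim_settings`.
#' @export
sim_settings <- function(coupled = TRUE, rows = 10, cols = 6, t_end = 100,
                         dt = 1 / 60, burn_fraction = 0.5,
                         multipliers = c(1, 1.1), shared_seed = TRUE,
                         noise_on = TRUE) {
  stopifnot(length(multipliers) == 2, burn_fraction >= 0, burn_fraction < 1)
  structure(list(coupled = coupled, rows = rows, cols = cols, t_end = t_end,
                 dt = dt, burn_fraction = burn_fraction,
                 multipliers = multipliers, shared_seed = shared_seed,
                 noise_on = noise_on),
            class = "sim_settings")
}

params_from_theta <- function(theta, settings, multiplier, seed) {
  model_params(
    alpha_m = theta[["alpha_m"]], alpha_p = theta[["alpha_p"]],
    mu_m = theta[["mu_m"]], mu_p = theta[["mu_p"]],
    degradation_multiplier = multiplier,
    P0_auto = theta[["P0_auto"]], n_auto = theta[["n_auto"]],
    tau_auto = theta[["tau_auto"]], P0_LI = theta[["P0_LI"]],
    n_LI = theta[["n_LI"]], tau_LI = theta[["tau_LI"]],
    coupled = settings$coupled, rows = settings$rows, cols = settings$cols,
    dt = settings$dt, t_end = settings$t_end,
    noise_on = settings$noise_on %||% TRUE, seed = seed
  )
}

sim_stat_window <- function(sim, settings) {
  sim$p[, sim$times >= settings$burn_fraction * settings$t_end, drop = FALSE]
}

#' CV-difference objective for the heterogeneity search
#'
#' Simulates the model at the two protein-stability conditions (1x and
#' 1.1x degradation by default) with otherwise identical parameters and
#' returns `error = CV(1x) - CV(1.1x)`, where CV is the population
#' coefficient of variation over all cells and retained time points.
#' More negative errors mean destabilising the protein increases
#' population heterogeneity more.
#'
#' @param theta Named parameter vector (see [default_search_space()] for
#'   names).
#' @param settings A [sim_settings()].
#' @param seed Seed for the simulation pair.
#' @return The error, with attributes `cv` (per multiplier) and
#'   `mean_protein` (at the first multiplier).
#' @export
objective_error <- function(theta, settings = sim_settings(), seed = 1L) {
  cvs <- vapply(settings$multipliers, function(dm) {
    s <- if (settings$shared_seed) seed else seed + match(dm, settings$multipliers)
    sim <- tryCatch(
      simulate_her6(params_from_theta(theta, settings, dm, s)),
      error = function(e) stop("simulation failed at multiplier ", dm, ": ",
                               conditionMessage(e))
    )
    x <- sim_stat_window(sim, settings)
    c(population_cv(as.vector(x)), mean(x))
  }, numeric(2))
  err <- cvs[1, 1] - cvs[1, 2]
  attr(err, "cv") <- setNames(cvs[1, ], paste0("x", settings$multipliers))
  attr(err, "mean_protein") <- cvs[2, 1]
  err
}

# deterministic per-evaluation seed derived from (master seed, run, eval)
derive_seed <- function(master, run, eval) {
  as.integer((as.double(master) * 2654435 + run * 97561 + eval * 7919) %%
               2147483647) + 1L
}

#' Generalised pattern search over the parameter box
#'
#' Runs `n_runs` independent pattern searches, each from a uniform
#' random start in the box, minimising [objective_error()]. The search
#' polls the 2n coordinate directions in the (log-transformed,
#' normalised) unit cube with an initial mesh of 0.25, doubling the mesh
#' on a successful poll and halving it on failure, and stops at
#' `max_evals` objective evaluations or when the mesh drops below
#' `mesh_tol`. Every evaluation uses a fresh seed derived from the
#' master seed, run index and evaluation counter, so the stochastic
#' objective is not overfitted to one noise realisation.
#'
#' @param space A [search_space()].
#' @param n_runs Number of optimiser restarts.
#' @param max_evals Objective-evaluation budget per run.
#' @param settings A [sim_settings()].
#' @param seed Master seed.
#' @param mesh_tol Stop when the mesh size falls below this.
#' @param objective Objective function `f(theta, settings, seed)`;
#'   replaceable for testing.
#' @return A list of class `pattern_search_runs`; each element records
#'   the start point, all evaluated points (`evals` tibble), the best
#'   (`final`) point, its error and recorded summary attributes, and the
#'   evaluation count.
#' @export
pattern_search <- function(space = default_search_space(), n_runs = 1,
                           max_evals = 500, settings = sim_settings(),
                           seed = 1L, mesh_tol = 1e-3,
                           objective = objective_error) {
  stopifnot(n_runs >= 0)
  runs <- vector("list", n_runs)
  d <- length(space$names)

  for (r in seq_len(n_runs)) {
    u0 <- withr::with_seed(derive_seed(seed, r, 0L),
                           runif(d))
    n_eval <- 0L
    evals <- list()
    f_of <- function(u) {
      n_eval <<- n_eval + 1L
      th <- space_from_unit(u, space)
      e <- objective(th, settings, derive_seed(seed, r, n_eval))
      evals[[n_eval]] <<- c(th, error = as.numeric(e),
                            mean_protein = attr(e, "mean_protein") %||% NA_real_,
                            cv_1 = unname(attr(e, "cv")[1] %||% NA_real_),
                            cv_2 = unname(attr(e, "cv")[2] %||% NA_real_))
      as.numeric(e)
    }

    u <- pmin(pmax(u0, 0), 1)
    f_best <- f_of(u)
    i_best <- n_eval
    mesh <- 0.25
    while (n_eval < max_evals && mesh >= mesh_tol) {
      improved <- FALSE
      for (dir in seq_len(2 * d)) {
        if (n_eval >= max_evals) break
        j <- (dir + 1) %/% 2
        sgn <- if (dir %% 2 == 1) 1 else -1
        cand <- u
        cand[j] <- min(max(cand[j] + sgn * mesh, 0), 1)
        if (cand[j] == u[j]) next
        f_new <- f_of(cand)
        if (f_new < f_best) {
          u <- cand; f_best <- f_new; i_best <- n_eval
          improved <- TRUE
          break # opportunistic polling
        }
      }
      mesh <- if (improved) min(2 * mesh, 0.5) else mesh / 2
    }

    ev <- tibble::as_tibble(do.call(rbind, evals))
    best_row <- ev[i_best, ]
    runs[[r]] <- list(
      run = r, start = space_from_unit(u0, space), evals = ev,
      final = setNames(as.numeric(best_row[1, space$names]), space$names),
      error = best_row$error[[1]], mean_protein = best_row$mean_protein[[1]],
      cv = c(best_row$cv_1[[1]], best_row$cv_2[[1]]),
      n_evals = n_eval, seed = derive_seed(seed, r, 0L)
    )
  }
  structure(runs, class = "pattern_search_runs",
            settings = settings, space = space, seed = seed)
}

#' @export
print.pattern_search_runs <- function(x, ...) {
  errs <- vapply(x, `[[`, numeric(1), "error")
  cat(sprintf("<pattern_search_runs: %d runs, best error %.4f>\n",
              length(x), if (length(errs)) min(errs) else NA))
  invisible(x)
}

#' Filter optimiser runs into accepted parameter sets
#'
#' Keeps final points whose recorded error is below `error_threshold`
#' and whose mean protein abundance at the normal-stability condition
#' exceeds `min_expression`, then (optionally) recomputes the full suite
#' of single-cell summary statistics at both stability conditions via
#' [summarise_param_set()].
#'
#' @param runs A [pattern_search()] result.
#' @param error_threshold Acceptance ceiling on the error (default
#'   -0.25: a definite CV increase).
#' @param min_expression Acceptance floor on mean protein abundance at
#'   1x (default 2000).
#' @param summarise Attach per-multiplier summary statistics.
#' @param seed Seed for the summary simulations.
#' @param ... Passed to [summarise_param_set()].
#' @return A tibble with one row per accepted set: the parameter vector,
#'   `error`, `mean_protein` and, when summarised, CV / median CV_t /
#'   median period / median coherence at both multipliers.
#' @export
filter_accepted <- function(runs, error_threshold = -0.25,
                            min_expression = 2000, summarise = TRUE,
                            seed = 1L, ...) {
  stopifnot(inherits(runs, "pattern_search_runs"))
  settings <- attr(runs, "settings")
  keep <- Filter(function(r) {
    is.finite(r$error) && r$error < error_threshold &&
      is.finite(r$mean_protein) && r$mean_protein > min_expression
  }, runs)
  if (length(keep) == 0) {
    return(tibble::tibble())
  }
  rows <- lapply(keep, function(r) {
    base <- tibble::as_tibble(as.list(c(r$final, error = r$error,
                                        mean_protein = r$mean_protein)))
    base$run <- r$run
    if (summarise) {
      base <- dplyr::bind_cols(
        base, summarise_param_set(r$final, settings,
                                  seed = derive_seed(seed, r$run, 999999L),
                                  ...))
    }
    base
  })
  dplyr::bind_rows(rows)
}

#' Summary statistics of a parameter set at both stability conditions
#'
#' Simulates the model at each degradation multiplier (shared seed),
#' discards the burn-in, and reports the population CV, the median
#' per-cell time-series CV, the median per-cell wavelet dominant period
#' and the median per-cell periodogram coherence. Spectral statistics
#' are computed on time series thinned to the imaging cadence
#' (`spectral_dt`, default 6 min).
#'
#' @param theta Named parameter vector.
#' @param settings A [sim_settings()].
#' @param seed Simulation seed.
#' @param spectral_dt Sampling interval used for period and coherence
#'   (h).
#' @param n_perm Wavelet permutation-null size per cell.
#' @return One-row tibble: `cv_x1`, `cv_x2`, `cvt_x1`, `cvt_x2`,
#'   `period_x1`, `period_x2`, `coherence_x1`, `coherence_x2`,
#'   `mean_protein_x1`, `mean_protein_x2`.
#' @export
summarise_param_set <- function(theta, settings = sim_settings(), seed = 1L,
                                spectral_dt = 0.1, n_perm = 100) {
  out <- lapply(seq_along(settings$multipliers), function(i) {
    dm <- settings$multipliers[i]
    sim <- simulate_her6(params_from_theta(theta, settings, dm, seed))
    x <- sim_stat_window(sim, settings)
    thin <- max(1L, round(spectral_dt / settings$dt))
    xs <- x[, seq(1, ncol(x), by = thin), drop = FALSE]
    dts <- settings$dt * thin
    per_cell <- lapply(seq_len(nrow(xs)), function(c) {
      y <- xs[c, ]
      if (sd(y) == 0 || mean(y) <= 0) {
        return(c(cvt = NA_real_, per = NA_real_, coh = NA_real_))
      }
      wp <- wavelet_period(y - mean(y), dts, n_perm = n_perm,
                           seed = derive_seed(seed, c, i))
      c(cvt = sd(y) / mean(y),
        per = wp$mean_period,
        coh = coherence(y - mean(y), dts)$coherence)
    })
    pc <- do.call(rbind, per_cell)
    c(cv = population_cv(as.vector(x)),
      cvt = median(pc[, "cvt"], na.rm = TRUE),
      period = median(pc[, "per"], na.rm = TRUE),
      coherence = median(pc[, "coh"], na.rm = TRUE),
      mean_protein = mean(x))
  })
  v <- c(out[[1]], out[[2]])
  names(v) <- c(paste0(c("cv", "cvt", "period", "coherence", "mean_protein"),
                       "_x1"),
                paste0(c("cv", "cvt", "period", "coherence", "mean_protein"),
                       "_x2"))
  tibble::as_tibble(as.list(v))
}
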