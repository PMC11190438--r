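#' Specification for synthetic single-cell track populations
#'
#' Describes a population of reporter tracks with known ground truth:
#' a fraction of cells oscillate (exact draws from the OUosc covariance,
#' or pure sinusoids when `osc_alpha = 0`), the rest fluctuate
#' aperiodically (OU draws); every cell carries a multiplicative
#' exponential downregulation trend, multiplicative lognormal
#' measurement noise and a stable nuclear-control channel. Matched
#' background tracks (no biological signal, measurement noise only) are
#' generated alongside for technical-noise calibration.
#'
#' Defaults emulate ultradian reporter imaging in neural progenitors:
#' 6-min sampling, 10 h tracks, a 30 percent oscillator fraction with a
#' 1.9 h period, peak-to-trough fold-changes around 1.6, and mild
#' developmental downregulation.
#'
#' @param n_cells Number of tracked cells.
#' @param fraction_oscillatory Fraction of cells in the oscillatory
#'   class.
#' @param period_h Oscillation period (h).
#' @param osc_alpha OUosc bandwidth (1/h): quality of oscillation, lower
#'   is cleaner; 0 gives deterministic sinusoids.
#' @param ou_alpha OU bandwidth (1/h) of the aperiodic class.
#' @param baseline Mean reporter intensity (a.u.).
#' @param fold_change Target typical peak-to-trough fold-change.
#' @param trend_ratio Relative trend ratio enforced over the track
#'   (last/first of the noise-free signal; < 1 is downregulation).
#' @param noise_cv Multiplicative measurement noise CV on the reporter.
#' @param control_level Nuclear-control channel mean intensity (a.u.).
#' @param control_noise_cv Measurement noise CV on the control channel.
#' @param dt Sampling interval (h).
#' @param duration_h Track duration (h).
#' @param n_background Number of background tracks.
#' @param seed RNG seed.
#' @return Object of class `track_spec`.
#' @export
track_spec <- function(n_cells = 60, fraction_oscillatory = 0.3,
                       period_h = 1.9, osc_alpha = 0.3, ou_alpha = 1.5,
                       baseline = 100, fold_change = 1.6, trend_ratio = 0.7,
                       noise_cv = 0.05, control_level = 500,
                       control_noise_cv = 0.05, dt = 0.1, duration_h = 10,
                       n_background = 10, seed = 1L) {
  stopifnot(n_cells >= 0, fraction_oscillatory >= 0,
            fraction_oscillatory <= 1, period_h > 0, osc_alpha >= 0,
            ou_alpha > 0, baseline > 0, trend_ratio > 0, noise_cv >= 0,
            control_level > 0, control_noise_cv >= 0, dt > 0,
            duration_h >= 3)
  if (fold_change < 1) stop("fold_change must be >= 1")
  structure(as.list(environment()), class = "track_spec")
}

# exact zero-mean GP draws with covariance sigma^2 exp(-a|tau|) cos(b tau)
ou_osc_draws <- function(n_draws, times, alpha, beta = 0, sigma2 = 1) {
  tau <- abs(outer(times, times, "-"))
  K <- sigma2 * exp(-alpha * tau) * cos(beta * tau)
  diag(K) <- diag(K) + 1e-9 * sigma2
  MASS::mvrnorm(n_draws, mu = numeric(length(times)), Sigma = K)
}

# lognormal multiplicative noise factors with unit mean
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdl^2 / 2, sdl))
}

#' Generate a synthetic track population with ground truth
#'
#' @param spec A [track_spec()].
#' @return A list: `tracks` (tibble `cell_id`, `time`, `signal`,
#'   `control`), `background` (same shape; technical noise only) and
#'   `labels` (tibble `cell_id`, `class`, `period_h`, `trend_ratio`,
#'   `true_fold` — the realised noise-free maximum peak-to-trough
#'   fold-change of each track).
#' @examples
#' gen <- generate_tracks(track_spec(n_cells = 4, seed = 2))
#' gen$labels
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  times <- seq(0, spec$duration_h, by = spec$dt)
  nt <- length(times)
  n_osc <- round(spec$n_cells * spec$fraction_oscillatory)
  classes <- rep(c("oscillatory", "aperiodic"),
                 c(n_osc, spec$n_cells - n_osc))
  # relative half-amplitude giving the target fold (1+a)/(1-a);
  # stochastic draws are scaled so a typical track extreme (~2.3 sd over
  # a 100-point track) reaches +/- a
  a <- (spec$fold_change - 1) / (spec$fold_change + 1)

  withr::with_seed(spec$seed, {
    s_rel <- matrix(0, spec$n_cells, nt)
    if (n_osc > 0) {
      if (spec$osc_alpha == 0) {
        phase <- runif(n_osc, 0, 2 * pi)
        for (i in seq_len(n_osc)) {
          s_rel[i, ] <- a * sin(2 * pi * times / spec$period_h + phase[i])
        }
      } else {
        z <- ou_osc_draws(n_osc, times, spec$osc_alpha,
                          2 * pi / spec$period_h)
        s_rel[seq_len(n_osc), ] <- (a / 2.3) * z
      }
    }
    if (spec$n_cells - n_osc > 0) {
      z <- ou_osc_draws(spec$n_cells - n_osc, times, spec$ou_alpha)
      s_rel[(n_osc + 1):spec$n_cells, ] <- (a / 2.3) * z
    }
    s_rel <- pmax(s_rel, -0.95)

    trend <- spec$trend_ratio^(times / spec$duration_h)
    ids <- sprintf("cell_%03d", seq_len(max(spec$n_cells, 1)))

    rows <- lapply(seq_len(spec$n_cells), function(i) {
      clean <- spec$baseline * trend * (1 + s_rel[i, ])
      tibble::tibble(
        cell_id = ids[i], time = times,
        signal = clean * lnoise(nt, spec$noise_cv),
        control = spec$control_level * lnoise(nt, spec$control_noise_cv)
      )
    })
    tracks <- dplyr::bind_rows(rows)

    bg <- dplyr::bind_rows(lapply(seq_len(spec$n_background), function(i) {
      tibble::tibble(
        cell_id = sprintf("bg_%03d", i), time = times,
        signal = spec$baseline * lnoise(nt, max(spec$noise_cv, 1e-4)),
        control = spec$control_level * lnoise(nt, spec$control_noise_cv)
      )
    }))

    true_fold <- vapply(seq_len(spec$n_cells), function(i) {
      clean <- trend * (1 + s_rel[i, ])
      (1 + max(s_rel[i, ])) / (1 + min(s_rel[i, ]))
    }, numeric(1))

    labels <- tibble::tibble(
      cell_id = ids[seq_len(spec$n_cells)], class = classes,
      period_h = ifelse(classes == "oscillatory", spec$period_h, NA_real_),
      trend_ratio = spec$trend_ratio, true_fold = true_fold
    )
    list(tracks = tracks, background = bg, labels = labels)
  })
}

#' Specification and generator for 3D nuclear snapshots
#'
#' Nuclei are placed as spatial doublets: pair centroids sit on a
#' jittered 3D lattice at `spacing_um`, and the two partners of a pair
#' lie a small fraction of the spacing apart, so each nucleus's nearest
#' neighbour is its partner and the pairwise intensity correlation is
#' exactly the Gaussian-copula `rho` (negative `rho` produces the
#' salt-and-pepper interspersion of high and low neighbours).
#' Venus-positive nuclei draw lognormal intensities around
#' `level_positive`, negatives around the background level; a separate
#' background intensity sample is returned for thresholding.
#'
#' @param n_nuclei Number of nuclei (rounded up to an even count).
#' @param spacing_um Centroid lattice spacing (micrometres).
#' @param rho Neighbour intensity correlation in `[-1, 1]`.
#' @param positive_fraction Fraction of Venus-positive nuclei.
#' @param level_positive Median Venus intensity of positives (a.u.).
#' @param bg_level Median background intensity (a.u.).
#' @param sdlog Lognormal spread of positive intensities.
#' @param bg_sdlog Lognormal spread of background.
#' @param n_background Size of the background sample.
#' @param seed RNG seed.
#' @return A list: `snapshot` (tibble `nucleus_id`, `x`, `y`, `z`,
#'   `venus`, `control`), `background` (numeric sample) and `truth`
#'   (list with `rho`, logical `positive`, integer `pair_id`).
#' @export
generate_snapshot <- function(n_nuclei = 1000, spacing_um = 10, rho = 0,
                              positive_fraction = 1, level_positive = 500,
                              bg_level = 100, sdlog = 0.3, bg_sdlog = 0.15,
                              n_background = 200, seed = 1L) {
  stopifnot(abs(rho) <= 1, spacing_um > 0, n_nuclei >= 2,
            positive_fraction >= 0, positive_fraction <= 1)
  n_pairs <- ceiling(n_nuclei / 2)
  n <- 2L * n_pairs

  withr::with_seed(seed, {
    k <- ceiling(n_pairs^(1 / 3))
    g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
    g <- g[seq_len(n_pairs), ] * spacing_um
    g <- g + matrix(runif(3 * n_pairs, -0.15, 0.15) * spacing_um,
                    ncol = 3)
    # partner offset: 1/4 of the spacing in a random direction
    dir <- matrix(rnorm(3 * n_pairs), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    off <- dir * (0.25 * spacing_um / 2)
    pos <- rbind(as.matrix(g) + off, as.matrix(g) - off)
    pair_id <- rep(seq_len(n_pairs), 2)

    z1 <- rnorm(n_pairs)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_pairs)
    zz <- c(z1, z2)
    positive <- runif(n) < positive_fraction
    venus <- ifelse(positive,
                    exp(log(level_positive) + sdlog * zz),
                    exp(log(bg_level) + bg_sdlog * rnorm(n)))
    snapshot <- tibble::tibble(
      nucleus_id = sprintf("nuc_%04d", seq_len(n)),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      venus = venus,
      control = exp(log(1000) + 0.1 * rnorm(n))
    )
    background <- exp(log(bg_level) + bg_sdlog * rnorm(n_background))
    list(snapshot = snapshot, background = background,
         truth = list(rho = rho, positive = positive, pair_id = pair_id))
  })
}

#' Generate a protein decay chase
#'
#' One-phase exponential decay tracks sampled the way a cycloheximide
#' chase is imaged (17-min frames for about 22 h by default), with
#' optional multiplicative measurement noise. Time is in minutes.
#'
#' @param half_life_min Protein half-life (min).
#' @param y0 Initial intensity (a.u.).
#' @param plateau Decay plateau (a.u.).
#' @param noise_cv Multiplicative measurement noise CV.
#' @param n_tracks Number of replicate tracks (0 gives an empty table).
#' @param interval_min Sampling interval (min).
#' @param duration_min Chase duration (min).
#' @param seed RNG seed.
#' @return Tibble with `cell_id`, `time` (min) and `signal`.
#' @export
generate_decay_chase <- function(half_life_min = 11, y0 = 1000, plateau = 0,
                                 noise_cv = 0, n_tracks = 1,
                                 interval_min = 17, duration_min = 1320,
                                 seed = 1L) {
  stopifnot(half_life_min > 0, n_tracks >= 0)
  times <- seq(0, duration_min, by = interval_min)
  k <- log(2) / half_life_min
  if (n_tracks == 0) {
    return(tibble::tibble(cell_id = character(), time = numeric(),
                          signal = numeric()))
  }
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_tracks), function(i) {
      clean <- plateau + (y0 - plateau) * exp(-k * times)
      tibble::tibble(cell_id = sprintf("decay_%03d", i), time = times,
                     signal = clean * lnoise(length(times), noise_cv))
    }))
  })
}
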