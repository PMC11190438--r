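#' Coefficient of variation of a population of intensities
#'
#' The ratio of the (sample, n-1 denominator) standard deviation to the
#' mean, the scale-free measure of expression heterogeneity used
#' throughout the package. For simulated tissue the values are typically
#' all protein levels from all cells and time points after burn-in.
#'
#' @param values Numeric vector with at least two finite values and a
#'   strictly positive mean.
#' @param denominator `"n-1"` (default, sample sd) or `"n"`.
#' @return The CV (dimensionless).
#' @examples
#' population_cv(c(1, 2, 3)) # 0.5
#' @export
population_cv <- function(values, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  mu <- mean(values)
  if (mu <= 0) stop("mean must be > 0 for a CV")
  s <- sd(values)
  if (denominator == "n") s <- s * sqrt((length(values) - 1) / length(values))
  s / mu
}

#' Per-cell time-series coefficient of variation
#'
#' CV of a single cell's intensity over time (sd over time divided by
#' mean over time). For model output, statistics are conventionally
#' computed on the final part of the simulation only (`last_fraction =
#' 0.5` discards the first half as burn-in).
#'
#' @param tracks A track table (`cell_id`, `time`, `signal`) or a bare
#'   numeric vector for a single cell.
#' @param last_fraction Fraction of the time series (from the end) to
#'   use; 1 uses everything.
#' @return A tibble with `cell_id` and `cv_t` (or a single number for
#'   vector input).
#' @export
timeseries_cv <- function(tracks, last_fraction = 1) {
  stopifnot(last_fraction > 0, last_fraction <= 1)
  one <- function(x) {
    n <- length(x)
    population_cv(x[seq.int(max(1L, n - ceiling(last_fraction * n) + 1L), n)])
  }
  if (is.numeric(tracks)) return(one(tracks))
  check_track_table(tracks)
  dplyr::summarise(dplyr::group_by(tracks, .data$cell_id),
                   cv_t = one(.data$signal), .groups = "drop")
}

#' Relative trend ratio of a track
#'
#' The last intensity divided by the first: 1 indicates steady
#' expression, below 1 downregulation over the track.
#'
#' @param tracks Track table or numeric vector (time-ordered).
#' @return Tibble with `cell_id` and `relative_trend`, or a number.
#' @export
relative_trend <- function(tracks) {
  one <- function(x) {
    if (x[1] <= 0) stop("first intensity must be > 0")
    x[length(x)] / x[1]
  }
  if (is.numeric(tracks)) return(one(tracks))
  check_track_table(tracks)
  dplyr::summarise(dplyr::group_by(tracks, .data$cell_id),
                   relative_trend = one(.data$signal), .groups = "drop")
}

#' Normalise the reporter channel to the nuclear control channel
#'
#' Pointwise division `signal / control`, which cancels multiplicative
#' acquisition artefacts shared by the two channels.
#'
#' @param tracks Track table with `signal` and `control` columns.
#' @return The track table with `signal` replaced by the normalised
#'   signal (the `control` column is retained).
#' @export
normalise_to_control <- function(tracks) {
  check_track_table(tracks, require = c("cell_id", "time", "signal", "control"))
  bad <- tracks$control <= 0
  if (any(bad)) {
    stop("control channel must be > 0 at all times; offending times: ",
         paste(utils::head(signif(tracks$time[bad], 4), 5), collapse = ", "))
  }
  dplyr::mutate(tracks, signal = .data$signal / .data$control)
}

# Gaussian-kernel local linear smoother. The bandwidth is set so the
# smoother's gain is 1/2 at the cut-off period `window`:
# sd = window * sqrt(log(2) / 2) / pi.
gauss_local_linear <- function(time, x, window) {
  as.vector(smoother_matrix(time, window) %*% x)
}

# the smoother is linear: trend = S x; exposed for covariance propagation
smoother_matrix <- function(time, window) {
  sigma <- window * sqrt(log(2) / 2) / pi
  d <- outer(time, time, "-") # d[i, j] = t_i - t_j
  w <- exp(-d^2 / (2 * sigma^2))
  s1 <- rowSums(w * (-d))
  s2 <- rowSums(w * d^2)
  den <- rowSums(w) * s2 - s1^2
  (w * (s2 + s1 * d)) / den
}

# detrending operator D = I - S (rows sum to zero; annihilates linear trends)
detrend_matrix <- function(time, window) {
  diag(length(time)) - smoother_matrix(time, window)
}

#' Remove slow trends from tracks
#'
#' Estimates a smooth trend with a Gaussian-kernel local linear smoother
#' whose bandwidth is chosen so that the smoother passes half of a
#' sinusoid at period `window_h` (and essentially all slower components),
#' then subtracts it. The default 4.5 h cut-off is three times the
#' expected ultradian period, so oscillations near 1.5 h pass through
#' almost unattenuated while developmental downregulation is removed.
#' Trend plus detrended reconstruct the input exactly.
#'
#' @param tracks Track table, or a numeric vector with `time` supplied.
#' @param window_h Cut-off timescale of the trend (h).
#' @param time Time vector, for vector input only.
#' @return For tables: the table with added `trend` and `detrended`
#'   columns. For vectors: a list with `trend` and `detrended`.
#' @export
detrend <- function(tracks, window_h = 4.5, time = NULL) {
  if (is.numeric(tracks)) {
    stopifnot(!is.null(time), length(time) == length(tracks))
    if (diff(range(time)) < window_h) {
      stop("track shorter than the detrending window")
    }
    tr <- gauss_local_linear(time, tracks, window_h)
    return(list(trend = tr, detrended = tracks - tr))
  }
  check_track_table(tracks)
  out <- dplyr::group_modify(dplyr::group_by(tracks, .data$cell_id),
    function(df, key) {
      if (diff(range(df$time)) < window_h) {
        stop("track ", key$cell_id, " shorter than the detrending window")
      }
      df$trend <- gauss_local_linear(df$time, df$signal, window_h)
      df$detrended <- df$signal - df$trend
      df
    })
  dplyr::ungroup(out)
}

# Analytic signal via FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Maximum peak-to-trough fold-change via the Hilbert transform
#'
#' Locates oscillation peaks and troughs as phase crossings of the
#' analytic signal of the detrended trace (peaks where the instantaneous
#' phase crosses 0, troughs where it crosses +/- pi), pairs subsequent
#' peak/trough events, evaluates the raw normalised signal at the paired
#' positions and returns the maximum peak/trough fold-change of the
#' track. Unpaired terminal extrema are dropped.
#'
#' @param normalised Raw normalised intensity values (time-ordered).
#' @param detrended Detrended values of the same track, same length.
#' @return The maximum fold-change (>= 1 in practice), or `NA` if the
#'   track contains no complete peak-trough pair.
#' @examples
#' t <- seq(0, 10, by = 0.1)
#' x <- 10 + 2 * sin(2 * pi * t / 2)
#' hilbert_fold_change(x, x - mean(x)) # 12 / 8 = 1.5
#' @export
hilbert_fold_change <- function(normalised, detrended) {
  stopifnot(length(normalised) == length(detrended))
  if (sd(detrended) == 0) return(NA_real_)
  phase <- Arg(analytic_signal(detrended))
  n <- length(phase)
  dphi <- diff(phase)
  # peaks: upward crossing of phase 0 (cos maximal); troughs: wrap through pi
  peaks <- which(phase[-n] < 0 & phase[-1] >= 0 & abs(dphi) < pi)
  troughs <- which(abs(dphi) > pi)
  ev <- rbind(
    if (length(peaks)) data.frame(i = peaks, type = "peak"),
    if (length(troughs)) data.frame(i = troughs, type = "trough")
  )
  if (is.null(ev) || nrow(ev) < 2) return(NA_real_)
  ev <- ev[order(ev$i), ]
  folds <- c()
  for (k in seq_len(nrow(ev) - 1)) {
    a <- ev[k, ]; b <- ev[k + 1, ]
    if (a$type == b$type) next
    pk <- if (a$type == "peak") a$i else b$i
    tr <- if (a$type == "trough") a$i else b$i
    if (normalised[tr] > 0) folds <- c(folds, normalised[pk] / normalised[tr])
  }
  if (length(folds) == 0) return(NA_real_)
  max(folds)
}

#' Periodogram coherence of a track
#'
#' Computes the raw (untapered) periodogram of a detrended, uniformly
#' sampled track, finds the dominant frequency, and reports coherence:
#' the fraction of total spectral power lying within +/- 10 percent of
#' the dominant frequency. A perfect sinusoid approaches 1; broadband
#' noise spreads power and scores low.
#'
#' @param x Detrended intensity values.
#' @param dt Sampling interval (h).
#' @param band Half-width of the band around the peak, as a fraction of
#'   the peak frequency.
#' @return Object of class `spectral_summary`: list with `frequencies`
#'   (1/h), `power`, `dominant_frequency`, `dominant_period` (h) and
#'   `coherence`.
#' @export
coherence <- function(x, dt, band = 0.1) {
  stopifnot(dt > 0)
  if (all(x == 0)) stop("all-zero track has no spectrum")
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2)) # positive frequencies only
  freq <- k / (n * dt)
  P <- P[k + 1]
  imax <- which.max(P)
  fpk <- freq[imax]
  in_band <- freq >= (1 - band) * fpk & freq <= (1 + band) * fpk
  structure(
    list(frequencies = freq, power = P, dominant_frequency = fpk,
         dominant_period = 1 / fpk, coherence = sum(P[in_band]) / sum(P)),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary: dominant period %.3g h, coherence %.3f>\n",
              x$dominant_period, x$coherence))
  invisible(x)
}

# Analytic Morlet continuous wavelet transform (FFT implementation,
# Torrence & Compo normalisation), centre frequency omega0 = 6.
morlet_cwt <- function(x, dt, periods, omega0 = 6) {
  n <- length(x)
  npad <- nextn(n, 2)
  xhat <- fft(c(x - mean(x), numeric(npad - n)))
  omega <- 2 * pi * c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad * dt)
  ff <- (4 * pi) / (omega0 + sqrt(2 + omega0^2)) # period = ff * scale
  scales <- periods / ff
  W <- matrix(0i, length(scales), n)
  for (s in seq_along(scales)) {
    psi <- pi^(-0.25) * sqrt(2 * pi * scales[s] / dt) *
      exp(-((scales[s] * omega - omega0)^2) / 2) * (omega > 0)
    W[s, ] <- (fft(xhat * psi, inverse = TRUE) / npad)[seq_len(n)]
  }
  W
}

#' Dominant period by continuous wavelet transform with a permutation null
#'
#' Computes the analytic Morlet continuous wavelet transform of a
#' uniformly sampled track, takes the period with the highest power at
#' each time point, and screens these against a permutation null: the
#' track is randomly shuffled `n_perm` times, each shuffle is
#' transformed, and the 95th percentile of null power at each period is
#' the significance threshold. The per-cell period is the mean of the
#' significant dominant periods.
#'
#' Track-level calibration: a track is deemed to contain genuine
#' periodicity only when its maximum wavelet power exceeds the
#' `probs` quantile of the null distribution of the maximum power
#' (the permutation global-max statistic), which fixes the track-level
#' false-positive rate at `1 - probs` by construction; otherwise the
#' mean period is reported missing.
#'
#' @param x Intensity values (detrended or trend-free).
#' @param dt Sampling interval (h).
#' @param periods Optional vector of analysis periods (h); defaults to a
#'   logarithmic grid from `4 * dt` to half the track duration, 16
#'   voices per octave.
#' @param n_perm Number of random permutations for the null.
#' @param probs Null quantile used as the power threshold.
#' @param seed Optional seed for the permutations.
#' @return Object of class `wavelet_period_result`: tibble `by_time`
#'   (`time`, `period`, `power`, `significant`), `mean_period` (NA when
#'   nothing is significant), `threshold` (per-period), `periods`.
#' @export
wavelet_period <- function(x, dt, periods = NULL, n_perm = 1000,
                           probs = 0.95, seed = NULL) {
  n <- length(x)
  stopifnot(n >= 8, dt > 0, n_perm >= 19)
  if (is.null(periods)) {
    pmax_ <- n * dt / 2
    pmin_ <- 4 * dt
    periods <- 2^seq(log2(pmin_), log2(pmax_), by = 1 / 16)
  }
  pow <- Mod(morlet_cwt(x, dt, periods))^2
  idx <- apply(pow, 2, which.max)
  dom_period <- periods[idx]
  dom_power <- pow[cbind(idx, seq_len(n))]

  draw <- function() {
    null_pow <- vapply(seq_len(n_perm), function(i) {
      Mod(morlet_cwt(sample(x), dt, periods))^2
    }, matrix(0, length(periods), n))
    list(per_freq = apply(null_pow, 1, quantile, probs = probs),
         gate = quantile(apply(null_pow, 3, max), probs = probs))
  }
  null <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  thr <- null$per_freq

  significant <- dom_power > thr[idx]
  track_periodic <- max(dom_power) > null$gate
  mean_period <- if (track_periodic && any(significant)) {
    mean(dom_period[significant])
  } else NA_real_
  structure(
    list(by_time = tibble::tibble(time = (seq_len(n) - 1) * dt,
                                  period = dom_period, power = dom_power,
                                  significant = significant),
         mean_period = mean_period, threshold = thr,
         gate_threshold = unname(null$gate), periods = periods),
    class = "wavelet_period_result"
  )
}

#' @export
print.wavelet_period_result <- function(x, ...) {
  cat(sprintf("<wavelet_period_result: mean significant period %s h (%d/%d time points significant)>\n",
              ifelse(is.na(x$mean_period), "NA", sprintf("%.3g", x$mean_period)),
              sum(x$by_time$significant), nrow(x$by_time)))
  invisible(x)
}

#' One-phase exponential decay fit for half-life estimation
#'
#' Least-squares fit of `y(t) = plateau + (y0 - plateau) * exp(-k * t)`
#' to a decay chase, as used to estimate protein half-life after
#' translation blockade. The half-life `log(2) / k` is returned in the
#' time units of `time`.
#'
#' @param time Time points (e.g. minutes).
#' @param y Intensities (> 0), at least 5 points.
#' @param fix_plateau Optionally fix the plateau (e.g. at 0).
#' @return List with `half_life`, `rate`, `y0`, `plateau` and the
#'   underlying `nls` fit. A track with no detectable decay returns
#'   `half_life = Inf` with a warning.
#' @export
half_life_fit <- function(time, y, fix_plateau = NULL) {
  stopifnot(length(time) == length(y), length(y) >= 5, all(y > 0))
  dec <- (y[1] - y[length(y)]) / y[1]
  if (sd(y) == 0 || dec < 1e-10) {
    warning("no detectable decay; half-life reported as Inf")
    return(list(half_life = Inf, rate = 0, y0 = y[1],
                plateau = min(y), fit = NULL))
  }
  plateau0 <- if (is.null(fix_plateau)) max(min(y) * 0.9, 1e-12) else fix_plateau
  k0 <- max(log(max(y[1], 1e-12) / max(y[length(y)] - plateau0 + 1e-12, 1e-12)) /
              (time[length(time)] - time[1]), 1e-6)
  df <- data.frame(t = time - time[1], y = y)
  fit <- if (is.null(fix_plateau)) {
    minpack.lm::nlsLM(y ~ plateau + (y0 - plateau) * exp(-k * t), data = df,
                      start = list(plateau = plateau0, y0 = y[1], k = k0),
                      lower = c(0, 0, 1e-9), control = list(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ plateau0 + (y0 - plateau0) * exp(-k * t), data = df,
                      start = list(y0 = y[1], k = k0),
                      lower = c(0, 1e-9), control = list(maxiter = 200))
  }
  cf <- coef(fit)
  k <- unname(cf[["k"]])
  list(half_life = log(2) / k, rate = k, y0 = unname(cf[["y0"]]),
       plateau = if (is.null(fix_plateau)) unname(cf[["plateau"]]) else fix_plateau,
       fit = fit)
}
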