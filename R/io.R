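# internal: validate the long-format track table contract
check_track_table <- function(tracks,
                              require = c("cell_id", "time", "signal")) {
  if (!is.data.frame(tracks)) stop("tracks must be a data frame")
  missing_cols <- setdiff(require, names(tracks))
  if (length(missing_cols)) {
    stop("track table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(tracks)
}

#' Read and write single-cell track tables
#'
#' Track tables are comma-separated text with a mandatory header and
#' columns `cell_id`, `time_h`, `signal`, `control` (optional `x`, `y`,
#' `z` in micrometres). On reading, time must be strictly increasing and
#' uniformly sampled within each cell, and tracks shorter than
#' `min_duration_h` are dropped (with a message reporting how many); the
#' standard curation rejects tracks under 3 h.
#'
#' @param path File path.
#' @param time_unit `"hours"` (default) or `"minutes"`; minutes are
#'   converted to hours on input.
#' @param min_duration_h Minimum track duration retained (h).
#' @return A tibble with columns `cell_id`, `time` (h), `signal`,
#'   `control` and any positional columns present.
#' @examples
#' f <- system.file("extdata", "synthetic_tracks.csv", package = "ultradian")
#' tr <- read_tracks(f)
#' head(tr)
#' @export
read_tracks <- function(path, time_unit = c("hours", "minutes"),
                        min_duration_h = 3) {
  time_unit <- match.arg(time_unit)
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "time_h", "signal")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tr <- dplyr::rename(tr, time = "time_h")
  if (time_unit == "minutes") tr$time <- tr$time / 60
  if (any(!is.finite(tr$signal)) || any(tr$signal < 0)) {
    stop("signal intensities must be finite and >= 0; first bad row: ",
         which(!is.finite(tr$signal) | tr$signal < 0)[1])
  }
  by_cell <- split(tr$time, tr$cell_id)
  for (id in names(by_cell)) {
    tt <- by_cell[[id]]
    if (length(tt) > 1) {
      dts <- diff(tt)
      if (any(dts <= 0)) stop("track ", id, ": time not strictly increasing")
      if (diff(range(dts)) > 1e-6 * max(dts)) {
        stop("track ", id, ": non-uniform sampling")
      }
    }
  }
  dur <- vapply(by_cell, function(tt) diff(range(tt)), numeric(1))
  short <- names(dur)[dur < min_duration_h]
  if (length(short)) {
    message(length(short), " track(s) shorter than ", min_duration_h,
            " h rejected")
    tr <- tr[!tr$cell_id %in% short, ]
  }
  if (nrow(tr) == 0) stop("no tracks retained from ", path)
  tibble::as_tibble(tr)
}

#' @rdname read_tracks
#' @param tracks Track table as produced by the package (internal `time`
#'   column, hours).
#' @export
write_tracks <- function(tracks, path) {
  check_track_table(tracks)
  out <- dplyr::rename(tracks, time_h = "time")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write 3D nuclear snapshot tables
#'
#' Snapshot tables are comma-separated text with header and columns
#' `nucleus_id`, `x`, `y`, `z` (micrometres), `venus`, `control`
#' (nuclear-marker intensity) and optionally `stage_hpf`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_snapshot <- function(path) {
  sn <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("nucleus_id", "x", "y", "z", "venus")
  missing_cols <- setdiff(need, names(sn))
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sn$nucleus_id)) stop("duplicate nucleus_id in ", path)
  if (any(!is.finite(sn$x + sn$y + sn$z))) stop("non-finite coordinates")
  tibble::as_tibble(sn)
}

#' @rdname read_snapshot
#' @param snapshot Snapshot table.
#' @export
write_snapshot <- function(snapshot, path) {
  readr::write_csv(snapshot, path)
  invisible(path)
}

#' Per-track summary statistics
#'
#' Runs the descriptive stage of the track pipeline: normalisation to
#' the control channel, detrending, and per-cell time-series CV,
#' relative trend, Hilbert maximum peak-to-trough fold-change,
#' periodogram coherence and (optionally) wavelet period.
#'
#' @param tracks Track table with `signal` and `control`.
#' @param detrend_window_h Detrending cut-off (h).
#' @param wavelet Also compute the wavelet dominant period per cell
#'   (slower; permutation null).
#' @param n_perm Permutations for the wavelet null.
#' @param seed Seed for the permutation null.
#' @return A tibble with one row per cell: `cv_t`, `relative_trend`,
#'   `fold_change`, `coherence`, `dominant_period` and, if requested,
#'   `wavelet_period`.
#' @export
analyse_tracks <- function(tracks, detrend_window_h = 4.5, wavelet = TRUE,
                           n_perm = 200, seed = NULL) {
  check_track_table(tracks, require = c("cell_id", "time", "signal", "control"))
  raw <- tracks
  norm <- normalise_to_control(tracks)
  det <- detrend(norm, window_h = detrend_window_h)

  per_cell <- function(df) {
    dt <- df$time[2] - df$time[1]
    cs <- coherence(df$detrended, dt)
    wp <- if (wavelet) {
      wavelet_period(df$detrended, dt, n_perm = n_perm, seed = seed)$mean_period
    } else NA_real_
    tibble::tibble(
      cv_t = population_cv(df$raw_signal),
      relative_trend = df$raw_signal[nrow(df)] / df$raw_signal[1],
      fold_change = hilbert_fold_change(df$signal, df$detrended),
      coherence = cs$coherence,
      dominant_period = cs$dominant_period,
      wavelet_period = wp
    )
  }
  det$raw_signal <- raw$signal
  out <- dplyr::group_modify(dplyr::group_by(det, .data$cell_id),
                             function(df, key) per_cell(df))
  dplyr::ungroup(out)
}

#' Run the synthetic-data / analysis / oscillation-calling pipeline
#'
#' Generates a synthetic track population (or reads one from disk),
#' computes per-cell summary statistics, classifies tracks as
#' oscillatory versus aperiodic, and writes all tables plus a manifest
#' (configuration, seed and package version) to an output directory.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config A named list. Recognised entries: `tracks_file` /
#'   `background_file` (read inputs instead of generating), `spec` (a
#'   [track_spec()] or argument list for it), `target_fdr` (default
#'   0.03), `detrend_window_h` (default 4.5), `n_synth` (null tracks for
#'   FDR calibration, default 500), `n_perm` (wavelet permutations,
#'   default 200), `seed`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the tracks, per-cell statistics and
#'   oscillation calls.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  target_fdr <- config$target_fdr %||% 0.03
  window <- config$detrend_window_h %||% 4.5
  n_synth <- config$n_synth %||% 500
  n_perm <- config$n_perm %||% 200

  if (!is.null(config$tracks_file)) {
    tracks <- read_tracks(config$tracks_file)
    background <- if (!is.null(config$background_file)) {
      read_tracks(config$background_file, min_duration_h = 0)
    } else NULL
    labels <- NULL
  } else {
    spec <- config$spec %||% track_spec(seed = seed)
    if (!inherits(spec, "track_spec")) spec <- do.call(track_spec, spec)
    gen <- generate_tracks(spec)
    tracks <- gen$tracks
    background <- gen$background
    labels <- gen$labels
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    write_tracks(background, file.path(out_dir, "background.csv"))
  }

  stats <- analyse_tracks(tracks, detrend_window_h = window,
                          n_perm = n_perm, seed = seed)
  readr::write_csv(stats, file.path(out_dir, "track_stats.csv"))

  calls <- classify_tracks(tracks, background, target_fdr = target_fdr,
                           detrend_window_h = window, n_synth = n_synth,
                           seed = seed)
  readr::write_csv(calls$calls, file.path(out_dir, "oscillation_calls.csv"))

  manifest <- list(
    package = "ultradian",
    version = as.character(utils::packageVersion("ultradian")),
    seed = seed,
    config = config[setdiff(names(config), "spec")],
    spec = if (exists("spec", inherits = FALSE)) unclass(spec) else NULL,
    percent_oscillatory = calls$percent_oscillatory,
    llr_threshold = calls$threshold
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(tracks = tracks, background = background, labels = labels,
                 stats = stats, calls = calls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
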