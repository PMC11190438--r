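#' Nearest-neighbour pairs in a 3D nuclear snapshot
#'
#' For every nucleus, finds the partner at minimal 3D Euclidean
#' distance. Pairs are recorded directionally (each cell 1 with its
#' nearest cell 2), the convention used for paired-intensity plots.
#' Coordinate ties are broken by id order with a warning when duplicate
#' coordinates are present.
#'
#' @param snapshot Snapshot table with `nucleus_id`, `x`, `y`, `z`,
#'   `venus` and optionally `control`.
#' @return Object of class `neighbour_pairs`: a tibble with `id1`,
#'   `id2`, `distance` and per-channel intensities `venus1`, `venus2`
#'   (and `control1`, `control2` when present).
#' @export
nearest_neighbour_pairs <- function(snapshot) {
  stopifnot(nrow(snapshot) >= 2)
  need <- c("nucleus_id", "x", "y", "z", "venus")
  stopifnot(all(need %in% names(snapshot)))
  xyz <- as.matrix(snapshot[, c("x", "y", "z")])
  if (anyDuplicated(xyz)) {
    warning("duplicate coordinates; nearest-neighbour ties broken by id order")
  }
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- Inf
  j <- apply(D, 1, which.min)
  out <- tibble::tibble(
    id1 = snapshot$nucleus_id,
    id2 = snapshot$nucleus_id[j],
    distance = D[cbind(seq_len(nrow(D)), j)],
    venus1 = snapshot$venus,
    venus2 = snapshot$venus[j]
  )
  if ("control" %in% names(snapshot)) {
    out$control1 <- snapshot$control
    out$control2 <- snapshot$control[j]
  }
  structure(out, class = c("neighbour_pairs", class(out)))
}

pair_channel <- function(pairs, channel) {
  c1 <- paste0(channel, "1")
  c2 <- paste0(channel, "2")
  if (!all(c(c1, c2) %in% names(pairs))) {
    stop("channel '", channel, "' not present in the pair set")
  }
  list(i1 = pairs[[c1]], i2 = pairs[[c2]])
}

#' Mean neighbour intensity ratio
#'
#' The per-pair intensity ratio between a cell and its nearest
#' neighbour, averaged over the population. The default ordered
#' convention `max / min` is always >= 1 and equals 1 only for exactly
#' equal neighbours, so noisy-but-similar neighbours score slightly
#' above 1 and salt-and-pepper interspersion scores high. The `signed`
#' convention reports raw `I1 / I2`.
#'
#' @param pairs A [nearest_neighbour_pairs()] result.
#' @param channel Intensity channel (`"venus"` or `"control"`).
#' @param convention `"ordered"` (max/min, default) or `"signed"`.
#' @return Mean ratio. Pairs containing a zero intensity are dropped
#'   with a message.
#' @export
pair_intensity_ratio <- function(pairs, channel = "venus",
                                 convention = c("ordered", "signed")) {
  convention <- match.arg(convention)
  ch <- pair_channel(pairs, channel)
  ok <- ch$i1 > 0 & ch$i2 > 0
  if (any(!ok)) {
    message(sum(!ok), " pair(s) with zero intensity dropped")
  }
  i1 <- ch$i1[ok]; i2 <- ch$i2[ok]
  if (length(i1) == 0) stop("no usable pairs")
  r <- if (convention == "ordered") pmax(i1, i2) / pmin(i1, i2) else i1 / i2
  mean(r)
}

#' Neighbour intensity correlation
#'
#' Pearson correlation of (cell 1, cell 2) intensities across
#' nearest-neighbour pairs: high for smooth expression fields, near zero
#' for random ones and negative for salt-and-pepper interspersion.
#'
#' @param pairs A [nearest_neighbour_pairs()] result (>= 3 pairs).
#' @param channel Intensity channel.
#' @return Pearson r, or `NA` (with a warning) when a channel has zero
#'   variance.
#' @export
pair_correlation <- function(pairs, channel = "venus") {
  ch <- pair_channel(pairs, channel)
  if (length(ch$i1) < 3) stop("need at least 3 pairs")
  if (sd(ch$i1) == 0 || sd(ch$i2) == 0) {
    warning("zero variance in a channel; correlation undefined")
    return(NA_real_)
  }
  cor(ch$i1, ch$i2)
}

#' Fraction of Venus-positive nuclei
#'
#' Thresholds nuclei against the embryo's background intensity sample.
#' By default the threshold is `median(background) + 2 * mad(background)`,
#' a deterministic stand-in for starting at the background median and
#' adjusting manually; alternatively a plain multiple of the median can
#' be requested.
#'
#' @param snapshot Snapshot table with a `venus` column.
#' @param background Numeric sample of background intensities.
#' @param mad_multiplier Number of MADs added to the median.
#' @param median_multiplier If given, use `median * median_multiplier`
#'   as the threshold instead.
#' @return The positive fraction in `[0, 1]`, with the threshold as
#'   attribute `threshold`.
#' @export
venus_positive_fraction <- function(snapshot, background,
                                    mad_multiplier = 2,
                                    median_multiplier = NULL) {
  if (nrow(snapshot) == 0) stop("empty snapshot")
  if (length(background) == 0) stop("empty background sample")
  thr <- if (is.null(median_multiplier)) {
    median(background) + mad_multiplier * mad(background)
  } else {
    median(background) * median_multiplier
  }
  structure(mean(snapshot$venus > thr), threshold = thr)
}

#' Persistently close cell pairs from positional tracks
#'
#' Computes the mean 3D distance over shared time points for every pair
#' of tracked cells and keeps the pairs that stay closer than
#' `max_mean_distance` on average (the criterion for selecting
#' neighbouring cell pairs from live tracking). Pairs with no temporal
#' overlap are skipped.
#'
#' @param tracks Track table with `cell_id`, `time`, `x`, `y`, `z`.
#' @param max_mean_distance Distance ceiling (micrometres, default 15).
#' @return Tibble with `id1`, `id2`, `mean_distance` and
#'   `n_shared_times` for the retained pairs.
#' @export
persistent_close_pairs <- function(tracks, max_mean_distance = 15) {
  check_track_table(tracks, require = c("cell_id", "time", "x", "y", "z"))
  cells <- split(tracks, tracks$cell_id)
  ids <- names(cells)
  out <- list()
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      ta <- cells[[a]]; tb <- cells[[b]]
      shared <- intersect(ta$time, tb$time)
      if (length(shared) == 0) next
      pa <- ta[match(shared, ta$time), c("x", "y", "z")]
      pb <- tb[match(shared, tb$time), c("x", "y", "z")]
      d <- sqrt(rowSums((as.matrix(pa) - as.matrix(pb))^2))
      if (mean(d) < max_mean_distance) {
        out[[length(out) + 1L]] <- tibble::tibble(
          id1 = ids[b], id2 = ids[a], mean_distance = mean(d),
          n_shared_times = length(shared))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(id1 = character(), id2 = character(),
                          mean_distance = numeric(),
                          n_shared_times = integer()))
  }
  dplyr::bind_rows(out)
}
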