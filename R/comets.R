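#' Detect comet-like spots in a frame
#'
#' Local maxima above `min_intensity` with non-maximum suppression at
#' `min_separation_px` (stronger maxima win), refined by intensity-weighted
#' center of mass over a 5x5 neighbourhood.
#'
#' @param frame 2-D intensity matrix.
#' @param min_intensity Minimum peak intensity.
#' @param min_separation_px Minimum distance between detections (>= 1).
#' @param smooth_sigma Optional matched-filter Gaussian pre-smoothing SD
#'   (px, 0 = off); reduces shot-noise jitter of detected centroids on
#'   noisy movies.
#' @return A tibble with `x`, `y` (px, sub-pixel) and `intensity`.
#' @export
detect_comets <- function(frame, min_intensity, min_separation_px = 5,
                          smooth_sigma = 0) {
  stopifnot(is.matrix(frame))
  if (smooth_sigma > 0) frame <- gaussian_blur(frame, smooth_sigma)
  if (min_separation_px < 1) {
    stop("min_separation_px must be >= 1", call. = FALSE)
  }
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3 || nc < 3) {
    return(tibble::tibble(x = numeric(), y = numeric(),
                          intensity = numeric()))
  }
  inner <- frame[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner > min_intensity
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max &
      inner >= frame[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(),
                          intensity = numeric()))
  }
  py <- idx[, 1] + 1L
  px <- idx[, 2] + 1L
  ints <- frame[cbind(py, px)]
  ord <- order(ints, decreasing = TRUE)
  py <- py[ord]; px <- px[ord]; ints <- ints[ord]
  keep <- rep(TRUE, length(px))
  for (i in seq_along(px)) {
    if (!keep[i]) next
    if (i < length(px)) {
      later <- (i + 1):length(px)
      d <- sqrt((px[later] - px[i])^2 + (py[later] - py[i])^2)
      keep[later[d < min_separation_px]] <- FALSE
    }
  }
  py <- py[keep]; px <- px[keep]; ints <- ints[keep]
  ref <- vapply(seq_along(px), function(i) {
    y0 <- max(1L, py[i] - 2L); y1 <- min(nr, py[i] + 2L)
    x0 <- max(1L, px[i] - 2L); x1 <- min(nc, px[i] + 2L)
    # local-background subtraction (patch minimum) keeps the uniform
    # offset and its shot noise from biasing the center of mass
    patch <- frame[y0:y1, x0:x1]
    patch <- patch - min(patch)
    w <- sum(patch)
    if (w <= 0) return(c(px[i], py[i]))
    c(sum(patch %*% (x0:x1)) / w,  # column weights via matrix product
      sum((y0:y1) %*% patch) / w)
  }, numeric(2))
  tibble::tibble(x = ref[1, ], y = ref[2, ], intensity = ints)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate links
#' between the active tracks' latest positions and the next frame's
#' detections are taken in order of increasing distance; links beyond
#' `max_displacement_px` are forbidden; unmatched detections start new
#' tracks; tracks with fewer than `min_track_length` points are discarded.
#' A deliberately simple stand-in for full linear-assignment particle
#' tracking — adequate for well-separated comets.
#'
#' @param detections A data frame with `frame`, `x`, `y` (one row per
#'   detection), e.g. built by running [detect_comets()] per frame.
#' @param max_displacement_px Maximum link distance (> 0).
#' @param min_track_length Minimum points per reported track (>= 2).
#' @return A tibble of class `track_set`: `track_id`, `frame`, `x`, `y`.
#' @export
link_tracks <- function(detections, max_displacement_px,
                        min_track_length = 2) {
  if (max_displacement_px <= 0) {
    stop("max_displacement_px must be > 0", call. = FALSE)
  }
  if (min_track_length < 2) {
    stop("min_track_length must be >= 2", call. = FALSE)
  }
  det <- dplyr::arrange(tibble::as_tibble(detections), .data$frame)
  frames <- sort(unique(det$frame))
  det$track_id <- NA_integer_
  next_id <- 1L
  prev_rows <- integer(0)
  for (f in frames) {
    cur_rows <- which(det$frame == f)
    if (length(prev_rows) > 0 && length(cur_rows) > 0) {
      d <- outer(seq_along(prev_rows), seq_along(cur_rows),
                 function(i, j) {
                   sqrt((det$x[prev_rows[i]] - det$x[cur_rows[j]])^2 +
                        (det$y[prev_rows[i]] - det$y[cur_rows[j]])^2)
                 })
      cand <- which(d <= max_displacement_px, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_prev <- rep(FALSE, length(prev_rows))
        used_cur <- rep(FALSE, length(cur_rows))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_prev[i] || used_cur[j]) next
          det$track_id[cur_rows[j]] <- det$track_id[prev_rows[i]]
          used_prev[i] <- TRUE
          used_cur[j] <- TRUE
        }
      }
    }
    new_rows <- cur_rows[is.na(det$track_id[cur_rows])]
    if (length(new_rows) > 0) {
      det$track_id[new_rows] <- seq(next_id, by = 1L,
                                    length.out = length(new_rows))
      next_id <- next_id + length(new_rows)
    }
    prev_rows <- cur_rows
  }
  out <- det |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= min_track_length) |>
    dplyr::ungroup() |>
    dplyr::select("track_id", "frame", "x", "y") |>
    dplyr::arrange(.data$track_id, .data$frame)
  out$track_id <- match(out$track_id, unique(out$track_id))
  structure(out, class = c("track_set", class(out)))
}

#' Per-track and mean comet speeds
#'
#' Per-track speed is the summed step length times `pixel_size` divided by
#' the track duration (`n_steps * frame_interval`); the movie mean is the
#' unweighted mean of per-track speeds.
#'
#' @param tracks A `track_set` from [link_tracks()].
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds per frame.
#' @return A tibble with one row per track: `track_id`, `n_points`,
#'   `path_um`, `duration_s`, `speed_um_s`; the movie mean is in the
#'   `mean_speed` attribute.
#' @export
comet_speeds <- function(tracks, pixel_size, frame_interval) {
  if (nrow(tracks) == 0L) stop("no tracks to measure", call. = FALSE)
  per_track <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      path_px = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      n_steps = dplyr::n() - 1L,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      path_um = .data$path_px * pixel_size,
      duration_s = .data$n_steps * frame_interval,
      speed_um_s = .data$path_um / .data$duration_s
    ) |>
    dplyr::select("track_id", "n_points", "path_um", "duration_s",
                  "speed_um_s")
  structure(per_track, mean_speed = mean(per_track$speed_um_s))
}
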