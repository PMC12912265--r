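#' Calibrated image stack
#'
#' The common currency of every measurement stage: a single-channel
#' time-lapse (or z-) stack together with its spatial and temporal
#' calibration. Frames are stored as a 3-D array indexed
#' `[frame, row, col]`, origin top-left, row index increasing downward.
#' Analysis movies are assumed pre-oriented with the EVL-YSL margin at the
#' top, so "animal/up" corresponds to decreasing row index.
#'
#' @param frames 3-D numeric array `(time x rows x cols)` of nonnegative
#'   intensities, or a list of equally sized matrices.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param frame_interval Seconds per frame (> 0).
#' @param channel_label Free-text channel description.
#'
#' @return An object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(frames, pixel_size, frame_interval,
                             channel_label = "") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must share identical row/col dimensions", call. = FALSE)
    }
    arr <- array(0, dim = c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (time x rows x cols)", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)",
         call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a single positive number (s/frame)",
         call. = FALSE)
  }
  structure(
    list(
      frames = frames * 1.0,  # all downstream math in floating point
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      channel_label = channel_label
    ),
    class = "calibrated_stack"
  )
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<calibrated_stack> %d frame(s), %d x %d px | %g um/px, %g s/frame%s\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval,
    if (nzchar(x$channel_label)) paste0(" | ", x$channel_label) else ""
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `calibrated_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "calibrated_stack"))
  dim(stack$frames)[1]
}

#' Extract one frame as a matrix
#' @param stack A `calibrated_stack`.
#' @param i Frame index (1-based).
#' @return A rows x cols numeric matrix.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (i < 1 || i > n_frames(stack)) stop("frame index out of range", call. = FALSE)
  stack$frames[i, , ]
}

# ---- Unit conversions ------------------------------------------------------
# All physical-unit conversions live here; no other operation multiplies by
# pixel_size or frame_interval directly.

#' Convert pixel lengths to micrometres
#' @param stack A `calibrated_stack`.
#' @param px Length(s) in pixels.
#' @return Length(s) in micrometres.
#' @export
px_to_um <- function(stack, px) {
  stopifnot(inherits(stack, "calibrated_stack"))
  px * stack$pixel_size
}

#' Convert micrometres to pixels
#' @inheritParams px_to_um
#' @param um Length(s) in micrometres.
#' @return Length(s) in pixels.
#' @export
um_to_px <- function(stack, um) {
  stopifnot(inherits(stack, "calibrated_stack"))
  um / stack$pixel_size
}

#' Convert frame indices (0-based offsets) to seconds
#' @inheritParams px_to_um
#' @param frames Frame offsets.
#' @return Times in seconds.
#' @export
frames_to_seconds <- function(stack, frames) {
  stopifnot(inherits(stack, "calibrated_stack"))
  frames * stack$frame_interval
}

#' Convert a per-frame pixel displacement to a velocity in um/min
#' @inheritParams px_to_um
#' @param d_px Displacement(s) in pixels per frame interval.
#' @return Velocity in micrometres per minute.
#' @export
px_per_frame_to_um_min <- function(stack, d_px) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d_px * stack$pixel_size / stack$frame_interval * 60
}

#' Convert a per-frame pixel displacement to a velocity in um/s
#' @inheritParams px_per_frame_to_um_min
#' @return Velocity in micrometres per second.
#' @export
px_per_frame_to_um_s <- function(stack, d_px) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d_px * stack$pixel_size / stack$frame_interval
}
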