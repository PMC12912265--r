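#' Project a stack to a single image
#'
#' Pixel-wise maximum or sum across the stack (time/z) axis. Puncta
#' counting defaults to a maximum-intensity projection so a vesicle
#' spanning slices is counted once.
#'
#' @param stack A [calibrated_stack()] with >= 1 frame.
#' @param mode `"max"` or `"sum"`.
#' @return A rows x cols matrix.
#' @export
project_stack <- function(stack, mode = c("max", "sum")) {
  stopifnot(inherits(stack, "calibrated_stack"))
  mode <- match.arg(mode)
  if (n_frames(stack) < 1L) stop("empty stack", call. = FALSE)
  apply(stack$frames, c(2, 3), if (mode == "max") max else sum)
}

# 8-connected component labeling (ImageJ convention).
# EBImage::bwlabel is 4-connected, so we take its labeling and merge labels
# that touch diagonally via a small union-find pass.
label_components_8 <- function(binary) {
  lab <- EBImage::bwlabel(binary != 0)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Detect size-filtered puncta
#'
#' Threshold-and-count quantification of endocytosed vesicles: binarize the
#' image at a fixed or Otsu threshold, label 8-connected components,
#' compute each component's calibrated area (pixel count times
#' `pixel_size^2`), and flag components whose area lies inside the closed
#' band `[area_band[1], area_band[2]]` (default 0.2-2 um^2, the band that
#' eliminates thresholding background). All components are recorded; the
#' in-band count is the reported vesicle count.
#'
#' @param image 2-D matrix (a frame or a projection from
#'   [project_stack()]).
#' @param threshold `"otsu"` for Otsu's automatic threshold, or a fixed
#'   numeric intensity; pixels strictly above it are foreground.
#' @param area_band Closed area band in um^2.
#' @param pixel_size Micrometres per pixel.
#' @return A tibble of class `puncta_set` with one row per component:
#'   `label`, centroid `x`, `y` (px), `area_um2`, `n_px`,
#'   `mean_intensity`, `in_band`. Attributes record the threshold used,
#'   the band, and `n_in_band`.
#' @export
detect_puncta <- function(image, threshold = "otsu", area_band = c(0.2, 2),
                          pixel_size) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("image must be nonnegative", call. = FALSE)
  if (area_band[1] <= 0) {
    stop("area band lower bound must be > 0", call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    thr <- if (diff(rng) == 0) rng[1] else {
      scaled <- (image - rng[1]) / diff(rng)
      EBImage::otsu(scaled, range = c(0, 1)) * diff(rng) + rng[1]
    }
  } else {
    thr <- as.numeric(threshold)
    if (thr < min(image) || thr > max(image)) {
      warning(sprintf(
        "fixed threshold %g outside image intensity range [%g, %g]",
        thr, min(image), max(image)), call. = FALSE)
    }
  }
  lab <- label_components_8(image > thr)
  nl <- max(lab)
  if (nl == 0L) {
    out <- tibble::tibble(label = integer(), x = numeric(), y = numeric(),
                          area_um2 = numeric(), n_px = integer(),
                          mean_intensity = numeric(), in_band = logical())
  } else {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    v <- image[lab > 0]
    n_px <- tabulate(l, nl)
    out <- tibble::tibble(
      label = seq_len(nl),
      x = as.vector(tapply(idx[, 2], l, mean)),
      y = as.vector(tapply(idx[, 1], l, mean)),
      n_px = n_px,
      area_um2 = n_px * pixel_size^2,
      mean_intensity = as.vector(tapply(v, l, mean))
    ) |>
      dplyr::mutate(in_band = .data$area_um2 >= area_band[1] &
                              .data$area_um2 <= area_band[2]) |>
      dplyr::select("label", "x", "y", "area_um2", "n_px",
                    "mean_intensity", "in_band")
  }
  structure(out, class = c("puncta_set", class(out)),
            threshold = thr, area_band = area_band,
            pixel_size = pixel_size, n_in_band = sum(out$in_band))
}

#' In-band puncta count
#' @param puncta A `puncta_set` from [detect_puncta()].
#' @return Integer count of components inside the area band.
#' @export
n_in_band <- function(puncta) {
  stopifnot(inherits(puncta, "puncta_set"))
  sum(puncta$in_band)
}
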