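#' Embryo circularity
#'
#' `4 * pi * A / P^2`, with area and perimeter measured on the sub-pixel
#' boundary of the silhouette: the mask is lightly Gaussian-smoothed and
#' the 0.5 iso-contour is extracted by marching squares
#' ([grDevices::contourLines()]); the perimeter is the contour polygon's
#' arc length and the area its shoelace area. Naive pixel-edge perimeters
#' overestimate P (and so depress circularity) and are not used. Values
#' are not capped at 1; slight overshoot flags a discretization artifact.
#'
#' @param mask Binary matrix with a single connected foreground component
#'   of at least 100 px.
#' @param pixel_size Micrometres per pixel (circularity is dimensionless;
#'   retained for interface symmetry).
#' @param smooth_sigma Pre-contour Gaussian smoothing SD in px.
#' @return Dimensionless circularity in (0, 1] up to discretization
#'   tolerance.
#' @export
circularity <- function(mask, pixel_size = 1, smooth_sigma = 1.5) {
  stopifnot(is.matrix(mask))
  mask <- 1 * (mask != 0)
  if (sum(mask) < 100) {
    stop("mask must have a foreground component of >= 100 px", call. = FALSE)
  }
  ncomp <- max(label_components_8(mask))
  if (ncomp != 1L) {
    stop(sprintf("mask must have exactly one connected component (found %d)",
                 ncomp), call. = FALSE)
  }
  if (any(mask[1, ] != 0) || any(mask[nrow(mask), ] != 0) ||
      any(mask[, 1] != 0) || any(mask[, ncol(mask)] != 0)) {
    stop("foreground touches the image border; outline is not closed",
         call. = FALSE)
  }
  z <- gaussian_blur(mask, smooth_sigma)
  cl <- grDevices::contourLines(seq_len(nrow(z)), seq_len(ncol(z)), z,
                                levels = 0.5)
  if (length(cl) == 0L) stop("no 0.5 iso-contour found", call. = FALSE)
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lens)]]
  xs <- c(p$x, p$x[1]); ys <- c(p$y, p$y[1])
  perimeter <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  area <- abs(sum(xs[-1] * diff(ys) - ys[-1] * diff(xs))) / 2
  4 * pi * area / perimeter^2
}

#' Epiboly progression fraction
#'
#' Distance from the animal pole to the margin projected onto the
#' animal-vegetal axis, divided by the pole-to-pole axis length. Invariant
#' under rigid transforms of all three landmarks.
#'
#' @param animal_pole,margin,vegetal_pole Landmark coordinates `c(x, y)`
#'   in pixels.
#' @param tolerance Allowed overshoot of the projection parameter beyond
#'   `[0, 1]` (default 0.02); the result is clamped to `[0, 1]`.
#' @return Progression fraction in `[0, 1]`.
#' @export
epiboly_progression <- function(animal_pole, margin, vegetal_pole,
                                tolerance = 0.02) {
  axis <- c(vegetal_pole[1] - animal_pole[1],
            vegetal_pole[2] - animal_pole[2])
  len2 <- sum(axis^2)
  if (len2 == 0) stop("animal and vegetal poles coincide", call. = FALSE)
  rel <- c(margin[1] - animal_pole[1], margin[2] - animal_pole[2])
  t <- sum(rel * axis) / len2
  if (t < -tolerance || t > 1 + tolerance) {
    stop(sprintf(
      "margin projects outside the pole-to-pole axis (t = %.4f)", t),
      call. = FALSE)
  }
  min(1, max(0, t))
}

#' Normalize measurements to a reference (wild-type) average
#'
#' Divides each value by the arithmetic mean of the reference values —
#' the per-trial normalization applied before pooling trials (each trial
#' normalized to its own wild-type average). Idempotent when the reference
#' is an already-normalized wild-type set (mean 1).
#'
#' @param values Numeric measurements.
#' @param reference_values Non-empty numeric reference (wild-type)
#'   measurements with nonzero mean.
#' @return Normalized values.
#' @export
normalize_to_reference <- function(values, reference_values) {
  if (length(reference_values) == 0L) {
    stop("reference must be non-empty", call. = FALSE)
  }
  m <- mean(reference_values)
  if (m == 0) stop("zero reference mean", call. = FALSE)
  values / m
}

#' Per-trial normalization of a measurement table
#'
#' Tidy wrapper around [normalize_to_reference()]: within each trial, every
#' value is divided by the mean of that trial's reference-group values.
#'
#' @param data A data frame of per-embryo measurements.
#' @param value Column name (string) holding the measurement.
#' @param group Column name holding the genotype/group label.
#' @param trial Column name holding the trial label.
#' @param reference_label Group label of the reference (wild type).
#' @return `data` with an added `<value>_norm` column.
#' @export
normalize_by_trial <- function(data, value, group, trial,
                               reference_label = "wt") {
  stopifnot(is.data.frame(data))
  out_col <- paste0(value, "_norm")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(trial))) |>
    dplyr::group_modify(function(d, key) {
      ref <- d[[value]][d[[group]] == reference_label]
      if (length(ref) == 0L) {
        stop("trial without reference-group values", call. = FALSE)
      }
      d[[out_col]] <- normalize_to_reference(d[[value]], ref)
      d
    }) |>
    dplyr::ungroup()
}
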