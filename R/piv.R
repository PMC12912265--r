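#' PIV parameters
#'
#' Parameters of the windowed cross-correlation flow estimator. The
#' interrogation window is specified in micrometres (default 14.8, the
#' region-of-interest scale used for cortical actin flow) and converted to
#' an even pixel count per run. Spurious vectors are rejected by a
#' peak-to-second-peak signal-to-noise threshold (default 1) and a speed
#' cap (default 1 um/min, the upper bound of reported cortical actin flow).
#'
#' @param window_um Interrogation window edge length (um).
#' @param overlap_fraction Window overlap in `[0, 1)` (default 0.5).
#' @param search_margin_px Search margin around the window (px).
#' @param s2n_threshold Signal-to-noise (first/second correlation peak)
#'   threshold; vectors at or below it are flagged invalid.
#' @param speed_cap Maximum plausible speed (um/min); faster vectors are
#'   flagged invalid.
#' @param subpixel Refine the correlation peak by three-point Gaussian
#'   interpolation.
#' @return A `piv_params` list.
#' @export
piv_params <- function(window_um = 14.8, overlap_fraction = 0.5,
                       search_margin_px = 8, s2n_threshold = 1.0,
                       speed_cap = 1.0, subpixel = TRUE) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  if (speed_cap <= 0) stop("speed_cap must be > 0", call. = FALSE)
  if (search_margin_px < 1) stop("search_margin_px must be >= 1", call. = FALSE)
  structure(list(window_um = window_um, overlap_fraction = overlap_fraction,
                 search_margin_px = search_margin_px,
                 s2n_threshold = s2n_threshold, speed_cap = speed_cap,
                 subpixel = subpixel),
            class = "piv_params")
}

# window edge in px: nearest even integer, floor 8
window_px <- function(window_um, pixel_size) {
  w <- max(8L, 2L * round(window_um / pixel_size / 2))
  as.integer(w)
}

step_px <- function(w_px, overlap_fraction) {
  max(1L, as.integer(round(w_px * (1 - overlap_fraction))))
}

# window centers for an nr x nc frame; windows are inset by the search
# margin so every search region lies inside the frame
piv_grid <- function(nr, nc, w_px, step, margin) {
  if (nr - w_px - margin + 1L < margin + 1L ||
      nc - w_px - margin + 1L < margin + 1L) {
    stop("window larger than frame (after search-margin inset)",
         call. = FALSE)
  }
  r0 <- seq(margin + 1L, nr - w_px - margin + 1L, by = step)
  c0 <- seq(margin + 1L, nc - w_px - margin + 1L, by = step)
  tidyr::expand_grid(r0 = r0, c0 = c0) |>
    dplyr::mutate(x = .data$c0 + (w_px - 1) / 2,
                  y = .data$r0 + (w_px - 1) / 2)
}

# three-point subpixel refinement along one axis of the correlation map;
# Gaussian when all three samples are positive (exact for Gaussian peaks),
# parabolic otherwise
refine_1d <- function(cm, cz, cp) {
  if (cm > 0 && cz > 0 && cp > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(cz))
    if (abs(den) > 1e-12) {
      delta <- (log(cm) - log(cp)) / den
      if (is.finite(delta) && abs(delta) <= 1) return(delta)
    }
  }
  den <- 2 * (cm + cp - 2 * cz)
  if (abs(den) > 1e-12) {
    delta <- (cm - cp) / den
    if (is.finite(delta) && abs(delta) <= 1) return(delta)
  }
  0
}

# 2-D cumulative sum (integral image)
cumsum2 <- function(m) {
  apply(apply(m, 2, cumsum), 1, cumsum) |> t()
}

# sliding w x w window sums of `img` for all (2m+1)^2 offsets, via the
# integral image; returns a (2m+1) x (2m+1) matrix
sliding_window_sums <- function(img, w, m) {
  S <- matrix(0, nrow(img) + 1, ncol(img) + 1)
  S[-1, -1] <- cumsum2(img)
  i0 <- seq_len(2 * m + 1)           # window top-left rows (1..2m+1)
  S[i0 + w, i0 + w, drop = FALSE] - S[i0 + w, i0, drop = FALSE] -
    S[i0, i0 + w, drop = FALSE] + S[i0, i0, drop = FALSE]
}

# correlate one window against its search region; returns displacement and
# signal-to-noise. a: w x w window (frame t); b: (w+2m) x (w+2m) search
# region (frame t+1). The map is the true per-offset normalized
# cross-correlation: for each candidate offset the window-sized sub-region
# of b is mean-subtracted and variance-normalized individually (integral
# images supply the per-offset sums), which keeps the correlation peak
# unbiased when local background varies across the search region.
correlate_window <- function(a, b, m, subpixel) {
  w <- nrow(a)
  n <- w * w
  a <- a - mean(a)
  sa <- sqrt(sum(a^2))
  L <- nrow(b)
  bs <- sliding_window_sums(b, w, m)
  bs2 <- sliding_window_sums(b * b, w, m)
  varb <- pmax(bs2 - bs^2 / n, 0)
  sb <- sqrt(varb)
  if (sa == 0 || all(sb == 0)) {
    return(list(dx = 0, dy = 0, s2n = 0, degenerate = TRUE))
  }
  ap <- matrix(0, L, L)
  ap[seq_len(w), seq_len(w)] <- a
  D <- Re(stats::fft(Conj(stats::fft(ap)) * stats::fft(b), inverse = TRUE)) /
    L^2
  # D[k+1, l+1] = sum_{i,j} a[i,j] * b[i+k, j+l] (a is zero-mean, so the
  # local mean of b drops out of the numerator); displacement = k - m
  num <- D[seq_len(2 * m + 1), seq_len(2 * m + 1)]
  cmap <- matrix(0, 2 * m + 1, 2 * m + 1)
  ok <- sb > 0
  cmap[ok] <- num[ok] / (sa * sb[ok])
  pk <- which(cmap == max(cmap), arr.ind = TRUE)[1, ]
  peak1 <- cmap[pk[1], pk[2]]
  excl <- cmap
  excl[max(1, pk[1] - 1):min(2 * m + 1, pk[1] + 1),
       max(1, pk[2] - 1):min(2 * m + 1, pk[2] + 1)] <- -Inf
  peak2 <- max(excl)
  s2n <- if (peak2 > 0) peak1 / peak2 else Inf
  dy <- pk[1] - 1 - m
  dx <- pk[2] - 1 - m
  if (subpixel && pk[1] > 1 && pk[1] < 2 * m + 1) {
    dy <- dy + refine_1d(cmap[pk[1] - 1, pk[2]], peak1, cmap[pk[1] + 1, pk[2]])
  }
  if (subpixel && pk[2] > 1 && pk[2] < 2 * m + 1) {
    dx <- dx + refine_1d(cmap[pk[1], pk[2] - 1], peak1, cmap[pk[1], pk[2] + 1])
  }
  list(dx = unname(dx), dy = unname(dy), s2n = unname(s2n),
       degenerate = FALSE)
}

#' Windowed cross-correlation flow estimation (PIV)
#'
#' For every consecutive frame pair and every tiled interrogation window,
#' computes the mean-subtracted normalized cross-correlation between the
#' window in frame *t* and the search region (window plus
#' `search_margin_px`) in frame *t + 1*; the displacement is the location
#' of the correlation maximum, optionally refined to sub-pixel precision by
#' three-point Gaussian interpolation per axis. Vector quality is the ratio
#' of the primary correlation peak to the secondary peak (maximum outside a
#' 3x3 exclusion zone around the primary).
#'
#' All vectors are returned; constant (zero-variance) windows are flagged
#' invalid with `s2n = 0`. Run [filter_vectors()] to apply the
#' signal-to-noise and speed-cap validity criteria.
#'
#' @param stack A [calibrated_stack()] with at least 2 frames.
#' @param params A [piv_params()].
#' @return A tibble of class `piv_field` with one row per window and frame
#'   pair: `frame_pair`, window center `x`, `y` (px), displacement `dx`,
#'   `dy` (px/frame), velocity `vx`, `vy`, `speed` (um/min), `s2n`, `valid`.
#' @export
compute_piv <- function(stack, params = piv_params()) {
  stopifnot(inherits(stack, "calibrated_stack"))
  nt <- n_frames(stack)
  if (nt < 2L) stop("PIV needs at least 2 frames", call. = FALSE)
  d <- dim(stack$frames)
  w <- window_px(params$window_um, stack$pixel_size)
  m <- as.integer(params$search_margin_px)
  grid <- piv_grid(d[2], d[3], w, step_px(w, params$overlap_fraction), m)
  res <- vector("list", nt - 1L)
  for (t in seq_len(nt - 1L)) {
    f1 <- stack$frames[t, , ]
    f2 <- stack$frames[t + 1L, , ]
    out <- purrr::pmap_dfr(grid, function(r0, c0, x, y) {
      a <- f1[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
      b <- f2[(r0 - m):(r0 + w + m - 1L), (c0 - m):(c0 + w + m - 1L)]
      cw <- correlate_window(a, b, m, params$subpixel)
      tibble::tibble(x = x, y = y, dx = cw$dx, dy = cw$dy, s2n = cw$s2n,
                     degenerate = cw$degenerate)
    })
    out$frame_pair <- t
    res[[t]] <- out
  }
  field <- dplyr::bind_rows(res) |>
    dplyr::mutate(
      vx = px_per_frame_to_um_min(stack, .data$dx),
      vy = px_per_frame_to_um_min(stack, .data$dy),
      speed = sqrt(.data$vx^2 + .data$vy^2),
      valid = !.data$degenerate
    ) |>
    dplyr::select("frame_pair", "x", "y", "dx", "dy", "vx", "vy", "speed",
                  "s2n", "valid", "degenerate")
  structure(field,
            class = c("piv_field", class(field)),
            params = params,
            pixel_size = stack$pixel_size,
            frame_interval = stack$frame_interval,
            window_px = w)
}

#' Flag spurious PIV vectors
#'
#' A vector is valid when its signal-to-noise ratio exceeds
#' `s2n_threshold` and its speed does not exceed `speed_cap` (um/min).
#' Only the `valid` flag changes; raw vector values are retained so
#' filtering is auditable, but invalid vectors are excluded from every
#' summary.
#'
#' @param field A `piv_field` from [compute_piv()].
#' @param params A [piv_params()]; defaults to the parameters the field was
#'   computed with.
#' @return The field with updated `valid` flags.
#' @export
filter_vectors <- function(field, params = NULL) {
  stopifnot(inherits(field, "piv_field"))
  if (is.null(params)) params <- attr(field, "params")
  if (nrow(field) == 0L) return(field)
  field$valid <- !field$degenerate &
    field$s2n > params$s2n_threshold &
    field$speed <= params$speed_cap
  field
}

#' Summarize flow direction and speed
#'
#' Pools the valid vectors of one or more PIV fields, computes the flow
#' angle `theta = atan2(-dy, dx)` in degrees (so up/animal = 90 deg under
#' the row-down image convention), assigns each vector to one of four
#' half-open 90-degree sectors centered on the axes (right `[-45, 45)`, up
#' `[45, 135)`, left `[135, 225)`, down `[225, 315)`), bins angles into a
#' rose histogram, and reports the arithmetic mean speed of valid vectors.
#'
#' @param fields A `piv_field` or a list of them (pooled).
#' @param rose_bins Number of equal rose-histogram bins over `[0, 360)`.
#' @return An object of class `directional_summary`: list with `quadrants`
#'   (tibble: direction, count, fraction), `rose` (tibble: bin_start,
#'   bin_mid, count), `n_valid`, `mean_speed`.
#' @export
directional_summary <- function(fields, rose_bins = 36) {
  if (inherits(fields, "piv_field")) fields <- list(fields)
  pooled <- dplyr::bind_rows(lapply(fields, function(f) {
    tibble::as_tibble(f)[, c("dx", "dy", "speed", "valid")]
  }))
  pooled <- dplyr::filter(pooled, .data$valid)
  if (nrow(pooled) == 0L) {
    stop("no valid vectors to summarize", call. = FALSE)
  }
  theta <- (atan2(-pooled$dy, pooled$dx) * 180 / pi) %% 360
  quadrant_names <- c("right", "up", "left", "down")
  qidx <- floor(((theta + 45) %% 360) / 90) + 1
  counts <- tabulate(qidx, nbins = 4L)
  edges <- seq(0, 360, length.out = rose_bins + 1)
  bin <- findInterval(theta, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  bin[bin > rose_bins] <- rose_bins  # guard for theta == 360 after rounding
  rose_counts <- tabulate(bin, nbins = rose_bins)
  structure(
    list(
      quadrants = tibble::tibble(direction = quadrant_names,
                                 count = counts,
                                 fraction = counts / sum(counts)),
      rose = tibble::tibble(bin_start = edges[-length(edges)],
                            bin_mid = edges[-length(edges)] +
                              180 / rose_bins,
                            count = rose_counts),
      n_valid = nrow(pooled),
      mean_speed = mean(pooled$speed)
    ),
    class = "directional_summary"
  )
}

#' @export
print.directional_summary <- function(x, ...) {
  cat(sprintf("<directional_summary> n_valid = %d, mean speed = %.4g um/min\n",
              x$n_valid, x$mean_speed))
  print(x$quadrants)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.directional_summary <- function(x, ...) x$quadrants

#' @exportS3Method generics::glance
glance.directional_summary <- function(x, ...) {
  tibble::tibble(n_valid = x$n_valid, mean_speed = x$mean_speed,
                 up_fraction = x$quadrants$fraction[x$quadrants$direction ==
                                                      "up"])
}

#' Chi-square goodness-of-fit on directional counts
#'
#' Pearson goodness-of-fit of observed category counts against reference
#' proportions: `X^2 = sum (O - E)^2 / E` with `E = N * reference`,
#' `df = k - 1`, upper-tail p-value (the one-tailed chi-square test applied
#' to quadrant distributions).
#'
#' @param observed Nonnegative counts (e.g. quadrant counts), or a
#'   `directional_summary`.
#' @param reference Reference proportions (all > 0, summing to 1). Default
#'   uniform.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`, `tails`,
#'   `n`.
#' @export
compare_quadrants <- function(observed, reference = NULL) {
  if (inherits(observed, "directional_summary")) {
    observed <- observed$quadrants$count
  }
  k <- length(observed)
  if (is.null(reference)) reference <- rep(1 / k, k)
  if (length(reference) != k) {
    stop("observed and reference lengths differ", call. = FALSE)
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed counts must be nonnegative with positive total",
         call. = FALSE)
  }
  if (any(reference <= 0)) {
    stop("all reference proportions must be > 0", call. = FALSE)
  }
  if (abs(sum(reference) - 1) > 1e-8) {
    stop("reference proportions must sum to 1", call. = FALSE)
  }
  n <- sum(observed)
  expected <- n * reference
  statistic <- sum((observed - expected)^2 / expected)
  df <- k - 1
  tibble::tibble(
    test = "chi-square goodness-of-fit",
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    tails = "one",
    n = n
  )
}
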