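#' Normalize a raw FRAP trace
#'
#' Full-scale (bleach-depth) normalization:
#' `N(t) = (F(t) - F_bleach) / (F_pre - F_bleach)` with `F_pre` the mean of
#' the prebleach frames and `F_bleach` the first postbleach value, so
#' `N = 0` at the bleach and `N = 1` at full recovery. Incomplete bleaching
#' is absorbed by the bleach-depth denominator. The result is invariant to
#' affine rescaling of the raw trace.
#'
#' @param raw Numeric vector of raw intensities per frame, or a data frame
#'   with an `intensity` column.
#' @param bleach_index Index of the first postbleach frame (>= 3, so that
#'   at least 2 prebleach frames exist).
#' @param frame_interval Seconds per frame.
#' @return A tibble of class `recovery_curve` with `time` (s, 0 at the
#'   bleach frame) and `intensity_norm`; normalization metadata in
#'   attributes `f_pre`, `f_bleach`, `n_pre`, `bleach_index`.
#' @export
normalize_frap <- function(raw, bleach_index, frame_interval) {
  if (is.data.frame(raw)) raw <- raw$intensity
  n <- length(raw)
  if (bleach_index < 3L || bleach_index > n) {
    stop("need >= 2 prebleach frames and a postbleach segment",
         call. = FALSE)
  }
  f_pre <- mean(raw[seq_len(bleach_index - 1L)])
  f_bleach <- raw[bleach_index]
  depth <- f_pre - f_bleach
  if (depth <= 0) {
    stop(sprintf(
      "no bleach detected: prebleach mean (%.6g) <= first postbleach value (%.6g)",
      f_pre, f_bleach), call. = FALSE)
  }
  curve <- tibble::tibble(
    time = (seq_len(n) - bleach_index) * frame_interval,
    intensity_norm = (raw - f_bleach) / depth
  )
  structure(curve, class = c("recovery_curve", class(curve)),
            f_pre = f_pre, f_bleach = f_bleach,
            n_pre = bleach_index - 1L, bleach_index = bleach_index)
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of `N(t) = m * (1 - exp(-t / tau))` over the
#' postbleach points of a normalized recovery curve
#' (Levenberg-Marquardt). The recovery half-time is `tau * ln 2` and the
#' mobile fraction is the plateau `m` of the normalized curve.
#' Initialization: `m0` = last observed value, `tau0` = time to reach half
#' of the final observed value.
#'
#' @param curve A `recovery_curve` from [normalize_frap()] (or a data frame
#'   with `time` and `intensity_norm`).
#' @return An object of class `frap_fit`: list with `tau`, `half_time`,
#'   `mobile_fraction`, `f0`, `f_inf` (raw scale, when normalization
#'   metadata is available), `residual_rms`, `n_post`, and the underlying
#'   `nls` fit. Supports [tidy()] and [glance()].
#' @export
fit_recovery <- function(curve) {
  post <- curve[curve$time >= 0, ]
  if (nrow(post) < 10L) {
    stop("need >= 10 postbleach points to fit recovery", call. = FALSE)
  }
  y <- post$intensity_norm
  t <- post$time
  m0 <- y[length(y)]
  if (!is.finite(m0) || m0 <= 0) m0 <- max(y, 0.1)
  half_level <- m0 / 2
  idx <- which(y >= half_level)
  tau0 <- if (length(idx) > 0 && t[idx[1]] > 0) t[idx[1]] / log(2)
          else stats::median(t[t > 0])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ m * (1 - exp(-t / tau)),
      data = data.frame(t = t, y = y),
      start = list(m = m0, tau = tau0),
      lower = c(m = 0, tau = 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf(
        "recovery fit did not converge (init m0 = %.4g, tau0 = %.4g): %s",
        m0, tau0, conditionMessage(e)), call. = FALSE)
    }
  )
  est <- stats::coef(fit)
  if (!is.finite(est[["tau"]]) || est[["tau"]] <= 0) {
    stop("recovery fit returned a nonpositive tau", call. = FALSE)
  }
  # flat (non-recovering) data: the plateau is indistinguishable from zero
  # and tau is unidentified
  if (est[["m"]] < 1e-6) {
    stop(sprintf(
      "recovery fit did not converge to an identifiable plateau (init m0 = %.4g, tau0 = %.4g)",
      m0, tau0), call. = FALSE)
  }
  f_pre <- attr(curve, "f_pre")
  f_bleach <- attr(curve, "f_bleach")
  structure(
    list(
      tau = unname(est[["tau"]]),
      half_time = unname(est[["tau"]]) * log(2),
      mobile_fraction = unname(est[["m"]]),
      f0 = f_bleach %||% 0,
      f_inf = if (!is.null(f_pre)) {
        f_bleach + est[["m"]] * (f_pre - f_bleach)
      } else est[["m"]],
      residual_rms = sqrt(mean(stats::residuals(fit)^2)),
      n_post = nrow(post),
      fit = fit,
      curve = curve
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> tau = %.4g s, half-time = %.4g s, mobile fraction = %.3f (RMS %.3g, n = %d)\n",
    x$tau, x$half_time, x$mobile_fraction, x$residual_rms, x$n_post))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.frap_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("tau", "mobile_fraction", "half_time"),
    estimate = c(x$tau, x$mobile_fraction, x$half_time),
    std.error = c(s["tau", "Std. Error"], s["m", "Std. Error"],
                  s["tau", "Std. Error"] * log(2))
  )
}

#' @exportS3Method generics::glance
glance.frap_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, half_time = x$half_time,
                 mobile_fraction = x$mobile_fraction,
                 residual_rms = x$residual_rms, n_post = x$n_post)
}

#' Measure the post-ablation gap width over time
#'
#' For each frame, the intensity profile along the animal-vegetal (row)
#' axis is averaged across the strip ROI's transverse extent; the gap is
#' the longest contiguous run of the profile below
#' `intensity_threshold_fraction` times the median pre-cut profile level,
#' with run edges located to sub-pixel precision by linear interpolation of
#' the threshold crossings.
#'
#' @param stack A [calibrated_stack()] of the ablation movie.
#' @param cut_frame Index of the first post-cut frame (frames before it are
#'   the pre-cut baseline; >= 2 required).
#' @param strip_roi Optional [roi_rect()] strip crossing the cut; default
#'   full frame.
#' @param intensity_threshold_fraction Threshold as a fraction of the
#'   median pre-cut level within the strip (default 0.5).
#' @return A tibble of class `recoil_series` with `frame`, `time` (s, 0 at
#'   `cut_frame`) and `width_um`.
#' @export
measure_gap_width <- function(stack, cut_frame, strip_roi = NULL,
                              intensity_threshold_fraction = 0.5) {
  stopifnot(inherits(stack, "calibrated_stack"))
  nt <- n_frames(stack)
  if (cut_frame < 2L) {
    stop("no pre-cut frame available for the baseline", call. = FALSE)
  }
  if (cut_frame > nt) stop("cut_frame beyond stack length", call. = FALSE)
  sub <- if (is.null(strip_roi)) stack else crop_roi(stack, strip_roi)
  profiles <- t(apply(sub$frames, 1, function(fr) {
    rowMeans(matrix(fr, dim(sub$frames)[2], dim(sub$frames)[3]))
  }))
  # profiles: nt x n_rows
  baseline <- stats::median(profiles[seq_len(cut_frame - 1L), ])
  thr <- intensity_threshold_fraction * baseline
  widths_px <- apply(profiles, 1, function(p) gap_run_width(p, thr))
  tibble::tibble(
    frame = seq_len(nt),
    time = frames_to_seconds(stack, seq_len(nt) - cut_frame),
    width_um = px_to_um(stack, widths_px)
  ) |>
    structure(class = c("recoil_series", "tbl_df", "tbl", "data.frame"),
              cut_frame = cut_frame, threshold = thr, baseline = baseline)
}

# longest contiguous below-threshold run of a profile, with sub-pixel edges
# by linear interpolation at the threshold crossings
gap_run_width <- function(p, thr) {
  below <- p < thr
  if (!any(below)) return(0)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  left <- if (i0 > 1L) {
    # crossing between i0-1 (>= thr) and i0 (< thr)
    (i0 - 1) + (p[i0 - 1L] - thr) / (p[i0 - 1L] - p[i0])
  } else i0 - 0.5
  right <- if (i1 < length(p)) {
    i1 + (thr - p[i1]) / (p[i1 + 1L] - p[i1])
  } else i1 + 0.5
  max(0, right - left)
}

#' Initial recoil velocity from a gap-width series
#'
#' Ordinary least-squares slope of gap width versus time over the first
#' `fit_frames` post-cut points — the noise-robust generalization of the
#' "width of opening over acquisition time" difference quotient (to which
#' it reduces at `fit_frames = 2`).
#'
#' @param series A `recoil_series` from [measure_gap_width()] (or a data
#'   frame with `time` and `width_um`).
#' @param fit_frames Number of post-cut points in the fit window
#'   (default 5).
#' @return A one-row tibble: `velocity_um_s`, `std_error`, `n`,
#'   `fit_window_s`.
#' @export
recoil_velocity <- function(series, fit_frames = 5) {
  post <- series[series$time >= 0, ]
  if (fit_frames < 2L) stop("fit_frames must be >= 2", call. = FALSE)
  if (nrow(post) < fit_frames) {
    stop("fewer post-cut points than fit_frames", call. = FALSE)
  }
  win <- post[seq_len(fit_frames), ]
  fit <- stats::lm(width_um ~ time, data = win)
  s <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(
    velocity_um_s = unname(stats::coef(fit)["time"]),
    std_error = if (nrow(win) > 2) s["time", "Std. Error"] else NA_real_,
    n = nrow(win),
    fit_window_s = max(win$time) - min(win$time)
  )
}

#' Mean ROI intensity over time, with optional normalization
#'
#' Computes the mean pixel intensity inside an ROI per frame.
#' `"first-frame"` mode divides by the frame-1 value (fluorescence
#' accumulation relative to the start); `"blastoderm-roi"` mode divides
#' each frame's ROI mean by the same frame's reference-ROI mean
#' (stage-matched comparison normalized to the embryo's blastoderm, also
#' compensating global per-frame intensity changes).
#'
#' @param stack A [calibrated_stack()].
#' @param roi Measurement ROI.
#' @param normalization `"none"`, `"first-frame"` or `"blastoderm-roi"`.
#' @param reference_roi Reference ROI; required for `"blastoderm-roi"`.
#' @return A tibble of class `intensity_series` with `frame`, `time_s`,
#'   `time_min`, `intensity` and `intensity_norm`; the mode is stored in
#'   the `normalization` attribute.
#' @export
intensity_series <- function(stack, roi,
                             normalization = c("none", "first-frame",
                                               "blastoderm-roi"),
                             reference_roi = NULL) {
  normalization <- match.arg(normalization)
  roi_mean_per_frame <- function(r) {
    sub <- crop_roi(stack, r)
    member <- attr(sub, "roi_mask")
    vals <- apply(sub$frames, 1, function(fr) {
      fr <- matrix(fr, dim(sub$frames)[2], dim(sub$frames)[3])
      mean(fr[member])
    })
    if (sum(member) == 0L) stop("empty roi", call. = FALSE)
    vals
  }
  raw <- roi_mean_per_frame(roi)
  norm <- switch(normalization,
    "none" = raw,
    "first-frame" = {
      if (raw[1] == 0) stop("zero first-frame mean", call. = FALSE)
      raw / raw[1]
    },
    "blastoderm-roi" = {
      if (is.null(reference_roi)) {
        stop("reference_roi is required for blastoderm-roi normalization",
             call. = FALSE)
      }
      ref <- roi_mean_per_frame(reference_roi)
      if (any(ref == 0)) stop("zero reference mean", call. = FALSE)
      raw / ref
    }
  )
  nt <- n_frames(stack)
  tibble::tibble(
    frame = seq_len(nt),
    time_s = frames_to_seconds(stack, seq_len(nt) - 1L),
    time_min = frames_to_seconds(stack, seq_len(nt) - 1L) / 60,
    intensity = raw,
    intensity_norm = norm
  ) |>
    structure(class = c("intensity_series", "tbl_df", "tbl", "data.frame"),
              normalization = normalization)
}

#' Fluorescence accumulation slope
#'
#' Ordinary least-squares slope of first-frame-normalized intensity versus
#' time in minutes — the per-embryo accumulation rate summarized across
#' genotypes.
#'
#' @param series An `intensity_series` in `"first-frame"` normalization
#'   mode with at least 3 time points.
#' @return A one-row tibble: `slope_per_min`, `std_error`, `n`.
#' @export
accumulation_slope <- function(series) {
  if (!identical(attr(series, "normalization"), "first-frame")) {
    stop("accumulation_slope requires a first-frame-normalized series",
         call. = FALSE)
  }
  if (nrow(series) < 3L) stop("need >= 3 time points", call. = FALSE)
  fit <- stats::lm(intensity_norm ~ time_min, data = series)
  s <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(
    slope_per_min = unname(stats::coef(fit)["time_min"]),
    std_error = s["time_min", "Std. Error"],
    n = nrow(series)
  )
}
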