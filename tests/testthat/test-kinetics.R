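test_that("FRAP normalization implements bleach-depth scaling", {
  # prebleach mean 100, first postbleach 40: a later value of 80 maps to
  # (80-40)/(100-40) = 2/3, and a value equal to the prebleach mean to 1
  raw <- c(100, 100, 100, 40, 60, 80, 100)
  cv <- normalize_frap(raw, bleach_index = 4, frame_interval = 0.5)
  expect_equal(cv$intensity_norm[6], (80 - 40) / (100 - 40))
  expect_equal(cv$intensity_norm[7], 1)
  expect_equal(cv$intensity_norm[4], 0)
  expect_equal(cv$time[4], 0)
  expect_equal(cv$time[1], -1.5)
  expect_error(normalize_frap(c(10, 10, 20, 30), 3, 0.5), "no bleach")
  expect_error(normalize_frap(raw, 2, 0.5), "prebleach")
})

test_that("FRAP normalization is affine-invariant and matches the closed form", {
  res <- make_frap_trace(tau = 10, f_pre = 1, f_bleach = 0.3, f_inf = 0.8,
                         n_pre = 5, n_post = 60, dt = 0.5, noise_sigma = 0)
  raw <- res$trace$intensity
  cv <- normalize_frap(raw, bleach_index = 6, frame_interval = 0.5)
  # closed-form oracle: N(t) = m (1 - exp(-t/tau)), m = (f_inf - f_b)/(f_pre - f_b)
  m <- (0.8 - 0.3) / (1 - 0.3)
  post <- cv[cv$time >= 0, ]
  expect_equal(post$intensity_norm, m * (1 - exp(-post$time / 10)),
               tolerance = 1e-10)
  # affine invariance: a*F + b leaves the curve unchanged
  cv2 <- normalize_frap(3.7 * raw + 11, bleach_index = 6,
                        frame_interval = 0.5)
  expect_equal(cv2$intensity_norm, cv$intensity_norm, tolerance = 1e-10)
})

test_that("recovery fitting recovers tau and fixes half_time = tau ln 2", {
  res <- make_frap_trace(tau = 10, n_pre = 5, n_post = 120, dt = 0.5,
                         noise_sigma = 0)
  cv <- normalize_frap(res$trace$intensity, 6, 0.5)
  fit <- fit_recovery(cv)
  expect_equal(fit$tau, 10, tolerance = 0.001)
  expect_equal(fit$half_time, fit$tau * log(2))  # identity, exact
  expect_equal(fit$mobile_fraction, (0.8 - 0.3) / (1 - 0.3),
               tolerance = 0.01)
  # raw-scale plateau reconstruction
  expect_equal(fit$f_inf, 0.8, tolerance = 0.01)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_setequal(td$term, c("tau", "mobile_fraction", "half_time"))
  expect_equal(glance(fit)$tau, fit$tau)
})

test_that("recovery fitting tolerates noise at the stated level", {
  res <- make_frap_trace(tau = 10, n_pre = 5, n_post = 120, dt = 0.5,
                         noise_sigma = 0.02, seed = 11)
  cv <- normalize_frap(res$trace$intensity, 6, 0.5)
  fit <- fit_recovery(cv)
  expect_lt(abs(fit$tau - 10) / 10, 0.05)
})

test_that("degenerate recovery input fails loudly", {
  flat <- tibble::tibble(time = seq(0, 20, by = 0.5),
                         intensity_norm = 0)
  expect_error(fit_recovery(flat), "converge|plateau")
  short <- tibble::tibble(time = c(-1, 0, 1), intensity_norm = c(1, 0, 0.5))
  expect_error(fit_recovery(short), ">= 10")
})

test_that("gap width measurement counts a binary gap exactly", {
  # binary strip with a 10 px gap at 0.2 um/px reads 2.0 um
  nr <- 60; nc <- 30
  strip <- matrix(100, nr, nc)
  gapped <- strip
  gapped[26:35, ] <- 0
  st <- calibrated_stack(list(strip, gapped, gapped), pixel_size = 0.2,
                         frame_interval = 1)
  rs <- measure_gap_width(st, cut_frame = 2)
  expect_equal(rs$width_um[1], 0)      # pre-cut frame: no gap
  expect_equal(rs$width_um[2], 2.0, tolerance = 0.2 * 0.5)
  expect_equal(rs$time, c(-1, 0, 1))
  expect_error(measure_gap_width(st, cut_frame = 1), "pre-cut")
})

test_that("gap widths track the generator ground truth within 1 px", {
  res <- make_ablation_stack(w_inf = 3, tau_r = 2, n_frames = 30, dt = 0.25,
                             pixel_size = 0.1, shape = c(96, 96),
                             strip_um = 6, seed = 13)
  # strip ROI over the bright band only (rows within the 6 um strip)
  strip_px <- 6 / 0.1
  y0 <- (96 - strip_px) / 2 + 3
  roi <- roi_rect(1, y0, 96, strip_px - 6)
  rs <- measure_gap_width(res$stack, cut_frame = res$cut_frame,
                          strip_roi = roi)
  gt <- res$ground_truth$widths
  expect_true(all(abs(rs$width_um - gt$width_um) <= 0.1))
})

test_that("recoil velocity is the early-window slope", {
  # exact line: widths 2, 3, 4 um at t = 0, 1, 2 s -> 1.0 um/s
  series <- tibble::tibble(time = c(-1, 0, 1, 2), width_um = c(0, 2, 3, 4))
  v <- recoil_velocity(series, fit_frames = 3)
  expect_equal(v$velocity_um_s, 1.0)
  expect_equal(v$std_error, 0)
  # constant width: zero velocity
  const <- tibble::tibble(time = 0:5, width_um = 2)
  expect_equal(recoil_velocity(const, 4)$velocity_um_s, 0)
  expect_error(recoil_velocity(series, 1), ">= 2")
  expect_error(recoil_velocity(series, 9), "fewer")
})

test_that("recoil velocity approximates w_inf/tau_r on the saturating family", {
  res <- make_ablation_stack(w_inf = 3, tau_r = 2, n_frames = 40, dt = 0.1,
                             pixel_size = 0.05, shape = c(160, 120),
                             strip_um = 5, seed = 17)
  strip_px <- 5 / 0.05
  y0 <- (160 - strip_px) / 2 + 5
  roi <- roi_rect(1, y0, 120, strip_px - 10)
  rs <- measure_gap_width(res$stack, cut_frame = res$cut_frame,
                          strip_roi = roi)
  v <- recoil_velocity(rs, fit_frames = 5)
  expect_lt(abs(v$velocity_um_s - 1.5) / 1.5, 0.1)
  # early-window linearization: widening the window can only lower the
  # slope estimate (monotone underestimation of the initial velocity)
  v_seq <- vapply(c(3, 6, 10, 16), function(k) {
    recoil_velocity(rs, k)$velocity_um_s
  }, numeric(1))
  expect_true(all(diff(v_seq) < 0))
})

test_that("intensity series normalizations behave as declared", {
  # constant stack, first-frame mode: all ones
  st <- calibrated_stack(array(50, dim = c(5, 20, 20)), 1, 30)
  roi <- roi_rect(3, 3, 10, 10)
  s1 <- intensity_series(st, roi, "first-frame")
  expect_true(all(s1$intensity_norm == 1))
  # ratio mode: roi mean 200, reference mean 100 -> 2.0
  fr <- matrix(100, 30, 30); fr[1:10, 1:10] <- 200
  st2 <- calibrated_stack(list(fr, fr), 1, 30)
  s2 <- intensity_series(st2, roi_rect(1, 1, 10, 10), "blastoderm-roi",
                         reference_roi = roi_rect(15, 15, 10, 10))
  expect_true(all(s2$intensity_norm == 2))
  expect_error(intensity_series(st2, roi, "blastoderm-roi"), "reference")
})

test_that("a linear intensity ramp yields its slope back", {
  # frames scaled by 1 + 0.1 * t_min
  t_min <- (0:9) * 0.5
  frames <- lapply(t_min, function(tm) matrix(80 * (1 + 0.1 * tm), 25, 25))
  st <- calibrated_stack(frames, 1, 30)
  s <- intensity_series(st, roi_rect(2, 2, 20, 20), "first-frame")
  expect_equal(s$intensity_norm, 1 + 0.1 * t_min, tolerance = 1e-10)
  sl <- accumulation_slope(s)
  expect_equal(sl$slope_per_min, 0.1, tolerance = 1e-10)
  # blastoderm mode is invariant to global per-frame scaling
  sb <- intensity_series(st, roi_rect(2, 2, 10, 10), "blastoderm-roi",
                         reference_roi = roi_rect(14, 14, 10, 10))
  expect_true(all(abs(sb$intensity_norm - 1) < 1e-10))
  # unnormalized input is rejected by the slope fit
  s_none <- intensity_series(st, roi_rect(2, 2, 20, 20), "none")
  expect_error(accumulation_slope(s_none), "first-frame")
})

test_that("noisy accumulation slopes agree with truth within fit error", {
  set.seed(5)
  t_min <- seq(0, 14.5, by = 0.5)
  y <- 1 + 0.02 * t_min + rnorm(30, sd = 0.01)
  s <- structure(
    tibble::tibble(frame = seq_along(t_min), time_s = t_min * 60,
                   time_min = t_min, intensity = y, intensity_norm = y),
    class = c("intensity_series", "tbl_df", "tbl", "data.frame"),
    normalization = "first-frame")
  sl <- accumulation_slope(s)
  expect_lt(abs(sl$slope_per_min - 0.02), 3 * sl$std_error)
})
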