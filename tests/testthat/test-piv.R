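make_texture <- function(seed = 3, shape = c(160, 160)) {
  sc <- flow_scenario("uniform", vx = 0, vy = 0, n_frames = 2,
                      noise = noise_model(), seed = seed)
  make_flow_stack(sc, shape = shape)$stack$frames[1, , ]
}

test_that("the FFT correlation engine matches the direct-sum oracle", {
  set.seed(21)
  w <- 16; m <- 4
  a <- matrix(runif(w^2), w)
  b <- matrix(runif((w + 2 * m)^2), w + 2 * m)
  oracle <- direct_correlation_map(a, b, m)
  pk <- which(oracle == max(oracle), arr.ind = TRUE)[1, ]
  cw <- yolkflow:::correlate_window(a, b, m, subpixel = FALSE)
  expect_equal(cw$dy, unname(pk[1]) - m - 1)
  expect_equal(cw$dx, unname(pk[2]) - m - 1)
  # s2n agrees with the oracle's peak ratio outside a 3x3 exclusion
  excl <- oracle
  excl[max(1, pk[1] - 1):min(2 * m + 1, pk[1] + 1),
       max(1, pk[2] - 1):min(2 * m + 1, pk[2] + 1)] <- -Inf
  expect_equal(cw$s2n, max(oracle) / max(excl), tolerance = 1e-10)
})

test_that("identity frame pairs give zero displacement with finite s2n", {
  img <- make_texture(1)
  st <- calibrated_stack(list(img, img), 0.25, 0.5)
  pf_int <- compute_piv(st, piv_params(subpixel = FALSE))
  expect_true(all(pf_int$dx == 0 & pf_int$dy == 0))
  # with subpixel refinement the autocorrelation peak stays within the
  # stated bias bound of the origin
  pf <- compute_piv(st)
  expect_lt(max(abs(pf$dx), abs(pf$dy)), 0.05)
  expect_true(all(is.finite(pf$s2n) | pf$s2n == Inf))
  expect_true(all(pf$s2n > 1))
})

test_that("integer circular shifts are recovered to better than 0.05 px", {
  img <- make_texture(2)
  for (sh in list(c(3, 0), c(0, -5), c(-4, 2), c(5, 5))) {
    f2 <- circshift(img, sh[1], sh[2])
    st <- calibrated_stack(list(img, f2), 0.25, 0.5)
    pf <- compute_piv(st)
    expect_lt(max(abs(pf$dy - sh[1])), 0.05)
    expect_lt(max(abs(pf$dx - sh[2])), 0.05)
  }
})

test_that("constant windows are flagged degenerate, not crashed", {
  img <- matrix(1, 100, 100)
  st <- calibrated_stack(list(img, img), 0.5, 1)
  pf <- compute_piv(st, piv_params(window_um = 10))
  expect_true(all(pf$degenerate))
  expect_true(all(pf$s2n == 0))
  expect_true(all(!filter_vectors(pf)$valid))
})

test_that("window larger than the frame is a parameter error", {
  img <- matrix(runif(400), 20, 20)
  st <- calibrated_stack(list(img, img), 1, 1)
  expect_error(compute_piv(st, piv_params(window_um = 64)), "larger")
  expect_error(compute_piv(calibrated_stack(array(0, c(1, 64, 64)), 1, 1)),
               "2 frames")
})

test_that("velocity calibration holds per vector and vectors tile the grid", {
  img <- make_texture(4)
  st <- calibrated_stack(list(img, circshift(img, 2, -1)), 0.25, 0.5)
  pf <- compute_piv(st)
  expect_equal(pf$vx, pf$dx * 0.25 / 0.5 * 60, tolerance = 1e-12)
  expect_equal(pf$vy, pf$dy * 0.25 / 0.5 * 60, tolerance = 1e-12)
  # conservation: number of vectors equals the tiling count however the
  # validity flags land
  w <- attr(pf, "window_px")
  expect_equal(nrow(pf),
               nrow(yolkflow:::piv_grid(160, 160, w, w %/% 2, 8)))
  pf_f <- filter_vectors(pf, piv_params(s2n_threshold = 1e6))
  expect_equal(nrow(pf_f), nrow(pf))
})

test_that("uniform flow with shot noise is recovered within 10%", {
  sc <- flow_scenario("uniform", vx = 0, vy = -0.5, n_frames = 8,
                      noise = noise_model(poisson = TRUE,
                                          photon_budget = 200,
                                          gaussian_sd = 2),
                      seed = 15)
  res <- make_flow_stack(sc, pixel_size = 0.25, frame_interval = 6,
                         shape = c(192, 192))
  pf <- filter_vectors(compute_piv(res$stack))
  v <- dplyr::filter(pf, valid)
  expect_gt(nrow(v), 50)
  expect_lt(abs(mean(v$vy) - (-0.5)), 0.05)
  expect_lt(abs(mean(v$vx) - 0), 0.05)
})

test_that("rotating the stack 90 degrees rotates the recovered flow", {
  # rotation (r, c) -> (nc + 1 - c, r) maps a displacement (dx, dy) to
  # (dy, -dx); an upward flow becomes a leftward flow
  rot <- function(m) {
    nc <- ncol(m)
    out <- matrix(0, nc, nrow(m))
    for (j in seq_len(ncol(m))) out[nc + 1 - j, ] <- m[, j]
    out
  }
  sc <- flow_scenario("uniform", vx = 0.1, vy = -0.4, n_frames = 6,
                      noise = noise_model(poisson = TRUE,
                                          photon_budget = 200),
                      seed = 23)
  res <- make_flow_stack(sc, pixel_size = 0.25, frame_interval = 6,
                         shape = c(192, 192))
  strot <- calibrated_stack(
    lapply(seq_len(n_frames(res$stack)),
           function(i) rot(get_frame(res$stack, i))),
    0.25, 6)
  v0 <- dplyr::filter(filter_vectors(compute_piv(res$stack)), valid)
  v1 <- dplyr::filter(filter_vectors(compute_piv(strot)), valid)
  speed <- sqrt(0.1^2 + 0.4^2)
  expect_lt(abs(mean(v1$vx) - mean(v0$vy)), 0.1 * speed)
  expect_lt(abs(mean(v1$vy) - (-mean(v0$vx))), 0.1 * speed)
  # quadrant fractions permute: up -> left
  s0 <- directional_summary(filter_vectors(compute_piv(res$stack)))
  s1 <- directional_summary(filter_vectors(compute_piv(strot)))
  up0 <- s0$quadrants$fraction[s0$quadrants$direction == "up"]
  left1 <- s1$quadrants$fraction[s1$quadrants$direction == "left"]
  expect_lt(abs(up0 - left1), 0.1)
})

test_that("vector filtering applies the speed cap and s2n threshold exactly", {
  img <- make_texture(5)
  st <- calibrated_stack(list(img, img), 0.25, 0.5)
  pf <- compute_piv(st)
  # forge a field with known speeds and s2n values
  pf$s2n <- rep_len(c(0.5, 1.5), nrow(pf))
  pf$speed <- rep_len(c(0.4, 1.2, 0.9), nrow(pf))
  out <- filter_vectors(pf, piv_params(s2n_threshold = 1, speed_cap = 1))
  expect_equal(out$valid, out$s2n > 1 & out$speed <= 1)
  # a 1.2 um/min vector dies to the 1 um/min cap even at high s2n
  expect_false(any(out$valid[out$speed == 1.2]))
  # raw values unchanged
  expect_equal(out$dx, pf$dx)
  # monotone: raising the threshold or tightening the cap never
  # resurrects a vector
  stricter <- filter_vectors(pf, piv_params(s2n_threshold = 1.4,
                                            speed_cap = 0.5))
  expect_true(all(out$valid | !stricter$valid))
})

test_that("directional summary follows the image orientation convention", {
  img <- make_texture(6)
  st <- calibrated_stack(list(img, img), 0.25, 0.5)
  pf <- compute_piv(st)[1:4, ]
  # single upward vector (dx, dy) = (0, -1): up fraction 1
  one <- pf[1, ]
  one$dx <- 0; one$dy <- -1; one$valid <- TRUE
  attr(one, "params") <- attr(pf, "params")
  class(one) <- class(pf)
  s <- directional_summary(one)
  expect_equal(s$quadrants$fraction[s$quadrants$direction == "up"], 1)
  # four axis-aligned unit vectors: one per quadrant
  four <- pf
  four$dx <- c(1, -1, 0, 0); four$dy <- c(0, 0, -1, 1)
  four$valid <- TRUE
  s4 <- directional_summary(four)
  expect_equal(s4$quadrants$fraction, rep(0.25, 4))
  expect_equal(sum(s4$rose$count), 4)
  # no valid vectors is an explicit error
  none <- pf; none$valid <- FALSE
  expect_error(directional_summary(none), "no valid vectors")
})

test_that("rose binning matches a direct histogram on random angles", {
  set.seed(3)
  n <- 1000
  theta <- runif(n, 0, 360)
  dx <- cos(theta * pi / 180)
  dy <- -sin(theta * pi / 180)
  df <- tibble::tibble(frame_pair = 1, x = 0, y = 0, dx = dx, dy = dy,
                       vx = dx, vy = dy, speed = 1, s2n = 2, valid = TRUE,
                       degenerate = FALSE)
  class(df) <- c("piv_field", class(df))
  s <- directional_summary(df, rose_bins = 36)
  expect_equal(sum(s$rose$count), n)
  oracle <- table(cut(theta, seq(0, 360, by = 10), right = FALSE))
  expect_equal(s$rose$count, as.vector(oracle))
  # quadrant fractions within 3 binomial SDs of uniform
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(s$quadrants$fraction - 0.25) < 3 * se))
  expect_equal(s$n_valid, n)
  expect_equal(s$mean_speed, 1)
})

test_that("quadrant chi-square matches hand computation and stats::chisq.test", {
  # perfect fit
  r0 <- compare_quadrants(c(25, 25, 25, 25))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # worked value: observed (30,20,25,25) vs uniform, N = 100
  r <- compare_quadrants(c(30, 20, 25, 25))
  expect_equal(r$statistic, 2.0)
  expect_equal(r$df, 3)
  # independent oracle: survival function of chi-square(3), and the stock
  # goodness-of-fit test
  expect_equal(r$p_value, pchisq(2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  ct <- suppressWarnings(stats::chisq.test(c(30, 20, 25, 25),
                                           p = rep(0.25, 4)))
  expect_equal(r$statistic, unname(ct$statistic))
  expect_equal(r$p_value, ct$p.value)
  # argument validation
  expect_error(compare_quadrants(c(1, 2, 3), rep(0.25, 4)), "lengths")
  expect_error(compare_quadrants(c(1, 2, 3, 4), c(0.5, 0.5, 0, 0)), "> 0")
  expect_error(compare_quadrants(c(0, 0, 0, 0)), "positive total")
  # chi_square_gof is the same computation re-exported
  expect_identical(chi_square_gof(c(30, 20, 25, 25)), r)
})
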