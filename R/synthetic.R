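#' Flow scenario specification
#'
#' Describes the programmed velocity field and imaging texture for
#' [make_flow_stack()]. Three field kinds are supported:
#' `uniform` (one velocity everywhere), `gradient` (vertical speed varying
#' linearly from the top row to the bottom row), and `mixture`
#' (each punctum is independently assigned to move up, down, left or right
#' with given class fractions and per-class speeds — emulating the mixed
#' directionality of cortical actin flow).
#'
#' Velocities use image coordinates: `vx` positive rightward, `vy` positive
#' downward (vegetal); upward (animal) flow has negative `vy`.
#'
#' @param kind `"uniform"`, `"gradient"` or `"mixture"`.
#' @param vx,vy Uniform-field velocity components (um/min).
#' @param top_speed,bottom_speed Gradient-field vertical velocities (um/min,
#'   signed `vy`) at the top and bottom rows.
#' @param fractions Named fractions for `mixture` (`up`, `down`, `left`,
#'   `right`), summing to 1.
#' @param speeds Per-class speeds (um/min) for `mixture`; a single number is
#'   recycled.
#' @param puncta_density Puncta per square micrometre.
#' @param puncta_sigma PSF standard deviation in micrometres.
#' @param n_frames Number of frames (>= 2).
#' @param noise Noise model from [noise_model()].
#' @param seed Integer seed (NULL = use current RNG state).
#' @return A `flow_scenario` list.
#' @export
flow_scenario <- function(kind = c("uniform", "gradient", "mixture"),
                          vx = 0, vy = -0.5,
                          top_speed = -0.5, bottom_speed = 0,
                          fractions = c(up = 0.7, down = 0.3, left = 0,
                                        right = 0),
                          speeds = 0.5,
                          puncta_density = 0.3, puncta_sigma = 0.3,
                          n_frames = 30,
                          noise = noise_model(poisson = TRUE,
                                              photon_budget = 200,
                                              gaussian_sd = 2),
                          seed = NULL) {
  kind <- match.arg(kind)
  if (puncta_density <= 0) stop("puncta_density must be > 0", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (kind == "mixture") {
    fractions <- fractions[c("up", "down", "left", "right")]
    fractions[is.na(fractions)] <- 0
    if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
      stop("mixture fractions must be nonnegative and sum to 1",
           call. = FALSE)
    }
    speeds <- rep_len(speeds, 4L)
    if (any(speeds < 0)) stop("speeds must be >= 0", call. = FALSE)
  }
  structure(list(kind = kind, vx = vx, vy = vy, top_speed = top_speed,
                 bottom_speed = bottom_speed, fractions = fractions,
                 speeds = speeds, puncta_density = puncta_density,
                 puncta_sigma = puncta_sigma, n_frames = n_frames,
                 noise = noise, seed = seed),
            class = "flow_scenario")
}

# per-puncta velocity (um/min) under a scenario; positions in px
scenario_velocities <- function(scenario, py, n_rows) {
  n <- length(py)
  switch(scenario$kind,
    uniform = list(vx = rep(scenario$vx, n), vy = rep(scenario$vy, n),
                   class = rep(NA_character_, n)),
    gradient = {
      f <- (py - 1) / max(1, n_rows - 1)
      list(vx = rep(0, n),
           vy = scenario$top_speed + f * (scenario$bottom_speed -
                                          scenario$top_speed),
           class = rep(NA_character_, n))
    },
    mixture = {
      cls <- sample(c("up", "down", "left", "right"), n, replace = TRUE,
                    prob = scenario$fractions)
      sp <- scenario$speeds[match(cls, c("up", "down", "left", "right"))]
      list(vx = ifelse(cls == "left", -sp, ifelse(cls == "right", sp, 0)),
           vy = ifelse(cls == "up", -sp, ifelse(cls == "down", sp, 0)),
           class = cls)
    }
  )
}

#' Generate a punctate-actin flow movie with known velocity field
#'
#' Seeds the field of view with Gaussian puncta (the texture PIV tracks),
#' advects them by the programmed velocity field with subpixel analytic
#' rendering, wraps positions periodically at the boundaries so puncta
#' density is stationary, and applies the camera noise model last. The
#' ground truth holds the true velocity field sampled on the default PIV
#' grid plus each punctum's class assignment.
#'
#' @param scenario A [flow_scenario()].
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds per frame.
#' @param shape `c(rows, cols)` in pixels.
#' @param piv_params PIV parameters used to lay out the ground-truth grid.
#' @return List with elements `stack` ([calibrated_stack()]) and
#'   `ground_truth`.
#' @export
make_flow_stack <- function(scenario, pixel_size = 0.25,
                            frame_interval = 0.5, shape = c(128, 128),
                            piv_params = NULL) {
  stopifnot(inherits(scenario, "flow_scenario"))
  if (is.null(piv_params)) piv_params <- piv_params()
  w_px <- window_px(piv_params$window_um, pixel_size)
  if (any(shape < 2 * w_px)) {
    stop("shape too small for >= 2x2 PIV windows at the default window size",
         call. = FALSE)
  }
  with_seed_if(scenario$seed, {
    nr <- shape[1]; nc <- shape[2]
    n_puncta <- max(4L, round(scenario$puncta_density *
                              (nr * pixel_size) * (nc * pixel_size)))
    px <- stats::runif(n_puncta, 0.5, nc + 0.5)
    py <- stats::runif(n_puncta, 0.5, nr + 0.5)
    vel <- scenario_velocities(scenario, py, nr)
    # um/min -> px/frame
    to_px <- frame_interval / 60 / pixel_size
    dxf <- vel$vx * to_px
    dyf <- vel$vy * to_px
    max_disp <- max(sqrt(dxf^2 + dyf^2))
    if (max_disp > w_px / 2) {
      warning("per-frame displacement exceeds half the PIV window; ",
              "flow is unrecoverable at these settings", call. = FALSE)
    }
    sigma_px <- scenario$puncta_sigma / pixel_size
    frames <- vector("list", scenario$n_frames)
    for (f in seq_len(scenario$n_frames)) {
      img <- matrix(0, nr, nc)
      for (i in seq_len(n_puncta)) {
        img <- add_gaussian_spot(img, px[i], py[i], sigma_px, 1)
      }
      frames[[f]] <- apply_noise(img, scenario$noise)
      px <- (px + dxf - 0.5) %% nc + 0.5
      py <- (py + dyf - 0.5) %% nr + 0.5
    }
    stack <- calibrated_stack(frames, pixel_size, frame_interval,
                              "synthetic actin puncta")
    grid <- piv_grid(nr, nc, w_px,
                     step_px(w_px, piv_params$overlap_fraction),
                     piv_params$search_margin_px)
    gt_field <- switch(scenario$kind,
      uniform = tibble::tibble(x = grid$x, y = grid$y,
                               vx = scenario$vx, vy = scenario$vy),
      gradient = {
        fr <- (grid$y - 1) / max(1, nr - 1)
        tibble::tibble(x = grid$x, y = grid$y, vx = 0,
                       vy = scenario$top_speed +
                            fr * (scenario$bottom_speed - scenario$top_speed))
      },
      mixture = {
        mv <- c(
          vx = sum(scenario$fractions * c(0, 0, -1, 1) * scenario$speeds),
          vy = sum(scenario$fractions * c(-1, 1, 0, 0) * scenario$speeds)
        )
        tibble::tibble(x = grid$x, y = grid$y, vx = mv["vx"], vy = mv["vy"])
      })
    gt <- list(
      scenario = "flow",
      kind = scenario$kind,
      field = gt_field,
      puncta = tibble::tibble(class = vel$class, vx = vel$vx, vy = vel$vy),
      pixel_size = pixel_size,
      frame_interval = frame_interval
    )
    list(stack = stack, ground_truth = gt)
  })
}

#' Generate a FRAP intensity trace with known kinetics
#'
#' Prebleach plateau at `f_pre` for `n_pre` frames, then single-exponential
#' recovery `F(t) = f_inf - (f_inf - f_bleach) * exp(-t / tau)` from the
#' bleach frame onward (t = 0 at the first postbleach frame), with optional
#' Gaussian noise. Incomplete bleaching is the normal case
#' (`f_bleach > 0`).
#'
#' @param tau Recovery time constant (s).
#' @param f_pre,f_bleach,f_inf Prebleach, first-postbleach and plateau
#'   intensities; require `f_bleach < f_inf <= f_pre`.
#' @param n_pre,n_post Number of pre/postbleach frames.
#' @param dt Frame interval (s).
#' @param noise_sigma Gaussian noise SD (intensity units).
#' @param seed Integer seed or NULL.
#' @return List with `trace` (tibble: `frame`, `time`, `intensity`, `phase`)
#'   and `ground_truth`.
#' @export
make_frap_trace <- function(tau, f_pre = 1, f_bleach = 0.3, f_inf = 0.8,
                            n_pre = 10, n_post = 120, dt = 0.5,
                            noise_sigma = 0, seed = NULL) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (f_bleach >= f_pre) {
    stop("f_bleach must be below f_pre (no bleach otherwise)", call. = FALSE)
  }
  if (!(f_bleach < f_inf && f_inf <= f_pre)) {
    stop("require f_bleach < f_inf <= f_pre", call. = FALSE)
  }
  with_seed_if(seed, {
    t_post <- (seq_len(n_post) - 1) * dt
    values <- c(rep(f_pre, n_pre),
                f_inf - (f_inf - f_bleach) * exp(-t_post / tau))
    if (noise_sigma > 0) {
      values <- values + stats::rnorm(length(values), sd = noise_sigma)
    }
    trace <- tibble::tibble(
      frame = seq_along(values),
      time = c(-(n_pre:1) * dt, t_post),
      intensity = values,
      phase = rep(c("pre", "post"), c(n_pre, n_post))
    )
    gt <- list(scenario = "frap", tau = tau, half_time = tau * log(2),
               f_pre = f_pre, f_bleach = f_bleach, f_inf = f_inf,
               mobile_fraction = (f_inf - f_bleach) / (f_pre - f_bleach),
               dt = dt, bleach_index = n_pre + 1L)
    list(trace = trace, ground_truth = gt)
  })
}

#' Generate a laser-ablation movie with known recoil kinetics
#'
#' A bright horizontal cortical strip develops a central dark gap from the
#' cut frame onward; the gap width along the animal-vegetal (row) axis grows
#' with saturating kinetics `w(t) = w_inf * (1 - exp(-t / tau_r))`, giving a
#' true initial recoil velocity `w_inf / tau_r`. Gap edges are rendered with
#' a smooth (Gaussian CDF) profile so threshold crossings are well defined
#' at sub-pixel scale.
#'
#' @param w_inf Asymptotic gap width (um).
#' @param tau_r Recoil time constant (s).
#' @param n_frames Total frames including `n_pre` pre-cut frames.
#' @param dt Frame interval (s).
#' @param pixel_size Micrometres per pixel.
#' @param shape `c(rows, cols)`.
#' @param n_pre Pre-cut frames (>= 1).
#' @param strip_um Strip height (um).
#' @param noise Noise model.
#' @param seed Integer seed or NULL.
#' @return List with `stack`, `ground_truth` (includes the per-frame true
#'   width curve and `v0 = w_inf / tau_r`), and `cut_frame`.
#' @export
make_ablation_stack <- function(w_inf, tau_r, n_frames = 20, dt = 0.5,
                                pixel_size = 0.1, shape = c(96, 96),
                                n_pre = 3, strip_um = 6,
                                noise = noise_model(), seed = NULL) {
  if (w_inf <= 0 || tau_r <= 0) {
    stop("w_inf and tau_r must be > 0", call. = FALSE)
  }
  if (w_inf / pixel_size >= shape[1]) {
    stop("gap wider than image", call. = FALSE)
  }
  with_seed_if(seed, {
    nr <- shape[1]; nc <- shape[2]
    cut_frame <- n_pre + 1L
    r0 <- (nr + 1) / 2
    strip_half <- strip_um / 2 / pixel_size
    rows <- seq_len(nr)
    edge_sigma <- 0.7  # px, rendering edge softness
    strip <- stats::pnorm((strip_half - abs(rows - r0)) / edge_sigma)
    frames <- vector("list", n_frames)
    times <- rep(NA_real_, n_frames)
    widths <- rep(0, n_frames)
    for (f in seq_len(n_frames)) {
      t_post <- (f - cut_frame) * dt
      w_px <- if (f >= cut_frame) {
        widths[f] <- w_inf * (1 - exp(-t_post / tau_r))
        widths[f] / pixel_size
      } else 0
      times[f] <- t_post
      open_frac <- if (w_px > 0) {
        stats::pnorm((w_px / 2 - abs(rows - r0)) / edge_sigma)
      } else rep(0, nr)
      # background-free rendering: with no additive offset the 50%%-of-
      # baseline criterion meets the rendered edge exactly at w/2; camera
      # offset and read noise enter through the noise model instead
      profile <- 200 * strip * (1 - open_frac)
      img <- matrix(profile, nr, nc)
      frames[[f]] <- apply_noise(img, noise)
    }
    stack <- calibrated_stack(frames, pixel_size, dt, "synthetic ablation")
    gt <- list(scenario = "ablation", w_inf = w_inf, tau_r = tau_r,
               v0 = w_inf / tau_r, cut_frame = cut_frame,
               widths = tibble::tibble(frame = seq_len(n_frames),
                                       time = times, width_um = widths),
               pixel_size = pixel_size, dt = dt)
    list(stack = stack, ground_truth = gt, cut_frame = cut_frame)
  })
}

#' Generate an endocytic-puncta image with known particle sizes
#'
#' Places non-overlapping uniform-intensity disks on a constant background:
#' `n_in_band` with areas strictly inside `area_band`, `n_oversize` above it
#' and `n_undersize` below it. Class margins are wide enough that
#' rasterization cannot move a particle across a band edge.
#'
#' @param n_in_band,n_oversize,n_undersize Disk counts per class.
#' @param area_band Closed area band in um^2 (default `c(0.2, 2)`).
#' @param pixel_size Micrometres per pixel.
#' @param shape `c(rows, cols)`.
#' @param intensity,background Disk and background intensities.
#' @param noise Noise model.
#' @param seed Integer seed or NULL.
#' @return List with `image` (matrix), `ground_truth` (per-disk tibble with
#'   centroid, true area, class) and `pixel_size`.
#' @export
make_puncta_image <- function(n_in_band, n_oversize = 0, n_undersize = 0,
                              area_band = c(0.2, 2), pixel_size = 0.1,
                              shape = c(256, 256), intensity = 100,
                              background = 5, noise = noise_model(),
                              seed = NULL) {
  if (area_band[1] <= 0) stop("area band lower bound must be > 0",
                              call. = FALSE)
  with_seed_if(seed, {
    lo <- area_band[1]; hi <- area_band[2]; span <- hi - lo
    areas <- c(
      if (n_in_band > 0) stats::runif(n_in_band, lo + 0.15 * span,
                                      hi - 0.15 * span),
      if (n_oversize > 0) stats::runif(n_oversize, 1.5 * hi, 3 * hi),
      if (n_undersize > 0) stats::runif(n_undersize, 0.25 * lo, 0.6 * lo)
    )
    cls <- rep(c("in_band", "oversize", "undersize"),
               c(n_in_band, n_oversize, n_undersize))
    n <- length(areas)
    nr <- shape[1]; nc <- shape[2]
    img <- matrix(background, nr, nc)
    if (n > 0) {
      radii <- sqrt(areas / pi) / pixel_size
      cx <- cy <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (attempt in seq_len(1e4)) {
          x <- stats::runif(1, radii[i] + 2, nc - radii[i] - 1)
          y <- stats::runif(1, radii[i] + 2, nr - radii[i] - 1)
          if (i == 1L || all(sqrt((x - cx[seq_len(i - 1)])^2 +
                                  (y - cy[seq_len(i - 1)])^2) >
                             radii[i] + radii[seq_len(i - 1)] + 2,
                             na.rm = TRUE)) {
            cx[i] <- x; cy[i] <- y; placed <- TRUE; break
          }
        }
        if (!placed) {
          stop("cannot place requested disks without overlap ",
               "(10^4 attempts)", call. = FALSE)
        }
      }
      for (i in seq_len(n)) {
        x0 <- max(1L, floor(cx[i] - radii[i] - 1))
        x1 <- min(nc, ceiling(cx[i] + radii[i] + 1))
        y0 <- max(1L, floor(cy[i] - radii[i] - 1))
        y1 <- min(nr, ceiling(cy[i] + radii[i] + 1))
        d2 <- outer((y0:y1 - cy[i])^2, (x0:x1 - cx[i])^2, `+`)
        patch <- img[y0:y1, x0:x1]
        patch[d2 <= radii[i]^2] <- intensity
        img[y0:y1, x0:x1] <- patch
      }
      disks <- tibble::tibble(x = cx, y = cy, area_um2 = areas,
                              radius_px = radii, class = cls)
    } else {
      disks <- tibble::tibble(x = numeric(), y = numeric(),
                              area_um2 = numeric(), radius_px = numeric(),
                              class = character())
    }
    img <- apply_noise(img, noise)
    gt <- list(scenario = "puncta", disks = disks,
               n_in_band = sum(cls == "in_band"),
               area_band = area_band, pixel_size = pixel_size)
    list(image = img, ground_truth = gt, pixel_size = pixel_size)
  })
}

#' Generate a comet movie with known per-comet speeds
#'
#' Gaussian spots translating at constant velocity, emulating EB3-GFP
#' plus-end comets. Start positions are drawn so every trajectory stays in
#' frame for the whole movie.
#'
#' @param n_comets Number of comets.
#' @param speeds Per-comet speeds (um/s); recycled to `n_comets`.
#' @param directions Per-comet directions (radians, image convention: 0 =
#'   +x/right, pi/2 = +y/down); recycled.
#' @param n_frames Number of frames.
#' @param dt Frame interval (s).
#' @param pixel_size Micrometres per pixel.
#' @param shape `c(rows, cols)`.
#' @param comet_sigma Spot SD (um).
#' @param intensity,background Spot amplitude and background level.
#' @param noise Noise model.
#' @param min_start_separation_px Minimum distance between start positions.
#' @param seed Integer seed or NULL.
#' @return List with `stack` and `ground_truth` (per-comet tibble).
#' @export
make_comet_stack <- function(n_comets, speeds, directions = NULL,
                             n_frames = 20, dt = 0.5, pixel_size = 0.2,
                             shape = c(128, 128), comet_sigma = 0.3,
                             intensity = 100, background = 5,
                             noise = noise_model(),
                             min_start_separation_px = 15, seed = NULL) {
  with_seed_if(seed, {
    speeds <- rep_len(speeds, n_comets)
    if (is.null(directions)) {
      directions <- stats::runif(n_comets, 0, 2 * pi)
    } else {
      directions <- rep_len(directions, n_comets)
    }
    nr <- shape[1]; nc <- shape[2]
    sp_px <- speeds * dt / pixel_size  # px per frame
    ddx <- sp_px * cos(directions)
    ddy <- sp_px * sin(directions)
    sigma_px <- comet_sigma / pixel_size
    margin <- 4 * sigma_px + 2
    x0 <- y0 <- rep(NA_real_, n_comets)
    for (i in seq_len(n_comets)) {
      span_x <- ddx[i] * (n_frames - 1)
      span_y <- ddy[i] * (n_frames - 1)
      lo_x <- margin + max(0, -span_x); hi_x <- nc - margin - max(0, span_x)
      lo_y <- margin + max(0, -span_y); hi_y <- nr - margin - max(0, span_y)
      if (lo_x >= hi_x || lo_y >= hi_y) {
        stop("trajectory does not fit in frame", call. = FALSE)
      }
      for (attempt in seq_len(1e4)) {
        x <- stats::runif(1, lo_x, hi_x)
        y <- stats::runif(1, lo_y, hi_y)
        if (i == 1L ||
            all(sqrt((x - x0[seq_len(i - 1)])^2 +
                     (y - y0[seq_len(i - 1)])^2) >
                min_start_separation_px, na.rm = TRUE)) {
          x0[i] <- x; y0[i] <- y; break
        }
      }
      if (is.na(x0[i])) {
        stop("cannot place comet start positions at the requested separation",
             call. = FALSE)
      }
    }
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      img <- matrix(background, nr, nc)
      for (i in seq_len(n_comets)) {
        img <- add_gaussian_spot(img, x0[i] + ddx[i] * (f - 1),
                                 y0[i] + ddy[i] * (f - 1), sigma_px,
                                 intensity)
      }
      frames[[f]] <- apply_noise(img, noise)
    }
    stack <- calibrated_stack(frames, pixel_size, dt, "synthetic comets")
    comets <- tibble::tibble(
      comet = seq_len(n_comets), speed_um_s = speeds,
      direction = directions, x0 = x0, y0 = y0,
      dx_px_frame = ddx, dy_px_frame = ddy
    )
    # can the simple nearest-neighbour linker resolve this instance
    # unambiguously? true when comets never approach within the step scale
    min_sep <- Inf
    if (n_comets > 1) {
      for (f in seq_len(n_frames)) {
        xs <- x0 + ddx * (f - 1); ys <- y0 + ddy * (f - 1)
        min_sep <- min(min_sep, min(stats::dist(cbind(xs, ys))))
      }
    }
    gt <- list(scenario = "comets", comets = comets,
               min_mutual_separation_px = min_sep,
               unambiguous = n_comets < 2 ||
                 min_sep > 2 * max(sp_px) + 1,
               pixel_size = pixel_size, dt = dt)
    list(stack = stack, ground_truth = gt)
  })
}

# Ramanujan's ellipse perimeter approximation
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Generate an elliptical embryo silhouette with landmarks
#'
#' Filled ellipse mask with semi-axis `a` along the animal-vegetal (row)
#' axis and `b` transverse, plus animal-pole, vegetal-pole and margin
#' landmarks at the stated epiboly progression fraction. Ground-truth
#' circularity uses the Ramanujan perimeter approximation.
#'
#' @param a,b Semi-axes (um); `a` along the animal-vegetal axis.
#' @param margin_fraction Epiboly progression fraction in `[0, 1]`.
#' @param pixel_size Micrometres per pixel.
#' @param shape `c(rows, cols)`.
#' @return List with `mask` (0/1 matrix), `landmarks` (named list of
#'   `c(x, y)` pixel coordinates) and `ground_truth`.
#' @export
make_embryo_mask <- function(a, b, margin_fraction = 0.5, pixel_size = 1,
                             shape = c(256, 256)) {
  if (margin_fraction < 0 || margin_fraction > 1) {
    stop("margin_fraction must be in [0, 1]", call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  a_px <- a / pixel_size; b_px <- b / pixel_size
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  if (a_px >= nr / 2 || b_px >= nc / 2) {
    stop("ellipse does not fit in frame", call. = FALSE)
  }
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- 1 * (((rows - cy) / a_px)^2 + ((cols - cx) / b_px)^2 <= 1)
  landmarks <- list(
    animal = c(x = cx, y = cy - a_px),
    vegetal = c(x = cx, y = cy + a_px),
    margin = c(x = cx, y = cy - a_px + margin_fraction * 2 * a_px)
  )
  P <- ramanujan_perimeter(a, b)
  gt <- list(scenario = "embryo",
             circularity = 4 * pi * (pi * a * b) / P^2,
             margin_fraction = margin_fraction,
             a = a, b = b, pixel_size = pixel_size)
  list(mask = mask, landmarks = landmarks, ground_truth = gt)
}

#' Write / read a ground-truth sidecar
#'
#' Every generated artifact carries its ground truth; these helpers
#' serialize it as JSON next to the written stack so a stack is never
#' separated from its sidecar.
#'
#' @param ground_truth Ground-truth list from a generator.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_ground_truth` returns the list.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
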