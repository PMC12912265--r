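#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# run code under a fixed seed when one is given, without disturbing the
# caller's RNG state
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Apply a fluorescence-camera noise model to an image
#'
#' Poisson shot noise on the noiseless image scaled to a stated photon
#' budget at the image peak, followed by additive Gaussian read noise.
#' Both components are optional. Output is clamped at zero.
#'
#' @param img Nonnegative numeric matrix (noiseless image).
#' @param noise List with elements `poisson` (logical), `photon_budget`
#'   (photons at the image peak; `NULL` means use intensities as photon
#'   counts directly), `gaussian_sd` (read-noise SD, same units as output).
#' @return Noisy matrix in photon units.
#' @export
apply_noise <- function(img, noise = noise_model()) {
  out <- img
  if (isTRUE(noise$poisson)) {
    peak <- max(out)
    if (peak > 0) {
      # scale to the photon budget and keep the output in photon units so
      # the Gaussian read-noise SD is in photons too
      scale <- if (!is.null(noise$photon_budget)) noise$photon_budget / peak else 1
      out <- matrix(stats::rpois(length(out), out * scale), nrow(out), ncol(out))
    }
  }
  sd <- noise$gaussian_sd %||% 0
  if (sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), sd = sd), nrow(out), ncol(out))
  }
  pmax(out, 0)
}

#' @rdname apply_noise
#' @param poisson Enable Poisson shot noise.
#' @param photon_budget Photons at the image peak (NULL = intensities are
#'   already photon counts).
#' @param gaussian_sd Additive Gaussian read-noise SD.
#' @export
noise_model <- function(poisson = FALSE, photon_budget = NULL,
                        gaussian_sd = 0) {
  list(poisson = poisson, photon_budget = photon_budget,
       gaussian_sd = gaussian_sd)
}

# separable Gaussian blur with edge replication; used for sub-pixel
# contouring, not for quantitative intensity measurements
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(n, r), , drop = FALSE])
    out <- apply(padded, 2, function(col) {
      stats::filter(col, k, sides = 2)
    })
    out[(r + 1):(r + n), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(img))))
}

# render a 2-D Gaussian spot of amplitude `amp` and SD `sigma` (px) at
# subpixel center (cx, cy) into `img` (in place semantics via return value)
add_gaussian_spot <- function(img, cx, cy, sigma, amp) {
  r <- ceiling(4 * sigma)
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol(img), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow(img), ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma^2))
  gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma^2))
  img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] + amp * outer(gy, gx)
  img
}
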