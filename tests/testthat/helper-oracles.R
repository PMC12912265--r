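# Independent oracles used across test files. These deliberately use naive
# direct computation, not the package's implementation paths.

# direct-sum mean-subtracted normalized cross-correlation between window `a`
# (w x w) and search region `b` ((w+2m) x (w+2m)); returns the full
# (2m+1) x (2m+1) correlation map, displacement (k, l) at map[k+m+1, l+m+1]
direct_correlation_map <- function(a, b, m) {
  w <- nrow(a)
  a <- a - mean(a)
  sa <- sqrt(sum(a^2))
  cmap <- matrix(NA_real_, 2 * m + 1, 2 * m + 1)
  for (k in -m:m) for (l in -m:m) {
    bs <- b[(1 + k + m):(w + k + m), (1 + l + m):(w + l + m)]
    bs <- bs - mean(bs)
    cmap[k + m + 1, l + m + 1] <- sum(a * bs) / (sa * sqrt(sum(bs^2)))
  }
  cmap
}

# circularly shift a matrix by (dr, dc): out[i, j] = img[i - dr, j - dc]
circshift <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1 - dr) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  img[ri, ci]
}

# exhaustive optimal frame-to-frame assignment (minimum total distance over
# all injective assignments, links capped at max_disp); for <= 4 points
brute_force_assignment <- function(prev, cur, max_disp) {
  np <- nrow(prev); nc_ <- nrow(cur)
  if (np == 0 || nc_ == 0) return(integer(0))
  k <- min(np, nc_)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  idx_prev <- seq_len(np)
  # enumerate which prev points link (subsets) and to which cur points
  # (permutations); maximize links, then minimize total distance
  subsets <- function(v, k) if (k == 0) list(integer(0)) else utils::combn(v, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  for (nlink in k:0) {
    for (sp in subsets(idx_prev, nlink)) {
      for (sc in subsets(seq_len(nc_), nlink)) {
        for (pc in perms(sc)) {
          d <- sqrt(rowSums((prev[sp, , drop = FALSE] -
                             cur[pc, , drop = FALSE])^2))
          if (all(d <= max_disp)) {
            cost <- sum(d)
            if (nlink > best_n || (nlink == best_n && cost < best_cost)) {
              best_n <- nlink; best_cost <- cost
              best <- rep(NA_integer_, np)
              best[sp] <- pc
            }
          }
        }
      }
    }
    if (!is.null(best)) break
  }
  best
}

# build a constant-velocity detection table
make_linear_detections <- function(starts, velocities, n_frames) {
  purrr::map_dfr(seq_len(nrow(starts)), function(i) {
    tibble::tibble(
      frame = seq_len(n_frames),
      x = starts[i, 1] + velocities[i, 1] * (seq_len(n_frames) - 1),
      y = starts[i, 2] + velocities[i, 2] * (seq_len(n_frames) - 1),
      truth = i
    )
  })
}
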