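---
title: "Quantifying yolk-cell cortical dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying yolk-cell cortical dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(yolkflow)
library(dplyr)
```

During zebrafish epiboly the blastoderm spreads over the yolk cell, pulled
in part by an actomyosin band that assembles in the external yolk syncytial
layer (e-YSL). yolkflow quantifies the cortical processes that build and
exercise that band from calibrated time-lapse microscopy: actin flow
(particle image velocimetry), actin turnover (FRAP), cortical tension
(laser-ablation recoil), myosin accumulation (intensity slopes),
macropinocytosis (size-filtered puncta counts), microtubule plus-end
dynamics (comet speeds), and whole-embryo morphometry. Because raw imaging
data for such experiments are rarely shareable at full size, the package
pairs every measurement stage with a synthetic generator that produces
calibrated stacks with exported ground truth, so the whole pipeline is
validated end to end by simulation.

All images travel as a `calibrated_stack`: a `time x rows x cols` array
with `pixel_size` (um/px) and `frame_interval` (s/frame). Images are
row-major with the origin at the top-left; analysis movies are assumed
oriented with the EVL-YSL margin at the top, so "animal/up" means
decreasing row index. TIFF metadata is never trusted for calibration —
explicit arguments always win, with a warning on disagreement — because
microscopy TIFF dialects are inconsistent. All arithmetic happens in
floating point with no bit-depth rescaling, preserving intensity
comparability across embryos imaged with identical settings, and every
physical-unit conversion goes through the stack accessors
(`px_to_um()`, `px_per_frame_to_um_min()`, ...), so units are converted in
exactly one place.

## Flow estimation by windowed cross-correlation

The flow estimator compares each interrogation window in frame *t* with
the corresponding search region in frame *t + 1*. The window edge is
specified physically (default 14.8 um, the region-of-interest scale at
which punctate cortical actin decorrelates slowly) and converted to an
even pixel count per run; windows overlap by 50% and are inset by the
search margin (8 px) so every search region stays inside the frame. For
each window the package computes the true normalized cross-correlation:
the window is mean-subtracted, and for every candidate offset the
window-sized sub-region of the search area is mean-subtracted and
variance-normalized individually (integral images make this cheap), which
keeps the peak location unbiased when the local background varies. The
displacement is the correlation argmax, refined per axis by three-point
Gaussian interpolation — exact for Gaussian-shaped peaks, which is what
Gaussian puncta produce — with a parabolic fallback when a neighbouring
sample is non-positive.

Vector quality is the ratio of the primary correlation peak to the
secondary peak found outside a 3x3 exclusion zone. A vector is kept when
this signal-to-noise ratio exceeds 1 and its speed does not exceed
1 um/min, the upper bound of plausible cortical actin flow; both
thresholds are parameters of `piv_params()`. (A correlation *coefficient*
cannot exceed 1, so a "threshold of 1" is only meaningful for the
peak-ratio statistic — that is the reading implemented here, and it is the
standard spurious-vector criterion in open PIV codes.) Filtering only
flips validity flags; raw vectors are retained for audit, and invalid
vectors are excluded from every summary.

Directions use the image convention `theta = atan2(-dy, dx)`, so upward
(animal) flow sits at 90 degrees. Quadrants are half-open 90-degree
sectors centered on the axes — right `[-45, 45)`, up `[45, 135)`, left
`[135, 225)`, down `[225, 315)` — giving deterministic assignment of
boundary angles to the counterclockwise sector. Vectors are pooled across
all frame pairs of a movie before the rose/quadrant summary, matching
per-embryo reporting; per-embryo summaries then feed the group tests.
Quadrant distributions are compared with a Pearson goodness-of-fit
statistic against explicit reference proportions with an upper-tail
p-value; the reference is never guessed (uniform must be requested
explicitly).

```{r piv-example}
sc <- flow_scenario("uniform", vx = 0, vy = -0.5, n_frames = 8,
                    noise = noise_model(poisson = TRUE, photon_budget = 200,
                                        gaussian_sd = 2),
                    seed = 7)
flow <- make_flow_stack(sc, pixel_size = 0.25, frame_interval = 6,
                        shape = c(192, 192))
field <- compute_piv(flow$stack) |> filter_vectors()
directional_summary(field)
```

A note on temporal sampling: at a 0.5 s frame interval — the acquisition
rate such movies are often recorded at — a flow of 0.5 um/min displaces
the texture by ~0.017 px between frames, far below what windowed
correlation can resolve per frame pair. Quantitative flow recovery
therefore needs either frame skipping or a longer sampling interval; the
package's validation simulations use a 6 s interval (0.08-0.32 px per
pair across 0.2-0.8 um/min), which window correlation resolves cleanly.
The generator's default interval remains 0.5 s to mirror typical
acquisition.

## FRAP kinetics

Recovery traces are normalized full-scale:
`N(t) = (F(t) - F_bleach) / (F_pre - F_bleach)` with `F_pre` the prebleach
mean and `F_bleach` the first postbleach value, so `N` runs from 0 at the
bleach to 1 at complete recovery. This bleach-depth normalization is the
fewest-assumptions choice when only the bleached region is recorded, and
it absorbs incomplete bleaching — the common case for bright cortical
actin labeling — into the denominator. It is exactly invariant to affine
rescaling of the raw trace.

Recovery is fit as a single exponential `N(t) = m (1 - exp(-t / tau))` by
Levenberg-Marquardt least squares (parameter tolerance 1e-8), initialized
with `m0` = last observed value and `tau0` = time to half of the final
level. The half-time is `tau * ln 2` and the mobile fraction is the
plateau `m`. A single-exponential model is the standard summary for
cortical actin turnover when only a half-time is reported;
reaction-diffusion models (e.g. pure-diffusion recovery) are deliberately
out of scope. Flat traces and nonpositive time constants are rejected
with errors that carry the initialization, rather than returning
meaningless parameters.

```{r frap-example}
tr <- make_frap_trace(tau = 10, noise_sigma = 0.02, seed = 11)
fit <- fit_recovery(normalize_frap(tr$trace$intensity, bleach_index = 11,
                                   frame_interval = 0.5))
glance(fit)
```

## Ablation recoil

Cortical tension is proxied by how fast a laser cut opens. The gap-width
series is measured from the intensity profile along the animal-vegetal
axis, averaged across the strip ROI: the gap is the longest contiguous
run below 50% of the median pre-cut level (the conventional midpoint
criterion for edge width; the fraction is configurable), with run edges
interpolated linearly between samples for sub-pixel precision. The
initial recoil velocity is the ordinary least-squares slope of width
versus time over the first `fit_frames` post-cut points (default 5) — the
noise-robust generalization of a two-point difference quotient, to which
it reduces at `fit_frames = 2`.

Because the true width curve saturates (`w(t) = w_inf (1 - e^{-t/tau_r})`
in the generator), any finite fit window underestimates the initial
velocity `w_inf / tau_r`, monotonically more so as the window grows: over
a window of `0.2 tau_r` the OLS slope of the exact curve is already ~9%
low. Validation therefore uses short early windows and treats ~10%
agreement as the attainable accuracy at that window; only the horizontal
cut geometry (opening along the animal-vegetal axis) is modeled. The
synthetic ablation movie is rendered background-free with smooth
(Gaussian CDF) gap edges: the 50%-of-baseline criterion then meets the
rendered edge exactly at the true half-width, and camera offset and read
noise enter through the noise model instead of the geometry.

## Intensity accumulation

`intensity_series()` reports the mean ROI intensity per frame under three
normalizations: none; first-frame (each value divided by the frame-1
value — accumulation relative to the start of the recording); and
reference-ROI (each frame's measurement ROI mean divided by the same
frame's reference-ROI mean, e.g. an embryo's blastoderm — which also
cancels global per-frame intensity changes such as photobleaching).
`accumulation_slope()` fits an OLS slope of first-frame-normalized
intensity against time in minutes, the natural scale for accumulation
over tens of minutes; recoil velocities are reported in um/s, the natural
scale for seconds-long recoil.

## Puncta counting and comet tracking

Endocytosed vesicle counting follows the threshold-and-size-filter
recipe: binarize (fixed threshold, or Otsu's method as the reproducible
automatic default — the threshold actually used is always recorded),
label 8-connected components, convert pixel counts to areas, and count
components whose area lies in the closed band 0.2-2 um^2. The band is
interpreted as area because that is the size semantics of the standard
particle-analysis tool; both band edges and the per-slice versus
projected mode are parameters (projection is the default so a vesicle
spanning slices is counted once). All components are recorded with an
in-band flag, so the filtering is auditable. Connected-component labeling
is 8-connected by construction (the 4-connected labeling is merged across
diagonal adjacencies), matching the reference tool's convention.

Comet speeds use a deliberately simple detector-linker: local maxima
above a minimum intensity with non-maximum suppression, centroids refined
by background-subtracted center of mass in a 5x5 neighbourhood (the
patch-minimum subtraction keeps the uniform background and its shot noise
from biasing the centroid), then greedy nearest-neighbour frame-to-frame
linking with a maximum displacement and minimum track length. On
well-separated comets the greedy linker provably coincides with the
exhaustive optimal assignment (the test suite checks this against a
brute-force oracle on small instances); full linear-assignment tracking
with gap closing and merge/split events is out of scope. Per-track speed
is summed step length divided by track duration, and the movie mean is
the unweighted mean of per-track speeds.

## Morphometry

Circularity is `4 pi A / P^2` with the perimeter measured on a sub-pixel
contour: the mask is lightly Gaussian-smoothed (sigma 1.5 px) and the 0.5
iso-contour is extracted by marching squares; the area is the contour's
shoelace area. Naive pixel-edge perimeters overestimate `P` by several
percent and were rejected — a rasterized radius-100 circle measures
within 0.5% of 1.0 with the contour approach. Values are not capped at
1.0; slight overshoot flags a discretization artifact rather than being
silently clipped. Epiboly progression is the projection of the margin
landmark onto the animal-vegetal axis divided by the pole-to-pole length
— invariant under rigid transforms of the landmark triple. Landmarks are
supplied manually (or by the generator); automatic segmentation of
stained margins is out of scope. Per-trial normalization divides each
measurement by its own trial's wild-type mean, and is idempotent once the
reference set is itself normalized.

## The synthetic generators

Each generator emulates the geometry and photometry of one imaging
modality and exports exact ground truth alongside the pixels:

* **Flow stacks** seed Gaussian puncta (PSF sigma 0.3 um) at a stated
  density, advect them with uniform, vertical-gradient or
  mixture (up/down/left/right class) fields, wrap positions periodically
  so density is stationary, and render spots analytically at subpixel
  centers — integer-shift resampling would alias and flatter the flow
  estimator. Ground truth includes the field sampled on the PIV grid and
  every punctum's class.
* **FRAP traces** are the exponential model plus Gaussian noise, with
  incomplete bleaching by default.
* **Ablation stacks** render a bright cortical strip whose central gap
  follows the saturating width curve.
* **Puncta images** place non-overlapping uniform disks in three size
  classes with margins wide enough that rasterization cannot move a
  particle across a band edge.
* **Comet stacks** translate Gaussian spots at constant velocity, with a
  pairwise-separation flag marking instances a nearest-neighbour linker
  can resolve unambiguously.
* **Embryo masks** are filled ellipses with analytic (Ramanujan-
  perimeter) circularity and pole/margin landmarks.

Noise is a standard fluorescence-camera model: Poisson shot noise scaled
to a stated photon budget at the image peak, then additive Gaussian read
noise, both optional; intensities are then in photon units. Validation
simulations state their own noise levels (photon budgets of 100-300 at
the peak) rather than claiming to match any particular acquisition.
Every generator draws from a single seeded RNG, so a fixed seed fixes
every pixel.

What the simulations do *not* emulate: spatially varying background,
puncta appearance/disappearance and photobleaching, motion blur,
non-rigid deformation of the cortical texture, and optical sectioning.
Passing the synthetic validation therefore demonstrates the correctness
of the estimators under their stated assumptions, not robustness to every
pathology of real movies.

## Problem sizes, tolerances and degenerate inputs

The validation suite uses 160-512 px frames, 8-15 frame movies, ~100-550
vectors per pooled summary, 100 replicate FRAP fits, 20 seeded puncta
scenes and 2000-replicate null calibrations — sizes chosen so the full
suite runs in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances. Numerical choices worth knowing: the FRAP fit
bounds `tau > 0` and `m >= 0` and declares failure rather than returning
a flat-plateau fit; the subpixel refinement falls back from Gaussian to
parabolic interpolation when a correlation sample is non-positive, and to
the integer peak when the curvature vanishes; zero-variance interrogation
windows are flagged (signal-to-noise 0) instead of propagating NaNs;
gap-width measurement reports 0 when no profile sample falls below the
threshold; and exact Mann-Whitney enumeration switches to the
tie-corrected normal approximation with continuity correction beyond
`n_a + n_b = 12` or in the presence of ties, with degenerate all-tied
comparisons reporting p = 1.
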