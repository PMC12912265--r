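# yolkflow

Quantification of yolk-cell cortical dynamics during zebrafish epiboly
from calibrated time-lapse microscopy.

During epiboly, an actomyosin band in the external yolk syncytial layer
(e-YSL) helps pull the blastoderm over the yolk cell. Asking whether a
mutant perturbs that machine means measuring, per embryo: how cortical
actin *flows* (direction and speed), how fast it *turns over*, how much
*tension* the band carries, how quickly myosin *accumulates*, how actively
the cortex *internalizes membrane*, how microtubule plus-ends *move*, and
what shape the embryo takes. yolkflow implements that whole measurement
pipeline for R, tidyverse-style — data frames in, tibbles out — together
with a synthetic time-lapse generator with exported ground truth so every
stage is validated end to end without any external data.

The core estimators:

* **Flow (PIV).** For each interrogation window (default 14.8 × 14.8 μm)
  and consecutive frame pair, the displacement is the argmax of the
  normalized cross-correlation map over a ±8 px search, refined to
  sub-pixel by three-point Gaussian interpolation:
  `v = d · pixel_size / frame_interval · 60` (μm/min). Vectors are kept
  when the peak-to-second-peak signal-to-noise ratio exceeds 1 and speed
  ≤ 1 μm/min; pooled vectors feed rose plots, quadrant fractions
  (up = animal), and a one-tailed χ² goodness-of-fit on quadrant counts.
* **FRAP.** Bleach-depth normalization
  `N(t) = (F(t) − F_bleach)/(F_pre − F_bleach)`, then a single-exponential
  fit `N(t) = m(1 − e^{−t/τ})`; half-time `τ ln 2`, mobile fraction `m`.
* **Ablation recoil.** Gap width from sub-pixel threshold crossings of the
  post-cut intensity profile; initial recoil velocity = OLS slope of width
  vs time over an early window (μm/s) — the tension proxy.
* **Accumulation.** Mean ROI intensity, first-frame- or
  reference-ROI-normalized; OLS slope per minute.
* **Puncta.** Threshold → 8-connected components → calibrated areas →
  count within the closed 0.2–2 μm² band.
* **Comets.** Local-maxima detection with center-of-mass refinement,
  greedy nearest-neighbour linking, per-track speed = path length /
  duration (μm/s).
* **Morphometry.** Circularity `4πA/P²` on a marching-squares sub-pixel
  contour; epiboly progression = margin projection along the
  animal–vegetal axis; per-trial normalization to the wild-type mean.
* **Group statistics.** Welch's *t*, Mann–Whitney *U* (exact for small
  untied samples), χ² goodness-of-fit — the tests applied to per-embryo
  summaries, with tails always recorded.

## Worked example

Simulate an upward-flowing punctate actin movie (0.5 μm/min, Poisson shot
noise at 200 photons/peak), estimate the flow, and summarize directions:

```r
library(yolkflow)
library(dplyr)

sc <- flow_scenario("uniform", vx = 0, vy = -0.5, n_frames = 8,
                    noise = noise_model(poisson = TRUE, photon_budget = 200,
                                        gaussian_sd = 2),
                    seed = 7)
flow <- make_flow_stack(sc, pixel_size = 0.25, frame_interval = 6,
                        shape = c(192, 192))
field <- compute_piv(flow$stack) |> filter_vectors()
directional_summary(field)
#> <directional_summary> n_valid = 112, mean speed = 0.5036 um/min
#> # A tibble: 4 × 3
#>   direction count fraction
#>   <chr>     <int>    <dbl>
#> 1 right         0        0
#> 2 up          112        1
#> 3 left          0        0
#> 4 down          0        0
```

All 112 valid vectors point into the "up" (animal) quadrant and the pooled
mean speed, 0.504 μm/min, recovers the programmed 0.5 μm/min within 1%.
FRAP works the same way — simulate, normalize, fit:

```r
tr <- make_frap_trace(tau = 10, noise_sigma = 0.02, seed = 11)
fit <- fit_recovery(normalize_frap(tr$trace$intensity, bleach_index = 11,
                                   frame_interval = 0.5))
glance(fit)
#> # A tibble: 1 × 5
#>     tau half_time mobile_fraction residual_rms n_post
#>   <dbl>     <dbl>           <dbl>        <dbl>  <int>
#> 1  10.0      6.96           0.730       0.0260    120
```

The fitted τ ≈ 10.0 s matches the simulated time constant; the half-time
is τ ln 2 ≈ 6.96 s, and the mobile fraction 0.73 reflects the programmed
incomplete recovery. Every fitted object supports `tidy()`/`glance()`,
and `ggplot2::autoplot()` renders quiver plots, rose diagrams, recovery
curves and recoil kinetics. A thin command-line front end over the same
functions lives at `inst/cli/yolkflow.R` (subcommands `simulate`, `piv`,
`frap`, `ablation`, `accumulation`, `intensity`, `puncta`, `comets`,
`morphometry`, `stats`).

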