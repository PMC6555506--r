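---
title: "Concentric-sphere active contours for nucleus localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentric-sphere active contours for nucleus localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakuscules)
```

# The model

A *snakuscule* is the smallest useful region-based active contour: a pair of
concentric spheres (disks in 2D) described by just two points `p` and `q`
that lie on a common line along the x axis, so the whole contour is the
center `c = (p + q)/2` and radius `R = ||p - q||/2`. Its energy contrasts
the image intensity inside the inner sphere (radius `rho * R`) against the
intensity in the shell between `rho * R` and `R`:

$$E(\mathbf p, \mathbf q) \;=\; \frac{1}{\|\mathbf p-\mathbf q\|^{d}}
\sum_{\mathbf k \in K} S(\|\mathbf k - \mathbf c\|)\, I(\mathbf k),$$

where `K` is the set of voxels within `R + Delta_R / 2` of the center, `d`
the image dimensionality, and `S(r)` a differentiable radial weight that is
negative on the inner core and positive on the shell. Minimizing `E` drives
the contour to enclose a bright blob (a stained nucleus) with its inner
sphere while keeping the shell on dark background. The inner/outer ratio is
`rho = 2^(-1/3)` in 3D (`2^(-1/2)` in 2D) so the inner region and the shell
have equal measure: on a constant image the two terms cancel exactly and the
contour neither moves nor resizes.

## The weight profile

Only the shape of `S(r)` is constrained by the theory: four regions
(negative core, inner transition of width `Delta_r`, positive shell, outer
transition of width `Delta_R`), differentiability, fixed transition widths
as the footprint scales, and a vanishing moment integral
$\int_0^\infty S(r)\, r^{d-1} dr = 0$.

This package implements `S` as a difference of two smooth step-downs built
from the cubic smoothstep $s(t) = 3t^2 - 2t^3$:

$$S(r) = f_{R,\Delta R}(r) \; - \; c \cdot f_{\rho R,\Delta r}(r), \qquad
f_{a,w}(r) = 1 - s\!\left(\tfrac{r - (a - w/2)}{w}\right),$$

with the inner-core magnitude `c` (the core weight is `1 - c = -A`) solved
in closed form from the moment condition. Two details are deliberate:

* **Difference form instead of explicit four-branch piecewise.** With the
  default `Delta_R = 4` voxels the inner and outer ramps overlap whenever
  `R < (Delta_R + Delta_r) / (2 (1 - rho))`, about 17 voxels — i.e. for most
  nucleus-sized contours. The four-region form is undefined there; the
  difference form reproduces it exactly whenever the regions are ordered and
  degrades smoothly (a slightly lower shell plateau) when they are not,
  while the zero-moment identity stays exact.
* **Exact rebalancing, discrete and continuous.** The grid backend re-solves
  `c` on the actual voxel lattice (`c = sum_k f_outer / sum_k f_inner` over
  the footprint), so a constant image gives *exactly* zero energy and
  gradient — not zero up to quadrature error. The Monte-Carlo backend uses
  the continuous closed-form `c(R)`; the two differ only by the lattice
  quadrature error of the profile itself (measured around 1e-5 relative).
  `dc/dR` is carried analytically through all gradients in both backends.

`Delta_r` is tied to the outer width by `Delta_r = Delta_R * 2^(-1/3)`
(`Delta_R / sqrt(2)` in 2D). `Delta_R = 4` voxels by default; the width is a
resolution in radius space — wider ramps give smoother energy landscapes,
narrower ramps approach the indicator-weight idealization.

## The binary-blob oracle and the normalization exponent

For the ideal blob $I(r) = 1 + \mathrm{sgn}(r_0 - r)$ — intensity 2 strictly
inside radius $r_0$ and 0 outside (note `sgn` of a negative argument is -1,
so the background is 0, not 1) — the unnormalized energy of a concentric
snake has a closed form with three branches; in 3D it is 0 for $R < r_0$,
$-(8/3)\pi(R^3 - r_0^3)$ while the blob boundary crosses the shell, and
$-(8/3)\pi r_0^3$ once the inner sphere contains the blob. Every contour at
least as large as optimal attains the same energy, so the energy is divided
by $R^\alpha$. The exponent is fixed by symmetry: the slope magnitudes of
$\bar E = \hat E / R^\alpha$ on the two sides of the optimum
$R^* = 2^{1/3} r_0$ must match, so that approaching contours expand as fast
as oversized ones contract. Solving the condition analytically gives
$\alpha = d$: 3 in 3D. The same derivation in 2D (branch energies 0,
$-2\pi(R^2 - r_0^2)$, $-2\pi r_0^2$; optimum $\sqrt 2 r_0$) gives
$\alpha = 2$, which is the package's 2D default — the original 2D
formulation does not state it, so the symmetry argument was re-run for this
case. `recover_normalization_exponent()` performs the numerical version of
this derivation and is used as an acceptance check.

```{r alpha}
recover_normalization_exponent(r0 = 1, dim = 3)
recover_normalization_exponent(r0 = 1, dim = 2)
```

## Gradients

All four independent partials (`d/dpx`, `d/dqx`, and the shared cross-axis
components `d/dpy = d/dqy`, `d/dpz = d/dqz`) are computed analytically by the
chain rule through `r`, `R`, the normalization `gamma = (2R)^(-d)`
(contributing the `±d/(q_x - p_x)` terms), and the rebalanced core magnitude
(`dc/dR`, including its lattice dependence in the grid backend). The suite
verifies agreement with central finite differences at relative tolerance
1e-3 over random smooth fields; this is what makes the `p`/`q`
parameterization descend reliably.

# Integration backends

*Grid*: exhaustive summation over voxel centers in the footprint, no
interpolation. *Monte-Carlo*: a fixed budget of `n_samples` (default
10,000) points drawn uniformly by measure in the footprint ball, intensity
tri-linearly interpolated, estimate `(ball volume / n) * sum S(r_i) I(x_i)`
with the same `(2R)^(-d)` normalization. Energy and gradient at one
iteration share one sample set (common random numbers), mirroring a fixed
per-contour budget that keeps data-parallel execution free of branch
divergence.

The radius transform is the measure-correct `radius * u^(1/d)`. A published
2D variant draws `radius * u`, which concentrates samples near the center
and biases the estimate; it is available behind
`sampling_config(radial_bias_compat = TRUE)` for comparison, and the
unbiasedness tests document why it is not the default.

Sampling uses a dedicated splitmix64 stream — independent of R's RNG — keyed
by `(seed, snake, iteration)`. The per-snake key is a hash of the snake's
*initial state* (the IEEE bit patterns of center and radius) rather than its
position in the population list: this keeps results bit-identical whether a
snake is evolved alone, in a population, in a permuted population, or on
either backend.

**A quadrature caveat that matters for testing.** The MC estimator converges
to the integral of the *tri-linear interpolant*, while the grid backend is a
*midpoint sum*. These are two different quadratures of the same continuous
integral; their difference is $\mathcal O(\nabla^2 I)$ against the weight
profile and is, for example, about 0.012 (5% of the optimal energy) on a
hard-edged blob — it decays as $1/\sigma^2$ with edge smoothness. On
integrands smoothed with $\sigma \gtrsim 4$ voxels the difference is far
below the MC noise at $n = 10^5$, so the $1/\sqrt N$ convergence checks
against the grid oracle are run on a $\sigma = 4$ smoothed blob (the
estimator's own spread obeys $1/\sqrt N$ regardless, which is tested
separately on the sharp blob). Pre-smoothing (`presmooth_sigma`) exists for
the same reason: MC assumes a well-behaved integrand, and a low-pass filter
enforces this on real, noisy stacks.

# Contour evolution

Gradient descent with a decaying learning rate: at iteration `n`,
`p <- p - (eps0/n) dE/dp` and likewise for `q`; the shared cross-axis
coordinates of `p` and `q` receive identical updates, so collinearity is
maintained exactly (analytically the two cross-axis partials coincide; with
shared MC samples they coincide in the estimator too, so no averaging
question arises). A snake stops when the largest component update drops
below `step_tol` (default 0.001 voxels, "much less than one pixel"), when it
exhausts `max_iters` (default 400), or when it degenerates — radius below
`R_min = max(2 * Delta_R, 3)` voxels or center leaving the volume — which
marks it `culled-domain`.

`eps0` is nowhere given by the theory, and the `1/n` decay makes it decisive:
the total travel budget of a contour is roughly its first step times
$\sum_{n\le 400} 1/n \approx 6.6$. Two design choices follow:

* **Per-snake auto-scaling.** By default `eps0` is set per snake so its own
  first (grid-backend) step is `first_step_voxels = 2`. A shared global rate
  was tried first and strands contours that start on weak-gradient plateaus
  — an oversized contour already enclosing a blob sees gradients ten times
  smaller than a half-overlapping one, and with a shared rate it exhausts
  400 iterations before finishing its descent (measured: 17 of 100 basin
  initializations). Per-snake scaling is still a deterministic function of
  the snake's own initial state, preserving order independence.
* **Step clamp.** Updates are clamped to `max_step_voxels = 2` per component
  per iteration, so a rate calibrated on a shallow plateau cannot produce a
  runaway move when the contour later reaches a steep region. Snakes on
  genuinely flat regions (|gradient| < 1e-8, e.g. constant images) fall back
  to a small fixed rate and converge immediately instead of amplifying
  numerical noise.

With these defaults the descent is monotone (no energy increase beyond 1e-6
per step) on noiseless phantoms under the grid backend, and 2-voxel first
steps give a worst-case travel budget comfortably above the farthest
blob-to-lattice distance at the default pitch.

# Detection pipeline

1. **Normalize** intensities to [0, 1] by min-max (degenerate-range images
   map to zero). All defaults below are stated on this scale.
2. **Pre-smooth** with `presmooth_sigma` if requested (used for noisy data).
3. **Initialize** a cubic lattice of snakes of radius `R0`
   (`initial_radius`, default 15 voxels ≈ 6 µm at typical confocal
   resolution) at pitch `1.5 * R0`, centered in the volume.
4. **Evolve** all snakes independently (Monte-Carlo backend by default).
5. **Re-evaluate** every surviving snake's energy with the grid backend at
   its converged configuration, so the accept/reject decisions below are
   free of MC noise.
6. **Cull by energy**: snakes with `E > E0` are removed
   (`energy_threshold`).
7. **Overlap competition**: snakes whose centers are closer than
   `max(R', R'') / 2^(1/3)` (the larger contour's inner radius) compete and
   the lower energy survives. Implemented as a greedy sweep in ascending
   energy order (ties: lower lattice index), removing any snake that
   overlaps an already-accepted survivor — this applies the pairwise rule
   transitively, is deterministic, and is independent of input order. It
   runs once, after convergence; the underlying formulation does not say
   whether competition ran during evolution, and post-hoc competition keeps
   the evolution fully data-parallel.

## The energy threshold

The reference operating point `E0 = -3` was stated for raw 8-bit
intensities; energies are linear in intensity, so on this package's [0, 1]
scale it corresponds to about -0.012, i.e. ~5% of the energy `-0.262`
reached by a perfectly fitted unit-contrast blob. That proved too lenient
under heavy noise: at 0.2 dB SNR (noise power equal to signal power, within
5%), contours that converge onto *smoothed noise* reach optimized energies
of -0.012 to -0.034 — each contour minimizes over its basin, so its final
energy is an extreme statistic, not a typical noise level — and a sparse
128³ volume then yields hundreds of false positives (measured F = 0.12).
The default is therefore `energy_threshold = -0.04`, 15% of the
unit-contrast optimum: true nuclei stay below it even under the worst-case
contrast compression that unclamped noise inflicts on min-max normalization
(measured blob energies ≤ -0.0455 at 0.2 dB), while optimized noise stays
above it (≥ -0.0342). Both the threshold and the normalization are exposed
(`--energy-threshold`, `normalize`), so the raw-intensity convention
remains available.

# Synthetic phantoms

`generate_phantom()` emulates the kind of data the detector targets —
bright, roughly spherical nuclei on dark background — with known ground
truth: `n_spheres` (default 20) spheres with radii uniform in
`radius_range` (default 8–12 voxels), centers rejection-sampled with a
minimum separation of `2.2 * max(radius)` and an in-volume margin, hard
voxelization followed by Gaussian edge smoothing (`smooth_sigma = 1`, which
both mimics optical blur and provides the smooth integrand MC assumes).
Noise is added separately: `add_gaussian_noise()` draws zero-mean Gaussian
noise with variance $P_{signal} / 10^{SNR_{dB}/10}$, where $P_{signal}$ is
the mean squared intensity of the clean image *including background* — the
SNR formula is stated here prominently because the noise experiment depends
on it and the source text never defines it. The output is unclamped by
default so the realized SNR is exact.

What a green phantom test does **not** establish: real nuclei are
asymmetric, unevenly stained, and densely packed; anisotropy, attenuation
with depth, and a microscope PSF are absent; the original noise-robustness
phantom was derived from manually segmented tissue, not spheres. Scores on
these phantoms are an upper bound on real-data performance, and the
published absolute scores on DAPI/embryo datasets cannot be reproduced
without those images.

# Evaluation

Detections are matched to ground-truth centers one-to-one, greedily in
ascending distance within a cutoff `max_dist` (default: the mean true
radius). Greedy matching is deterministic and, whenever true centers are
separated by more than `2 * max_dist` — guaranteed by the phantom packing
and by the overlap competition — provably optimal; on arbitrary cluttered
geometries it can undercount relative to optimal assignment, which the
property tests document. From TP/FP/FN counts:
precision `Pr = TP/(TP+FP)`, recall `Re = TP/(TP+FN)`,
`F = 2 Pr Re / (Pr + Re)`, Jaccard `J = Pr Re / (Pr + Re - Pr Re)`
(equal to `TP/(TP+FP+FN)`). Ratios with zero denominators are reported as
flagged `NA`, never as 0.

# Input/output and anisotropy

Confocal stacks are anisotropic (axial step coarser than lateral pixels);
since the contour model is spherical, volumes are made isotropic first:
`resample_isotropic()` linearly interpolates along the axial axis to the
lateral spacing (new axial size `round(nz * spacing_z / spacing_xy)`),
leaving lateral axes untouched. All radii and coordinates are in voxels
after resampling; the CLI also reports detections in original axial
coordinates. TIFF reading/writing is implemented in-package (uncompressed
grayscale, 8/16-bit unsigned or 32-bit float, multi-page, both byte orders
on read) because no TIFF codec exists in the supported dependency set; RGB
and compressed files are rejected with instructions rather than guessed at.

# Numerical choices and degenerate inputs

* Coordinates are 0-based voxels, centers at integers, x fastest-varying;
  out-of-domain intensity is 0 (penalizes contours drifting off the image).
* A snake with `R <= Delta_R` is rejected as degenerate wherever it appears.
* Constant images: exactly zero energy/gradient (discrete rebalancing);
  evolution converges immediately via the flat-region fallback.
* `step_tol = Inf` converges after exactly one iteration (degenerate
  tolerance contract).
* Equal-energy ties in competition are broken by lattice index; matching
  ties by truth then detection index — all deterministic.
* The closed-form/discrete comparison uses `Delta_R = 0.25` (the narrowest
  ramp the grid resolves): the closed form assumes indicator weights, and
  on a 96³ grid with `r0 = 10` the residual discretization disagreement is
  at most ~1.9%, dominated by boundary-voxel assignment at the inner-sphere
  edge.

# Known limitations

* Spherical contours only; elongated or lobed nuclei are localized but not
  delineated, and no segmentation mask is produced.
* Bright-on-dark polarity is assumed; invert the image upstream otherwise.
* The lattice spends most of its computation on contours that are later
  culled (the formulation's own stated limitation); no seeded or dynamic
  initialization is provided.
* Fixed energy threshold: images whose nuclei span very different
  contrasts need the threshold adapted (or the image normalized per region).
* The `1/n` decay makes total displacement finite; blobs farther than
  roughly `6.6 * max_step_voxels` from every lattice point can be missed —
  at default pitch this does not occur, but sparse custom lattices should
  keep the pitch below that bound.
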