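---
title: "Models and methods behind magnegel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magnegel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnegel)
```

This vignette documents the physical model, the estimators, the numerical
choices, and the limits of the synthetic-data world that the test suite
relies on. Nothing here states an empirical result that the tests or the
acceptance script do not themselves compute.

## 1. The two-magnet device

Each magnet is modeled as a uniformly magnetized cuboid. Outside the block,
the field of a uniform magnetization is identical to that of two uniformly
charged pole faces, and the resulting integrals have the classical closed
form as sums of `atan` and `log` corner terms; the implementation was
validated against an independent surface-charge quadrature oracle to 0.1%
(see `test-magnetics.R`). The device places two identical blocks
magnetized along the same +x direction, pole-to-pole across a 7.2 mm gap,
mirror-symmetric about the gap midplane.

Parameters, with defaults and why:

- **Magnet face 40 × 20 mm, depth 10 mm.** The device drawing fixes only
  two dimensions; the depth (along the magnetization axis) is a free
  parameter. Directionality predictions depend on field-line geometry, which
  is robust to depth, and the calibration step absorbs the magnitude
  uncertainty.
- **Remanence 1.31 T before calibration** — the nominal N42 grade value.
- **Calibration** (`calibrate_device()`) rescales the remanence so the
  midpoint flux density matches a target (default 51 mT, the center of the
  50–52 mT window measured for the physical device; 52.3 mT reproduces the
  field reported for the simulated sample area). The field is linear in
  remanence, so the match is exact and no field-line direction changes. The
  calibrated remanence (~0.12 T) is much lower than the physical N42 value:
  modeling the device faithfully enough to get 52 mT in a 7.2 mm gap from
  1.31 T blocks would require geometry details that are not available
  (magnet shape reading, sample offset from the gap center). We keep the
  printed gap and face dimensions and let calibration own the magnitude.
- **Gradient of |H|²** is computed by central differences of the scalar
  |H|² with step 1e-5 m — far below the millimeter scale over which the gap
  field varies, far above the 1e-8 relative float noise. The test suite
  cross-checks it against a structurally different oracle (2 JᵀH with a
  component-wise Jacobian at a different step) to 1e-3 relative.

**The quoted 25 T/m sample-area gradient is not reproduced** by this
geometry: with the midpoint calibrated to 52.3 mT the mean |∇|B|| over the
default 8 × 8 × 2 mm sample region is ~0.7 T/m
(`sample_region_gradient()`). A near-uniform field between two large
attracting pole faces cannot simultaneously sit at ~52 mT and have a 25 T/m
mean gradient across a central millimeter-scale region unless the sample is
strongly offset or the geometry differs from its printed description. The
value is therefore *reported, never asserted*, and no result downstream
depends on the gradient magnitude (only on its direction field).

## 2. Magnetophoretic particle tracing

The force on a magnetizable bead is the point-dipole gradient force with
the Clausius–Mossotti contrast factor,
`F = 2π r_p³ μ0 μ_f ((μ_p − μ_f)/(μ_p + 2 μ_f)) ∇|H|²`, with defaults
`r_p = 125 nm`, `χ_p = 6.27`, `ρ = 5240 kg/m³` and water as the fluid
(`η = 1.0e-3 Pa·s`, `χ_f = 0`). Bead inertia is neglected: the Stokes
relaxation time at this size is nanoseconds, so each bead moves at its
terminal drift velocity `v = F/(6π η r_p)` (overdamped regime). Tracing is
explicit Euler with the prescribed `dt = 0.01 s` to `t_end = 0.1 s`,
starting from a uniform draw in a 100 µl sphere at the center of an 8 mm
cubic well (the well side is not printed; the droplet, radius 2.88 mm, must
fit). Walls reflect; at the ~nm-scale net displacements produced by this
field they are never reached.

The motion angle of each bead is the angle of its net displacement,
measured *from the axis orthogonal to the applied field* and folded into
[0°, 180°): motion along the field axis reads 90°. The device midplane
mirror symmetry makes the angle distribution symmetric about 90°, so the
median converges to 90° regardless of the histogram's width.

Numerical/design notes:

- **Geometry makes the angle distribution broad.** In this gap the |H|²
  landscape is a shallow saddle: axial and transverse gradients are of
  comparable size, so individual beads move at many angles and the 90° peak
  is mild. The *median* is pinned by symmetry; acceptance runs therefore use
  1e5 beads (the requirement is "at least 1000"; the source does not print
  its own count) to keep the Monte-Carlo error of the median well inside
  the ±1° comparison band.
- **Viscosity and remanence invariance.** Scaling `η` (or the remanence,
  which scales |∇H²| by k²) only reparametrizes time along the same drift
  path, so motion angles are invariant in the continuous model. Explicit
  Euler breaks this exactness at the discretization level; the residue at
  these step sizes is far below 0.05°, which is the asserted bound.
- **Brownian motion is off by default** (the traced model is deterministic
  drift), but available (`brownian = TRUE`, 310 K, per-axis variance
  `2 D dt`). Physically, at these force levels diffusion would dominate a
  single 0.1 s trace (`sqrt(2 D t)` ≈ 0.6 µm vs ~10 nm of drift); the
  deterministic trace characterizes the *bias* direction field, which is
  what the alignment prediction needs.
- **Particle–particle dipolar interactions and chaining are not simulated.**
  String formation is emulated only by the image generator; the tracing
  addresses single-bead magnetophoresis.

## 3. Fourier-spectrum directionality

`fourier_directionality()` estimates the distribution of oriented structure
from the angular distribution of 2-D spectral power: subtract the mean,
apply a Hann window (suppresses the spectral cross of the image frame),
zero-pad to square, FFT, and integrate `|F|²` over angular sectors after
excluding radii below 3 frequency pixels (illumination gradients, window
residue) and above Nyquist. A structure oriented at θ concentrates spectral
energy at θ ± 90°, so sector angles are rotated back before binning into
ninety 2° bins over [0°, 180°), normalized to sum 1. The sign/offset
convention is fixed by gratings with known orientation and by a rotation
equivariance test on padded scenes (±1 bin).

`fit_gaussian()` fits `baseline + A exp(−(θ−c)²/(2σ²))` by bounded
L-BFGS-B least squares after circularly shifting the mode to mid-range
(orientation is 180°-periodic; the fitted center is mapped back).
Histograms with zero variance are flagged degenerate rather than fitted.
`classify_anisotropy()` implements the single-isolated-peak rule with
invented but configurable thresholds (the verbal criterion fixes none):
amplitude > 2× baseline, R² ≥ 0.5, and no secondary local maximum (on a
5-bin circular moving average) above half the main peak height over
baseline and more than 20° away.

A known property of power-spectrum directionality worth flagging: power is
quadratic in structure contrast and length, so one long, bright, coherent
fiber can dominate a single bin. Synthetic single scenes (~120 fibers) are
therefore spectrally spiky and a per-scene fitted σ is noisy — occasionally
collapsing toward the optimizer's lower width bound when one bin towers. The
workflow averages histograms across replicate gels before fitting
(`average_histograms()`), exactly as the experimental procedure prescribes,
which removes this in practice; recovery tests accordingly assert
unbiasedness of the fitted center over ≥10 seeds and monotonicity of the
mean fitted σ in the generator spread, not per-scene equality.

## 4. The segmentation (gap) metric

The transect is the single pixel row at `floor(height/2)` (0-based; a
single row, not a band — the band width used originally is unknown and one
row is the minimal faithful reading). The threshold is 25% of the maximum
over *non-excluded transect positions* (not the whole image; configurable),
comparisons are strict (`< T`; exactly-at-threshold pixels break runs),
qualifying runs are ≥ 15 µm of consecutive sub-threshold non-excluded
pixels, and edge-touching runs count (configurable). Exclusions break runs
and drop out of the maximum. Equivalence with a brute-force state-machine
oracle is tested exhaustively on all 3-level profiles of length ≤ 7 and on
randomized profiles up to length 10⁴ (an exhaustive sweep to length 20 over
3 levels would be 3.5e9 profiles — computationally out of reach; the bound,
not the property, was shrunk).

## 5. The synthetic world — and what a green test establishes

The generators state the world the tests live in: wrapped-Gaussian
orientation scatter (matching the Gaussian-fit analysis model),
additive-Gaussian rendering of line/ellipse profiles, 1.61 µm/px default
pixel size (plausible for the low-magnification confocal fields the
workflow targets), 256² images, ~120 fibers or 50 cells per scene, 5%
additive noise. Gel scenes render hard-edged dark bands on a bright fibrous
background clamped safely above the 25% threshold, and their ground-truth
gap count applies the same ≥ 15 µm rule the metric uses.

What they deliberately do not emulate: optics (no PSF, no depth sectioning),
photon noise statistics, fiber curvature and branching, MNP string
aggregation physics, intensity nonuniformity across the field, and the
sheer fibril density of real collagen (hence the spectral spikiness note in
§3). A green recovery test therefore establishes that the estimators are
correct and unbiased *under this stated world* — not that they reproduce
the original study's per-image numbers, whose raw micrographs are not
available.

## 6. Open choices resolved here

- **Angle convention conflict**: the motion-angle definition ("from the
  orthogonal to the applied field") and the prose describing the median
  ("90.33° *from the applied field*") cannot both hold; we follow the
  definition (field axis = 90°), which matches the published histogram
  peaking at 90°.
- **"40 × 20 mm"** is read as the pole-face dimensions of a rectangular
  block (the vendor part is a block magnet); a disc reading would change
  only the calibration scale factor, which is absorbed.
- **Sample position**: centered in the gap (the verbal description is
  ambiguous); mirror symmetry of every reported statistic follows from
  this.
- **Histogram binning of motion angles**: 0.5°, unstated originally;
  medians are computed on raw angles, never on bins.
- **Pipeline statistics** stop at mean ± SD per group; ANOVA is routine and
  out of scope, but per-group raw values are exported for external tools.

## 7. Known limitations

Single-bead physics only; no gel viscoelasticity (affects speed, not
direction, of drift); 2-D orientation analysis of projections only; TIFF
I/O unavailable in this build (PNG/PGM/CSV supported); the 25 T/m gradient
question above; anisotropy thresholds are heuristic and should be
calibrated against expert calls before use in a new imaging context.
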