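---
title: "Single-projection reconstruction of small circular fields: model, defaults, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-projection reconstruction of small circular fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scifidose)
```

## The measurement and its inverse problem

A ribbon of thin scintillating fibers placed perpendicular to a photon beam
reads out, fiber by fiber, the dose integrated along each fiber's length.
The ribbon therefore measures a one-dimensional projection `p(x)` of the
two-dimensional dose field `D(x, z)` — for a field with revolution
symmetry, the Abel transform of its radial profile. Recovering `D(r)` from
a single projection is possible exactly because stereotactic cone
collimators produce rotationally symmetric fields whose dose decreases
monotonically off axis.

The package represents the field as `m` superimposed concentric disks with
radii `R_j` and non-negative thicknesses `beta_j`; the stack height
`d(r) = sum_j beta_j [r <= R_j]` is the dose. A fiber at off-axis distance
`x_i` intersects disk `j` along a chord of length `2 sqrt(R_j^2 - x_i^2)`,
so the folded half-profile satisfies `S = A beta` with
`a_ij = 2 delta_ij sqrt(R_j^2 - x_i^2)`. The system is overdetermined
(`n = 123 >= m = 122`) but severely ill-conditioned: the innermost disks
are seen by only the first few samples, and numerically `A` is
rank-deficient, so the on-axis height is a weakly determined direction.
Regularisation is an iteration cap on the SIRT solver rather than an
explicit penalty.

Two readings of the reconstructed profile are provided. The default for
all metrics is the **stack height** `d(r)`, which is the physically
consistent dose (a flat-top field yields a flat-top profile). The
**chord-weighted reprojection**
`pr(x) = sum_j delta_xj beta_j sqrt(R_j^2 - x^2)` — half the forward
projection of the stack — is kept as an alternative `profile_kind` for
residual diagnostics and comparison studies; applied to a flat-top field it
would give a semicircle-like shape whose FWHM is about `sqrt(3)/2` of the
field diameter, which is why it is not used for beam metrics.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| layer pitch / stagger / layers | 0.275 / 0.5 / 6 | mm / – / – | ribbon construction; effective comb 0.1375 mm |
| fiber diameter | 0.250 | mm | line-centre integration by default; top-hat averaging optional |
| half-profile samples `n` | 123 | – | 24.6 mm support at 0.2 mm spacing, sample 1 on the axis |
| profile spacing | 0.2 | mm | reconstruction grid; native comb resampled linearly |
| disk radii | 0.6–24.8, step 0.2 | mm | recurrence seed 0.4 mm; `m = 122` covers the largest cone |
| SIRT iterations | 7000 | – | the regulariser; no early stopping |
| initial condition | `beta = 0` | – | fixed point of the zero signal; non-negative path |
| median filter | 3×3 | px | impulse (transient) removal before any averaging |
| binning | 5×5 mean | px | 14 dB SNR gain; mean keeps amplitudes pitch-independent |
| background estimate | outer 10% median | – | robust to sparse outliers; clamped at zero afterwards |
| centre threshold | 5% of max | – | centroid over in-field samples only |
| penumbra sigma (generator) | 0.8 | mm | typical 6 MV cone edge; used for the whole simulated suite |
| camera pixel pitch | 0.0275 | mm/px | 5 px per effective fiber pitch, resolved stripes |
| stripe cross-profile sigma | 0.02 | mm | free parameter (the optical PSF is not specified by the hardware description); sharp enough to keep fibers distinct |

The simulated suite assigns flat-top doses 0.68, 0.76, 0.81, 0.87, 0.92,
0.96, 1.00 to the 4–15 mm cones, emulating the source-occlusion output drop
typical of 6 MV stereotactic cones; these values were fixed once as the
study conditions and are not tuned.

## What the generator emulates — and what it does not

The phantom module produces: flat-top circular fields with error-function
penumbra `D(r) = peak * pnorm((diameter/2 - r)/sigma)`; rotated square
fields (exact rectangle-Gaussian convolution, separable in the rotated
frame); per-fiber line integrals by rectangle quadrature on a 0.05 mm
grid with linear cross-interpolation; stripe-rendered camera images whose
per-stripe integral equals the fiber signal; Gaussian read noise and
sparse impulse noise, fully seed-deterministic.

It does **not** model radiation transport (no source occlusion shape, no
scatter tails beyond the Gaussian edge), optical attenuation along the
fiber, inter-fiber cross-talk, camera PSF beyond the stripe width, gain
non-uniformity, or dose differences between the six layers (collapsed into
one interleaved comb). Passing tests therefore demonstrate that the
*processing chain* inverts its own forward model to the stated tolerances —
not that a physical detector achieves them.

## Numerical choices

- **Clamp timing.** Non-negativity is applied after every SIRT update, not
  once at the end; with a zero start the iterate path stays non-negative in
  practice and the final residual never exceeds the initial one.
- **Precomputed operators.** The update is applied as
  `beta <- pmax(beta + b - M beta, 0)` with `M = C A' R A` and
  `b = C A' R S` computed once — algebraically identical to the two-matrix
  form, one small mat-vec per iteration.
- **Zero rows/columns.** Inverse sums of empty rows or columns are set to
  zero with a warning, freezing the unobservable components (the continuity
  limit of the unclamped iteration).
- **Staircase sampling.** The stack height is piecewise constant; metrics
  sample it at the step centres and interpolate linearly, which halves the
  0.2 mm radius-quantisation error of level crossings (FWHM recovery
  improves from ~0.2 mm to ~0.05 mm worst case over the suite).
- **Level crossings.** FWHM and penumbra crossings are found by walking
  outward from the global maximum and linearly interpolating the first
  bracketing pair — robust to noise-induced extra crossings far off axis.
  Levels are fractions of the profile maximum: small fields have no plateau
  to fit.
- **Folding.** The profile is recentred by linear interpolation at
  `center ± (i-1)*0.2` mm and the two sides averaged; values beyond the
  measured support are treated as zero.
- **Background.** Median of the outer 10% of samples on each side,
  subtracted and clamped at zero, with a warning if the estimate exceeds
  20% of the maximum (field reaching the edge of the ribbon).

## Design decisions that were genuinely open

- **Disk indexing.** The radius recurrence has seed 0.4 mm; the package
  treats the seed as *not* itself a disk, giving `R_1 = 0.6` mm
  (`R_1 > 0` as the model requires) through `R_122 = 24.8` mm.
- **Metric profile.** Stack height, not chord-weighted reprojection (see
  above); both are exported and selectable via
  `pipeline_config(reconstruction = list(profile_kind = ...))`.
- **Native-to-reconstruction resampling.** The 137.5 µm comb is resampled
  to the 200 µm grid by linear interpolation before folding; how this
  mapping "should" be done is not fixed by the hardware, and linear
  interpolation is exact on ramps and keeps the chain monotone.
- **Noise injection point.** The noise model lives on the camera image
  (where the physical transients occur); robustness studies in the tests
  and the acceptance script inject 1%-of-peak Gaussian read noise plus
  sparse impulses there and let the mandated chain (median filter, binning,
  y-integration) attenuate it.

## Known limitations

- **Smallest-cone on-axis bias.** With a 0.8 mm penumbra, the 4 mm cone's
  dose still varies ~3.4% inside the innermost representable disk
  (`r < 0.6` mm), so the reconstructed plateau — the disk-average — sits
  ~1% below the true axis dose, and the ill-conditioned axis direction
  adds a further ~1% deficit even at full convergence (verified against a
  non-negative least-squares oracle). The 4 mm output factor is therefore
  systematically low by ~2% relative; the effect shrinks rapidly with cone
  size (≈1.8% at 5 mm, ≈0.9% at 6 mm, <0.25% from 7.5 mm up).
- **Noise sensitivity of the plateau.** The on-axis height is a near-null
  direction of `A`, and the first folded samples are not averaged over two
  sides; camera noise therefore moves the plateau more than any other part
  of the profile, with a positive, heavy-tailed bias (clamp rectification)
  that is largest for the largest field. Under 1%-of-peak camera noise the
  15 mm reference inflates by ~0.8% on average, lowering all noisy output
  factors by ~0.3–0.5 points beyond their noiseless values.
- **Sparse targets converge slowly.** A single-disk thickness vector is
  recovered exactly by non-negative least squares but only sublinearly by
  the capped SIRT iteration; the cap is a smoothness regulariser, and
  solutions with isolated spikes should not be expected from it.
- **Penumbra broadening.** The iteration-capped inversion widens the
  20–80% penumbra by up to ~0.13 mm at the largest cone (1.48 mm
  reconstructed vs 1.35 mm analytic for the 0.8 mm Gaussian edge).

## Problem sizes used by the tests

The unit and property tests run the full 123×122 system at the default
7000 iterations wherever a claim depends on it, and reduced systems
(20×19) for oracle comparisons. The end-to-end suite simulates all seven
cones at 0.05 mm grid spacing; the noise studies use 8–20 seeds per
claim. The complete test run takes a few minutes on one CPU.
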