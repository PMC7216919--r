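# scifidose

Quality-assurance toolkit for **small static radiotherapy fields** shaped by
stereotactic cone collimators (4–15 mm diameter), measured with a
**scintillating-fiber (SciFi) ribbon detector**: a 6-layer stack of 250 µm
plastic scintillating fibers at 275 µm pitch, adjacent layers staggered by
half a pitch so the union of fiber centres samples the across-fiber axis
every 137.5 µm. Each fiber emits light proportional to the dose integrated
along its length, so a camera image of the ribbon output encodes the **1D
projection** of the 2D dose field — for a rotationally symmetric cone field,
its Abel transform.

The package is written for medical physicists doing small-field dosimetry
and for anyone who needs a tested, reusable single-projection Abel-type
inversion with a non-negativity constraint.

## The reconstruction model

A revolution-symmetric field is modelled as a superimposition of `m`
concentric disks of strictly increasing radii `R_j` whose thicknesses
`β_j ≥ 0` sum to the local dose. The fiber at off-axis distance `x_i` reads
the chord-weighted sum

```
S_i = 2 Σ_j δ_ij β_j √(R_j² − x_i²),   δ_ij = 1 if x_i ≤ R_j, else 0
```

With `n = 123` half-profile samples at 200 µm spacing (24.6 mm support) and
disks `R_j = 0.4 + 0.2·j` mm for `j = 1..122` (0.6–24.8 mm), `A β = S` is an
overdetermined, ill-conditioned triangular-support system. It is solved by
the **Simultaneous Iterative Reconstruction Technique (SIRT)**,

```
β ← β + C Aᵀ R (S − A β),   then β_j < 0 ↦ 0
```

where `C` and `R` hold the inverse column and row sums of `A`; starting from
`β = 0` and stopping after a fixed 7000 iterations, which is the
regularizer. The radial dose profile is the stack height
`d(r) = Σ_j β_j [r ≤ R_j]`, from which FWHM, 20–80 % penumbra and relative
output factors (OF, on-axis dose normalised to the 15 mm cone) are derived.

Upstream of the inversion the package implements the full measurement
chain: a synthetic-data generator (cone/square dose fields with
error-function penumbra, fiber-level line-integral forward model, camera
stripe rendering, Gaussian read noise and radiation-induced impulse noise)
and the image preprocessing the detector uses (3×3 median filter, 5×5
binning, y-axis integration, background subtraction, 200 µm resampling,
symmetric folding about the profile centroid).

## Worked example

Simulate the seven-cone clinical suite and run the full chain:

```r
library(scifidose)
report <- run_pipeline(pipeline_config(), fields = cone_suite())
print(report)
#> <qa_report> 7 field(s)
#>      field fwhm_mm penumbra_20_80_mm on_axis_dose center_mm output_factor
#> 1    cone4   4.067             1.360      0.01635 0.0011124        0.6567
#> 2    cone5   5.036             1.389      0.01855 0.0011523        0.7453
#> 3    cone6   6.016             1.410      0.01998 0.0011514        0.8027
#> 4  cone7.5   7.504             1.434      0.02161 0.0008573        0.8680
#> 5   cone10  10.002             1.453      0.02289 0.0007874        0.9197
#> 6 cone12.5  12.505             1.469      0.02389 0.0007329        0.9598
#> 7   cone15  15.006             1.481      0.02489 0.0007370        1.0000
```

The reconstructed FWHM tracks the nominal cone diameters within a few
hundredths of a millimetre; the 20–80 % penumbra reflects the simulated
0.8 mm Gaussian edge (analytic value 1.35 mm, slightly broadened by the
iteration-capped inversion); `center_mm` is the centroid of each projected
profile (fields simulated on-axis, recovered to ≈1 µm); `output_factor`
is the on-axis stack height relative to the 15 mm cone. Individual stages
are exported (`cone_dose_field()`, `project_field()`,
`render_detector_image()`, `median_filter_3x3()`, `bin_5x5()`,
`sirt_solve()`, `fwhm()`, …) and a thin CLI wraps them
(`inst/scripts/scifi.R` with `simulate`, `reconstruct`, `metrics`,
`pipeline` subcommands).

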