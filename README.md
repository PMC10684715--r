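# unwrap3d

Robust three-dimensional phase unwrapping for gradient-echo MRI, intended as
a preprocessing step for quantitative susceptibility mapping (QSM),
susceptibility-weighted imaging and other phase-sensitive applications.

## The problem and the method

The measured MR phase is the principal value of the complex signal's
argument, confined to (−π, π]; wherever the true phase φ leaves that
interval, the measurement is *wrapped*: φ = φ_wrapped + 2πk with an unknown
integer k per voxel. Recovering k is easy where the phase is smooth and
well-measured, and hard where noise is severe, where the phase changes by
more than π between neighbors, and where wrap discontinuities end inside
the object.

`unwrap3d` implements a split–merge unwrapper:

1. **Region partitioning** — the principal interval is split into six equal
   subintervals; noisy connector voxels (region-edge voxels with
   out-of-region neighbors within three voxels on at least two axes) are
   excised so no initial region hides a 2π wrap; the surviving connected
   components with ≥ 100 voxels become wrap-free **blocks**, the rest become
   residual voxels.
2. **Block merging** — starting from the largest block, the nearest
   not-yet-merged block is repeatedly unwrapped by a single integer offset
   k = round((X·ĉ − φ_wrapped)/2π), where X·ĉ is a local 3D polynomial
   (full tensor basis, orders 2 per axis) fitted by least squares to the
   100 closest unwrapped voxels and evaluated at the 100 closest block
   voxels, with a majority vote over the per-voxel offsets.
3. **Quality-guided residual growing** — remaining voxels are unwrapped one
   by one in order of a phase-derivative reliability score, each by a
   distance-weighted local polynomial fit inside an 11³ window (with
   model-order selection, an extrapolation guard, and a phase-continuation
   competitor for rapidly varying but coherent phase).

The package also ships the two standard synthetic benchmarks (a Gaussian
phase bump under an SNR sweep 0.5–5, and a variable-gradient sinusoidal
phantom at SNR 5), the misclassification-ratio (MCR) evaluation against the
noise-corrected reference phase, NIfTI input/output, and a command-line
interface. See the methods vignette (`vignettes/phase-unwrapping.Rmd`) for
the model, its assumptions and the numerical design.

## Worked example

```r
library(unwrap3d)

# a 64^3 wrapped Gaussian-bump phantom at SNR 5 (peak 14 rad, noise SD 20)
ds  <- simulate_gaussian_dataset(shape = c(64, 64, 64), gaussian_sd = 13,
                                 peak = 14, magnitude = 100, noise_sd = 20,
                                 seed = 42)
vol <- wrapped_volume(ds$wrapped_phase)
fit <- unwrap(vol)
print(fit)
#> 3D phase unwrapping by region partitioning + local polynomial model
#>   ROI voxels:        262,144
#>   blocks:            5 (largest 65,025 voxels)
#>   residual voxels:   169,633 first, 3,974 second
#>   unwrapped:         262,144 / 262,144 (0 unreachable)
#>   2*pi consistency:  8.88e-16 rad
#>   elapsed:           8.0 s

compute_mcr(fit$unwrapped, ds$reference_phase)
#> MCR 0% (0 / 262144 voxels wrong, threshold 0.3142 rad, global offset 0)
```

The report reads: the ROI was split into 5 wrap-free blocks (the largest,
65,025 voxels, seeded the solution), 174 thousand voxels were handled by
quality-guided growing, every voxel was unwrapped, and the output satisfies
`unwrapped = wrapped + 2*pi*k` to machine precision. Scored against the
noise-corrected reference with the π/10 threshold (after removing the modal
global 2π offset), not a single voxel received a wrong wrap count.

From the shell, the same pipeline runs through the installed CLI script:

```sh
Rscript inst/cli/unwrap3d simulate --experiment 1 --snr 5 --seed 7 -o phantom/
Rscript inst/cli/unwrap3d unwrap phantom/wrapped_phase.nii.gz \
    -o unw.nii.gz --k-out k.nii.gz --report run.json
Rscript inst/cli/unwrap3d evaluate unw.nii.gz phantom/reference_phase.nii.gz
```

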