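---
title: "Region-partitioned 3D phase unwrapping with a local polynomial model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-partitioned 3D phase unwrapping with a local polynomial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwrap3d)
```

## The problem

A gradient-echo MR acquisition yields a complex signal whose argument — the
phase — carries field-map information needed by quantitative susceptibility
mapping, susceptibility-weighted imaging and water–fat separation. The
arctangent only returns the principal value in $(-\pi, \pi]$, so wherever the
true phase $\psi$ leaves that interval the measured phase
$\varphi = \psi - 2\pi k$ is *wrapped* by an unknown integer $k$ per voxel.
Unwrapping recovers $\psi = \varphi + 2\pi k$ under the assumption that the
true phase is spatially smooth. The practical difficulties are severe noise
(low SNR), phase that changes by more than $\pi$ between neighboring voxels,
and open-ended wrap discontinuities that defeat naive path following.

`unwrap3d` implements a split–merge unwrapper for 3D volumes built from
three ingredients:

1. **Region partitioning.** The principal interval is cut into six equal
   subintervals, $(-\pi,-2\pi/3], \dots, (2\pi/3,\pi]$. Any connected set of
   voxels drawn from a single subinterval is wrap-free by construction.
   Before connected components are identified, *noisy connector voxels* are
   excised: a voxel is removed when it sits on the region edge (a face
   neighbor outside the region) and has out-of-region neighbors within three
   voxels along at least two of the three axes. This severs the thin noisy
   bridges through which two areas a whole wrap apart can masquerade as one
   region (a *hidden wrap*). The surviving components with at least
   `size_threshold` voxels (default 100) become **blocks**; smaller
   components become **second residual voxels** and the excised connectors
   **first residual voxels**. Blocks plus the two residual classes partition
   the ROI exactly.

2. **Nearest-first block merging.** The largest block seeds the solution
   with offset $k = 0$. Repeatedly, the not-yet-merged block closest to the
   unwrapped set (Euclidean distance between closest voxels, exact distance
   transform) is merged: a local 3D polynomial
   $\sum_{l\le L}\sum_{m\le M}\sum_{n\le N} C_{lmn} x^l y^m z^n$ (full
   tensor basis, default orders $2,2,2$, 27 terms) is fitted by least
   squares to the `fitting_count` (default 100) unwrapped voxels nearest the
   block, evaluated at the 100 block voxels nearest the unwrapped set, each
   prediction is rounded to an integer number of cycles
   $k = \operatorname{round}((\hat\psi - \varphi)/2\pi)$, and the modal $k$
   (ties: rounded mean of the real-valued offsets) unwraps the whole block
   rigidly, preserving its wrap-free interior.

3. **Quality-guided residual growing.** Remaining voxels are unwrapped one
   at a time, each by a distance-weighted local polynomial fit to the
   already-unwrapped voxels inside a centered `window`$^3$ region (default
   11). The processing order follows a reliability score — the phase
   derivative: lower local derivative, earlier processing.

## Numerical design of the growing step

The growing step decides one integer per voxel; a decision is correct
whenever the model prediction is within $\pi$ of the (noisy) true phase.
Several concrete mechanisms keep that error controlled across two very
different regimes — near-random phase at SNR $\tfrac12$ and coherent phase
changing by up to $2.4$ rad/voxel:

* **Tricube distance weighting.** Fits use every unwrapped voxel in the
  window, weighted by $(1-(d/D)^3)^3$ with $D$ the window half-diagonal —
  the standard kernel of local polynomial regression. Nearby voxels
  dominate, yet hundreds of points still contribute when the field is flat.

* **Nested-model selection with an F-gate.** The weighted mean is the
  baseline; the trilinear model and then the full tensor-order model are
  adopted only when they explain significantly more variance ($F > 4$).
  On noise-only windows no spurious trend is chased — the single most
  important protection against the runaway in which each over-extrapolated
  voxel feeds a larger extrapolation downstream.

* **Predictive mean-squared-error competition.** Every accepted model is
  scored by $\hat\sigma^2 (1 + h_0)$, where $\hat\sigma^2$ is its residual
  variance (which absorbs lack of fit) and $h_0$ the leverage of the query
  voxel (which scales noise amplification and flags extrapolation beyond
  the data support). The candidate with the smallest estimated predictive
  MSE wins. A further candidate competes in the same currency: the mean
  *phase continuation* $y_u + \mathrm{wrap}(\varphi_v - \varphi_u)$ over
  unwrapped 26-neighbors — exact whenever the true phase steps by less than
  $\pi$ across a link — priced by the empirical scatter of the
  continuations, or for a single link by an aliasing-risk tail whose scale
  is the smallest per-axis RMS phase step at the voxel (noise is isotropic;
  structure is directional). On coherent rapidly varying phase the
  continuation wins; on incoherent noise wide averaging wins.

* **Front-aware ordering.** A candidate's queue priority is the worse of
  its static quality score and the smallest wrapped step along any link to
  the unwrapped front. Steep interfaces are therefore crossed where the
  field is locally gentle, and regions behind a steep wall wait until a
  consistent path (often along a low-gradient direction) reaches them. The
  residual classes are grown in one interleaved pass: the quality ordering
  already processes small coherent regions (second residuals) before noisy
  connectors (first residuals), and a strict class barrier would force the
  growth to cross steep interfaces just to stay within one class
  (`strict_passes = TRUE` restores the literal two-pass order).

* **Safeguards.** Predictions are clamped to the window's value range
  $\pm 2\pi$ (a voxel adjacent to the front cannot legitimately exceed its
  neighborhood by more than one wrap), rank-deficient designs take the
  minimum-norm solution, and later ladder stages are skipped once the
  predictive MSE falls below $0.15\,\mathrm{rad}^2$ — a 1-$\sigma$
  prediction error of $\sim 0.4$ rad against the $\pi$ rounding margin, at
  which point further refinement cannot change any integer decision. The
  full-order stage is evaluated on the nearest $8 \times 27$ points, which
  bounds its cost and keeps the quadratic a local correction.

Two block-level safeguards mirror these: the inter-block fit demotes its
polynomial order while the median target leverage exceeds 1 (interface
geometries are thin curved shells on which an unconstrained quadratic can
predict hundreds of radians), and a block whose gap to the unwrapped set
exceeds the window edge is not merged by long-range extrapolation at all —
it is handed to residual growing, which crosses the gap voxel by voxel.
When no region reaches the size threshold (very low SNR), the largest
cleaned region seeds the growth, and as a last resort the single most
reliable ROI voxel does.

All of this is deterministic: identical inputs give identical outputs, and
every output voxel satisfies
$\hat\psi = \varphi + 2\pi k$ to machine precision, which the run report
verifies (`consistency_rad`) and the emitted integer `k` map makes
externally auditable.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `size_threshold` | 100 | voxels | minimum block size; smaller regions become second residuals |
| `fitting_count` | 100 | voxels | fitting voxels per side of an inter-block interface |
| `window` | 11 | voxels | edge of the residual fitting window (odd) |
| `orders` | (2,2,2) | — | per-axis polynomial orders, full tensor basis |
| `connectivity` | 26 | — | neighborhood for labeling and growing adjacency |
| `fit_cap` | `window^3 - 1` | voxels | cap on window fitting points |
| `exclusion_reach` | 3 | voxels | axis distance probed by the noisy-voxel test |

The block-size threshold trades robustness against coverage: large values
leave fewer, farther-apart blocks (stressing inter-block modeling), small
values admit noisy blocks early in the merge path. The window size trades
fitting-data volume against model validity — beyond the scale on which a
quadratic approximates the field, more data only adds bias; the kernel
weighting softens this trade-off considerably.

## The synthetic phantoms

`simulate_gaussian_dataset()` emulates an SNR sweep: a radially symmetric
Gaussian phase bump (SD 20 voxels over a $100^3$ grid) scaled to a peak of
20 rad (about three wraps center-to-edge), converted to complex data at
magnitudes 10–100 with independent complex Gaussian noise of SD 20 per
channel, i.e. SNR 0.5–5. The bump's peak amplitude is a package choice (the
phantom family fixes only the spatial SD); 20 rad gives several closed wrap
fronts while keeping the voxelwise gradient ($\le 0.61$ rad/voxel) inside
the smoothness assumption, and a sweep over peaks 7–16 rad in the test
suite confirms exact noiseless recovery does not depend on the choice.

`simulate_variable_gradient_dataset()` emulates rapid, depth-dependent phase variation:
$\psi = H[(\sin x/\pi)(1.50 - z) + (\sin y/\pi)(0.49 + z)]$ on a
$101 \times 101 \times 51$ grid with $H = 5$, $x, y$ the raw voxel indices
in radians (period $\approx 6.3$ voxels, gradients up to 2.4 rad/voxel
whose direction rotates with the normalized slice coordinate $z$),
magnitude 50 and noise SD 10 (SNR 5). Taking the indices directly as
radians is the convention that actually produces "different phase change
levels" steep enough to defeat classical unwrappers; a `xy_scale` argument
exposes the alternative milder readings.

The scoring reference is the generated true phase plus the noise-induced
principal phase change — congruent to the noisy wrapped phase at every
voxel — and the misclassification ratio (MCR) is the percentage of ROI
voxels whose unwrapped phase misses that reference by more than $\pi/10$
rad after removing the modal global $2\pi$ offset (any unwrapper output is
defined only up to one global wrap; voxels left not-done count as wrong).
Because reference and wrapped phase agree modulo $2\pi$, the MCR is exactly
the fraction of incorrect integer offsets.

What these phantoms do *not* emulate: spatially varying SNR and signal
dropout, anisotropic voxels, background-field gradients at air–tissue
interfaces, open-end cutlines entering from outside a restricted ROI mask,
and coil-combination artifacts. Passing the benchmarks therefore shows the
algorithm's behavior under noise and steep smooth variation, not the full
difficulty of in vivo abdominal data.

## What the benchmarks can and cannot show

A floor argument is useful when reading MCR values at very low SNR. With
the noise-corrected reference, a voxel is scored wrong exactly when the
predictor misses the *noisy* true phase by more than $\pi$; errors
therefore concentrate where the voxel's own phase noise is near $\pm\pi$.
Even a hypothetical predictor equal to the ideal smoothed field — limited
only by averaging the window's noise — retains a slip probability of order
$f(\pi)\,\sigma_{\mathrm{pred}}$ per voxel, where $f(\pi)$ is the density
of the phase-noise distribution at $\pm\pi$ ($\approx 0.08$ per rad at SNR
0.5). No growing method of this class can reach an arbitrarily small MCR
at SNR 0.5; the attainable pooled mean over the 0.5–5 sweep is a few
hundredths of a percent at best, dominated entirely by the two lowest SNR
levels, while every level at SNR $\ge 2.5$ unwraps to within a few
thousandths of a percent. The package reports the per-SNR breakdown next
to the pooled mean so both readings are visible.

## Problem sizes used

The repeated-simulation harness defaults to the full phantom sizes
($100^3$ and $101 \times 101 \times 51$) and three repetitions — about
fifteen minutes on one CPU — which stabilizes the pooled mean to well
inside the tolerances checked by the test suite; `reps`, `seeds` and a
`shape` override allow both quicker smoke runs and the full 50-repetition
protocol (`run_simulation_experiment(1, reps = 50)`) when hours of compute
are acceptable. Unit tests run on 14–40 voxel cubes where every invariant
(partition completeness, $2\pi$ consistency, exact noiseless recovery,
oracle agreement) is checked exhaustively.

## Known limitations

* A single integer per block presumes the partition never fuses two areas
  separated by a hidden wrap; the noisy-voxel exclusion makes this likely,
  not certain. The ambiguous phrasing of its second criterion (any
  out-of-region neighbor within reach, versus a fully out-of-region side)
  is exposed as `exclusion_conjunctive`; the two readings give
  indistinguishable results on both phantom families.
* Phase steps genuinely larger than $\pi$ between face neighbors are
  unrecoverable pointwise by any method honoring the smoothness assumption;
  near-Nyquist gradients (the variable-gradient phantom's 2.4 rad/voxel)
  already leave a small residue of isolated errors near turning points.
* Unreachable ROI islands (no 26-connected path from the seed) are
  reported, not invented.
* Distances are measured in voxel units; anisotropic spacing is ignored,
  matching the algorithm's formulation.
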