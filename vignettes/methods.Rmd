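---
title: "Directional FSC diagnosis and entropy-regularized map restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional FSC diagnosis and entropy-regularized map restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodecon)
```

## Scope and model

Preferred particle orientation makes the information content of a
single-particle reconstruction direction-dependent. `cryodecon` treats the
reconstruction as the ground-truth density observed through an anisotropic
optical transfer function (OTF) plus noise, estimates that OTF from the
data themselves (via directional FSC between half-maps), and inverts it
under regularization. This vignette records the model, the conventions,
the tunable parameters, and the design choices made where the literature
leaves the details open.

## Conventions

All volumes are cubic, even-sided (`N >= 8`) grids with an isotropic voxel
size in Å/px; the forward FFT is unscaled and the inverse carries `1/N³`.
Fourier-space volumes are stored DC-centred: the voxel at index `N/2 + 1`
is DC and an offset of `k` voxels corresponds to frequency
`k/(N·voxel_size)` 1/Å. Euler angles are ZYZ (`rot`, `tilt`, `psi`), the
convention of the common refinement packages, and a particle's view axis
is the third row of its rotation matrix
`(-sin t cos r, sin t sin r, cos t)` — its angle to +z is the tilt and is
independent of the in-plane angle `psi`. This convention is stated
explicitly because nothing in the pipeline can recover from a silent
ZXZ/ZYZ mix-up.

## Directional FSC

`global_fsc()` computes the standard half-map FSC on shells one Fourier
voxel wide (voxel assigned by rounded radial index, DC excluded, shells
beyond the Nyquist sphere dropped). `compute_dfsc()` repeats the
computation restricted to double cones — voxels within `apex_angle/2`
(default 20°) of a direction or its antipode — centred on `n_dirs`
(default 500) Fibonacci-lattice directions. Double-cone membership is
forced by physics: a real map's transform is Hermitian, so the two nappes
carry identical information and a single-nappe cone would simply halve
every count. Shells with fewer than 10 cone voxels are reported `NA` and
excluded from resolution estimation rather than zero-filled; at small box
sizes the innermost shells of every cone are undefined, which is the
honest statement of their information content.

Resolution at a threshold (0.143 for half-maps, 0.5 against a reference
or model map) is the reciprocal frequency of the first crossing, linearly
interpolated between shells; a curve that never crosses is reported at
Nyquist with a `crossed = FALSE` flag.

`render_dfsc_volume()` paints each Fourier voxel with a weighted average
of all cones containing it, each curve interpolated at the voxel's radial
frequency. The weight for a cone with axis `d` is
`max(0, cosθ − cos(apex/2))` — linear in the cosine, positive inside the
cone, vanishing at its edge — chosen because the published description
("weighted average") fixes no functional form and this one is smooth,
cheap and manifestly positive. Voxels covered by no cone receive the
unweighted direction mean; DC is set to 1. The rendered volume is
explicitly symmetrized across antipodes because BLAS summation order can
otherwise leave last-ulp asymmetries.

## From dFSC to OTF

The OTF is `clamp(dFSC, 0, 1) × |FT(PSF)|`, normalized so DC is exactly 1.
The PSF is an isotropic Gaussian with `σ = res/(π√2·ps)` pixels, the width
that makes its transfer fall to 1/e at frequency `1/res` (the `molmap`
convention); `res` defaults to the global half-map FSC(0.143) resolution
and is overridable. Negative dFSC values are clamped to zero before the
product: negative shell correlations are noise realizations, and a
transfer magnitude must be nonnegative. The Gaussian factor plays the role
of a smooth global envelope that prevents unbounded high-frequency
amplification during inversion.

## The deconvolution functional

The solver minimizes

```
J(f) = Σ_v (A f − g)²_v + λ · Σ_v T · log(1 + (Δf)²_v / T)
```

with `A` multiplication by the OTF in Fourier space, `Δ` the 27-point
discrete Laplacian (mean of the 26 neighbours minus the centre) with
periodic boundaries, smoothing weight `λ` (default 0.5) and nonlinearity
scale `T` (default 10⁴). The penalty is deliberately constructed so that

* `λ` scales the whole regularizer (the "smoothing" knob),
* small `T` saturates the penalty for large curvature — edge-preserving,
  entropy-like behaviour,
* `T → ∞` reduces it to the Tikhonov quadratic `λ Σ (Δf)²`, whose exact
  minimizer `F = O·G / (O² + λ|L̂|²)` is computable per Fourier voxel
  (`quadratic_solution()`) and serves as an independent oracle for the
  iterative solver in the test suite.

This functional is a reimplementation in spirit, not a port: the reference
implementation of entropy-regularized deconvolution in the light-microscopy
lineage does not publish its exact functional, so parameter values here
are comparable in role, not necessarily in magnitude, and the grid screen
below is the calibration mechanism.

Positivity is enforced by optimizing `s` with `f = s²`, initialized from
`s = √max(g, 0)`: the constraint set stays smooth for conjugate gradient,
and `min(f) ≥ 0` holds exactly rather than approximately. It is applied
globally rather than inside a region of interest — the simpler choice, and
the solvent region of a masked map is near zero anyway. Optimization is
Polak–Ribière conjugate gradient with a parabolic-fit line search plus
Armijo backtracking, so the objective trace is nonincreasing by
construction; iteration stops at a relative objective change below `tol`
(default 1e-6) or at `max_iter` (default 100). The solver output is *not*
normalized; `run_pipeline()` normalizes (zero mean, unit sd) as its final
step, keeping the solver comparable to the closed-form oracle and linear
in its input in the quadratic limit.

## Masking

`bounding_sphere_mask()` finds the axis-aligned bounding box of voxels at
or above a display threshold, takes the circumscribing sphere (half the
box diagonal — no above-threshold density is ever cut), and applies a
raised-cosine soft edge (default 20 px), the standard band-limited edge
profile. Bias-correction of masked FSC by phase randomization is out of
scope; the soft spherical mask is the mitigation. Shaped masks from other
tools can be supplied as files wherever a mask is accepted.

## The synthetic data model

The generator stands in for the re-reconstruction experiments used to
validate the original method: rather than re-running a refinement package
on selected particles, it degrades phantoms directly in Fourier space,
preserving the statistical structure the pipeline consumes — anisotropic
information loss plus independent half-map noise.

* `random_blob_phantom()`: a sum of Gaussian blobs, centres confined to
  the central half of the box (solvent margin), widths 2–4 Å and peak
  densities 0.5–1.5 by default on a 64³, 1 Å/px grid — compact,
  band-limited features at a desk-scale box size.
* `degrade_missing_cone()`: zeroes the Fourier double cone of a chosen
  half-angle about an axis (strict membership, so the zero-angle limit is
  the identity and DC always survives). Removing views tilted more than
  60° from z corresponds to a missing double cone of half-angle 30°, the
  geometry used throughout the tests.
* `sampling_weights()` / `weights_to_filter()`: central-slice accumulation
  (nearest-plane binning, `|k·v| ≤ 0.5` voxel) of an orientation set and a
  Wiener-style conversion `w·snr/(1 + w·snr)` to an attenuation — the
  gentler, attenuating counterpart of the hard cone. Nearest-plane binning
  means a voxel at radius `r` can be touched by slices whose poles are up
  to `asin(0.5/r)` away; the provably empty region after a 60° tilt cut is
  therefore the cone shrunk by that margin, and that is what the tests
  assert.
* `make_half_maps()`: two copies of a volume plus independent white
  Gaussian noise (seeds `2·seed`, `2·seed + 1`). Real half-map noise is
  coloured and resolution-dependent; white noise is the stated
  simplification, sufficient for the correlation structure the FSC
  machinery consumes. Noise sd 0.02–0.05 against blob peaks of ~1 gives
  fixtures whose global FSC(0.143) resolution sits at 4.5–5.5 Å on a 64³
  grid — far from both the trivially-perfect and the hopeless regimes.

What passing tests on these fixtures do **not** show: behaviour under CTF
effects, coloured noise, mask-model mismatch, or the refine-deconvolve
iteration loop with an external refinement package — all outside this
package's scope.

## Evaluation metrics

`cone_partition_resolution()` averages per-direction resolutions inside
versus outside a cone of directions. Elongation is measured by
`fwhm_axes()`: axis-parallel 1D profiles through a feature,
half-maximum crossings linearly interpolated (principal-axis ellipsoid
fits would be less testable for no benefit at phantom scale). One
subtlety, documented because it is easy to trip over: an FWHM probe is
only meaningful if the feature is *resolved*. A marker blob whose FWHM
equals the map's resolution limit measures the PSF, not the restoration;
the acceptance fixtures therefore use a σ = 3 px marker (FWHM 7.1 Å
against a ~5 Å map). `fourier_cone_correlation()` quantifies missing-cone
recovery directly: the normalized correlation of Fourier coefficients
inside the cone between a map and the ground truth.

## Parameter screening

`screen_parameters()` deconvolves for every pair on a smoothing ×
nonlinearity grid (defaults: the standard 18 × 5e-5…5e2 by 8 × 1…1e7
lists, 144 pairs) and scores each result by the mean per-direction dFSC
resolution against a reference map at threshold 0.5. The published
procedure compares screens visually; a scalar score is needed for
automation, and mean map-to-reference resolution is the least surprising
choice. The screen is a ranking device, so its dFSC sampling defaults to
60 directions for speed. Test-suite screens run at 16³–32³ with 3–15
iterations per cell; these sizes are the package's chosen desk-scale
conditions and complete in minutes on one CPU.

## Numerical choices and limitations

* Voxel size is read from MRC cell/grid header fields; per-axis mismatch
  above 1e-4 relative is an error (isotropic voxels are assumed
  throughout). Non-cubic maps are rejected, not padded.
* Tilt-filter boundaries are inclusive with a 1e-9° tolerance, so
  `acos(cos(120°))` rounding cannot flip a boundary particle; with
  inclusive bounds the uniform-orientation retention is exactly 1/2 in the
  continuum limit.
* The raised-cosine low-pass filter is a projection only when its edge
  width is zero; with a soft edge, applying it twice squares the
  transition band. Idempotence holds (and is tested) for the hard-edge
  case.
* The missing-cone restoration recovers in-cone *correlation* robustly
  (≈ 0 → 0.7–0.85 on 64³ fixtures across seeds) but reduces real-space
  elongation only for features within the band the positivity constraint
  can refill; a hard-empty cone at the resolution limit is information
  that no regularizer can honestly reinvent.
* Determinism: every generator takes an explicit seed and restores the
  caller's RNG state; the solver is seed-free and deterministic, so whole
  pipeline runs are bit-identical under fixed inputs.
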