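---
title: "Template-based field map prediction and shimming: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based field map prediction and shimming: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Static B0 shimming homogenizes the scanner's main field over the brain by
driving room-temperature coils whose fields are shaped as solid spherical
harmonics (X, Y, Z, Z2, XZ, ...). The usual workflow first acquires a B0
field map — a voxelwise map of off-resonance in Hz computed from the phase
evolution between two gradient-echo readouts — and then solves a masked
linear least-squares problem for the coil settings. The field map costs a
minute or more of scan time.

`fieldshim` implements the template alternative: because the
susceptibility-induced field in the head is dominated by low-order
structure that is highly consistent across people (an inferior–superior
gradient from the body and neck, an anterior–posterior gradient, plus
localized perturbations near the frontal sinus and ear canals), a
*template* field map — the voxelwise mean of many subjects' field maps
co-registered into one standard space — predicts an unseen subject's field
well enough for shimming. Only a seconds-long structural localizer is
needed at scan time: it is registered to the standard anatomy (12 dof),
the transform is inverted, and the template mean is warped into subject
space, where the shim is computed exactly as it would be from a measured
map.

## The shim model

The hardware model is the real solid spherical-harmonic family in
unnormalized Cartesian polynomial form,

$$ 1;\; x;\; y;\; z;\; z^2 - \tfrac{x^2+y^2}{2};\; xz;\; yz;\;
   x^2-y^2;\; xy;\; \dots $$

through fourth order ((N+1)^2 terms through order N). Coordinates are
world millimetres about the magnet isocenter — the shim field is fixed in
the scanner, not the head, which is exactly why subject position matters
for "fixed" shims — so an order-n coefficient carries units Hz·mm^-n.
Every polynomial satisfies Laplace's equation exactly, which the test
suite verifies with a fourth-order finite-difference Laplacian (exact for
quartics, so the check is at rounding level). The Cartesian convention was
chosen because it matches coil naming on clinical systems; no published
normalization is assumed.

Shim computation (`compute_shim`) minimizes the sum of squares of
`field + synthesized shim` over the brain-mask voxels. Two conventions
are fixed once and asserted in tests:

* **Sign**: the shim field *adds* to the subject field, so the optimal
  coefficients are the negated projection of the field onto the basis.
* **DC term**: always in the design. With an intercept present,
  minimizing the residual RMS is identical to minimizing its standard
  deviation, so the reported figure of merit (population-std of the
  residual, divisor N) is also the quantity optimized. Divisor N versus
  N−1 is immaterial at brain-mask voxel counts but is pinned for
  reproducibility.

The least-squares solve uses a QR factorization after column
equilibration, and a deficient rank is a hard error naming the collapsed
terms — silent truncation would quietly corrupt strategy comparisons.

Coil calibration (`calibrate_coil`) decomposes fields measured at a ladder
of hardware settings into harmonic coefficients and fits each term
linearly against the setting. Hardware units are treated as opaque
throughout: the calibration maps "one hardware unit" to Hz·mm^-n, and
nothing in the pipeline interprets the unit itself.

## The synthetic cohort

No deposited field-map database exists, so the package generates one. The
generator is first-class, tested code, and its defaults define the study
conditions used everywhere:

* **Grid**: 64³ voxels at 2 mm isotropic — the resolution of typical
  brain field mapping. Axes: +x right, +y anterior, +z superior.
* **Anatomy**: an ellipsoidal head with a neck stub, brain inside, a
  frontal sinus (anterior–inferior of the brain) and two ear-canal
  cavities. Air carries a +0.36 ppm susceptibility offset against tissue.
* **Field**: the Fourier-domain dipole convolution of the susceptibility
  model, D(k) = 1/3 − k_z²/|k|², in the Lorentz-sphere-corrected
  convention (a uniform sphere has zero interior shift; the test suite
  checks the interior and the closed-form exterior dipole to within a few
  percent). D(0) is set to zero: the spatial mean is a convention, and
  shimming is invariant to DC. The volume is zero-padded by a factor of 2,
  with the susceptibility centred, to suppress circular-convolution
  wrap-around; cavity edges use a partial-volume ramp of one voxel so the
  discrete sphere behaves like a sphere rather than a staircase.
* **Low-order background**: explicit gradients of 1.5 Hz/mm along z and
  0.6 Hz/mm along y in the *scanner* frame emulate the body-induced field
  that dominates whole-brain inhomogeneity.
* **Cavity amplitudes**: 300 Hz (sinus) and 200 Hz (ears) peak
  perturbation at 7 T scale (B0 = 297.2 Hz/ppm), each multiplied per
  subject by a uniform factor in [0.6, 1.4]. These are free parameters of
  the generator, chosen once as plausible for air–tissue interfaces at
  ultrahigh field; they are not claims about humans. They place the
  intersubject field variance where it belongs — near the cavities — and
  leave a realistic high-order residual inside the brain that no
  second-order shim can remove.
* **Pose**: each subject is the canonical anatomy under a random affine —
  rotations N(0, (5,3,3)°), translations N(0, (2,2,4) mm), per-axis
  log-scales N(0, 4%) — reflecting positioning without special
  instructions. The anatomy is evaluated *analytically* at the
  transformed coordinates, not interpolated, so ground-truth transforms
  are exact and registration tests are not contaminated by double
  interpolation.
* **Noise and baseline**: 1 Hz i.i.d. field noise; a baseline shim drawn
  uniformly per term (±30 Hz DC, ±0.8–1.2 Hz/mm first order,
  ±0.008–0.015 Hz/mm² second order) that downstream processing removes.

Physical fidelity has limits, stated plainly: rotating a head truly
changes its induced field (the generator's `dipole` mode captures this,
since the dipole kernel stays aligned with scanner z while the anatomy
rotates), but tissue classes, chemical shift, R2* decay and flow are
absent, and the anatomy is an ellipsoid, not a head. A passing suite
therefore demonstrates the *method's* correctness and its behaviour under
the stated statistical structure — not performance on human data. The
`warp_template` mode goes one step further from physics: subject fields
are exactly affinely related to the template field. It exists to validate
the registration/prediction chain in isolation, where "perfect prediction
up to interpolation" is the correct expectation.

## Field-map processing

Dual-echo phase pairs (TE1 = 4.08 ms, ΔTE = 1.02 ms by default) give the
field as wrap(φ2 − φ1)/(2πΔTE), alias-free within ±1/(2ΔTE) ≈ ±490 Hz.
The wrap convention is the half-open interval (−π, π].

Unwrapping is a quality-guided region-growing unwrapper with quality =
inverse local variance of the wrapped phase gradients, optionally
magnitude-weighted — the same contract as the established
region-expanding unwrappers: within each 6-connected mask component the
output is congruent to the input modulo 2π voxelwise and recovers smooth
phase up to one global 2π multiple per component. That per-component
constant is fixed by bringing the component's median phase as close to
zero as a 2π shift allows; since shimming is DC-invariant this choice is
safe. Slices are treated as a 3D volume. Severely aliased fields (beyond
±490 Hz at the default ΔTE) cannot be disambiguated from the phase pair
alone; the package does not guess.

Baseline-shim removal subtracts the synthesized field of the recorded
setting and tags the map, because the operation is linear and *not*
idempotent — applying it twice corrupts the map, so the `shim_state` tag
travels with every field map. Database QC follows the 90% rule: the
fraction of the structural brain mask covered by the field-map footprint
must reach 0.90, with both the threshold and the transform between the
two spaces explicit arguments.

## Spatial normalization

Transforms are 4×4 world-mm matrices with explicit source/target space
labels; composition checks the labels, so assembling
subject→structural→standard chains in the wrong order is an error rather
than a silent bug. Registration is intensity-based multi-resolution local
optimization: a block-averaged pyramid (coarsest level ≥ 16 voxels per
axis), Nelder–Mead followed by a BFGS polish with numeric gradients at
each level, correlation ratio as the default cost (options: SSD, NCC),
evaluated on fixed-image foreground voxels only — including the huge
empty background both dilutes and measurably biases the optimum. The
similarity is computed by pulling the moving image through the candidate
transform with compiled trilinear interpolation at exactly those
foreground points. Registration is a means here, not the contribution:
externally computed transforms (plain-text 4×4) can be supplied to every
consumer, so outputs of any external registration tool can be injected.

The standard space is the package's own canonical anatomy on the 2-mm
grid — a deliberate replacement for a brain atlas so that the repository
needs no external downloads; any NIfTI atlas with a brain mask drops in.
Field maps are interpolated trilinearly; masks nearest-neighbour.
Resampling is pull-based and out-of-footprint voxels are marked invalid
(NA) and excluded from template counts and masks. The two-stage strategy
(field-map magnitude → structural at 6 dof, structural → standard at 12
dof) mirrors the fact that structural scans cover the whole brain and
carry more registration information.

Template construction averages the warped field maps voxelwise over the
subjects whose footprint and brain mask cover each voxel, retaining the
voxelwise standard deviation and the contributing count. Prediction
registers the localizer to the standard structural (12 dof), inverts, and
resamples the template mean into subject space, masked by the transformed
standard brain mask.

## The strategy comparison

`loocv_evaluate` reproduces the seven-way comparison: for each held-out
subject the template, the individual fixed shims, their average, and the
random-shim ranges are computed from the remaining subjects only. The
strategies are: measured (the least-squares optimum on the subject's own
field — by construction a lower bound on every other strategy evaluated
with the same basis and mask, which the tests assert as an exact
inequality); individual registered (each donor's field warped into the
subject's space); averaged registered (the template prediction);
individual fixed (each donor's own optimal shim applied unchanged);
averaged fixed (termwise mean); random (each term uniform within the
training min–max); and tune-up. Two ambiguities had to be resolved and
are fixed as follows:

* Whether random-shim ranges and averaged shims exclude the held-out
  subject is not obvious; the no-leakage choice (recompute within each
  fold) is used, and a test reproduces a fold by hand from the training
  subjects alone to prove nothing leaks.
* The residual is evaluated over the same brain mask used for fitting.
* The tune-up shim is represented by the all-zero setting: on synthetic
  data there is no phantom-calibrated vendor default, and zero is the
  natural "no subject-specific information" reference. On real systems
  the tune-up setting is nonzero; substituting the recorded vendor values
  is a one-line change.
* Subject-to-standard transforms come either from the cohort's recorded
  ground truth (`transform_source = "true"`, the default — deterministic
  and fast) or from registration of each subject's structural
  (`"register"`, the full pipeline as run on real data).

The paired comparison between strategies uses a Wilcoxon signed-rank test
implemented from first principles: zero differences dropped (the original
treatment), mid-ranks for ties, exact enumeration of all 2^n sign
patterns for n ≤ 12 (the two-sided p doubles the smaller tail), and a
normal approximation with tie correction and continuity correction above.
The exact branch is validated against an independent brute-force
enumeration in the tests.

## Numerical choices and problem sizes

* Harmonic fits: QR with column equilibration; rank deficiency errors.
* Dipole convolution: padding factor 2, susceptibility centred, kernel
  rebuilt per call from the voxel size; requires an axis-aligned grid.
* Registration determinism: fixed initialization (identity), fixed
  iteration budgets; no stochastic search.
* Unwrapping ties: deterministic tie-break on voxel index in the
  priority queue.
* All randomness (cohort, baseline shims, random shims, noise) flows
  from explicit integer seeds; the same seed reproduces a cohort
  bit-for-bit.

The shipped tests run the full pipeline at sizes chosen to exercise every
code path at desk scale: pure-numerics checks on 8³–16³ grids, cohort
properties on 32³ at 4 mm (the head geometry needs a ~128 mm field of
view), and the registration, prediction and strategy-ordering checks on
the default 64³ cohort with 10–20 subjects. The strategy ordering asserted
on the default cohort (tune-up worst; random better than tune-up but worse
than individual fixed shims; averaged strategies at least as good;
measured best) is asserted as orderings of cohort means only — the Hz
values themselves depend on generator amplitudes and are not claims about
human data.

## Known limitations

* Affine registration only; no nonlinear refinement, so anatomy that a
  12-dof transform cannot express becomes prediction error — by design,
  since the prediction method itself is affine.
* Brain extraction is out of scope: masks are inputs for real data and
  generated for synthetic data.
* No shim-current hardware limits or clamping; computed settings are the
  unconstrained least-squares optimum.
* The unwrapper's guarantee holds where true neighbour phase differences
  stay below π; pathological noise can still fragment a component, in
  which case each fragment carries its own 2π constant.
* 2D multi-slice phase acquisitions are treated as 3D volumes.
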