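---
title: "Simultaneous multi-slice free-breathing PSIR LGE: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous multi-slice free-breathing PSIR LGE: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smslge)
```

This vignette is the package's account of its science: what is modeled,
which knobs matter, what the synthetic world does and does not emulate,
and where the numerically delicate decisions sit.  No empirical claim is
made here that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. What is being simulated

Free-breathing motion-corrected LGE acquires, for every slice of a
short-axis stack, `N = 8` ECG-triggered single-shot bSSFP images over
two RR intervals each: one inversion-recovery (IR) shot and one
reference shot, so that a phase-sensitive (PSIR) reconstruction can
restore the sign of the inverted magnetization.  The repetitions are
taken under free breathing, co-registered and averaged.  A 16-slice
stack therefore costs `16 × 8 × 2 = 256` heartbeats.  Exciting slice
pairs simultaneously (multiband 2) halves this to 128.

The package reproduces this at desk scale on digital phantoms,
end to end: phantom → CAIPIRINHA/SMS encoding → interleaved
undersampling → GRAPPA → FOV partitioning → PSIR → center-of-mass
selection → non-rigid registration → averaging → metrics.

## 2. Signal model

Tissue contrast uses the ideal single-inversion closed form

$$ s(\mathrm{TI}) = M_0\,\bigl(1 - 2 e^{-\mathrm{TI}/T_1}\bigr), $$

with post-contrast defaults (1.5 T, synthetic choices): blood
`T1 = 350 ms`, healthy myocardium `450 ms`, scar `280 ms`; `M0` 1.0 /
0.85 / 1.0; background `M0 = 0`.  The default
`TI = 450·ln 2 ≈ 312 ms` nulls healthy myocardium, making scar the
brightest myocardial tissue — the LGE contrast mechanism.  Incomplete
recovery between inversions, readout-driven saturation, inflow and fat
are deliberately not modeled: the pipeline under test needs the
bright-scar/nulled-myocardium geometry, not quantitative relaxometry.
The PSIR reference shot is modeled as a proton-density-like image equal
to `M0` (the actual low-flip reference contrast is not specified by
free-breathing LGE protocols in a form we could copy; any positive
reference with the correct phase serves the sign-restoration role).

## 3. CAIPIRINHA encoding as an in-plane problem

Slice-specific RF phase cycling gives the two simultaneously excited
slices per-TR phase increments of `+π/2` and `−π/2`.  Only the
*relative* modulation matters for aliasing: the difference is `π` per
acquired phase-encode line, which by the Fourier shift theorem displaces
slice 2 by half the (doubled) phase FOV.  The package therefore encodes:
zero-pad both slice images into the `2×`-oversampled grid, circularly
shift slice 2 by `ny_ext/2`, multiply by each coil sensitivity, and take
a centered unitary 2D FFT.  The slice-separation problem becomes a
plain 1D in-plane acceleration problem at `R = 2N`, and separation after
reconstruction is an exact crop-and-shift (`partition_fov`).

The absolute increments matter only for the bSSFP frequency response and
live in the Bloch module (section 7).  Conventions fixed here: centered
FFT with DC at `floor(n/2)+1`; phase-encode lines counted 0-based from
the top of the extended FOV; the slice-2 shift sign is `+ny_ext/2`
(the half-period makes the sign unobservable); phase oversampling is
symmetric about the prescribed FOV; the oversampled line count is
rounded to an even integer (reference arm: `1.2 × 64 → 76`).

## 4. T-GRAPPA reconstruction

Repetition `r` samples lines `≡ r (mod R)`, so `R` consecutive
repetitions tile k-space.  Calibration merges the interleaves (most
recent repetition wins) into one full k-space; ridge-regularized least
squares fits, per gap offset, a kernel of 4 source lines × 5 readout
columns over all coils (`λ = 10⁻⁴` relative to the trace of the normal
matrix).  Missing lines are synthesized coil-by-coil; out-of-grid
sources read zero, and one virtual base line below the first sample lets
edge lines be synthesized too.

Numerical facts the tests pin down: with coil maps whose spectra fit
inside the kernel, the calibration residual reaches `< 10⁻⁶` (GRAPPA is
exact in that world); with the package's smooth Gaussian-lobe maps the
kernel is an approximation and the acceptance requirement is the
meaningful one — image-domain NRMSE `< 0.05` inside the object at
`R = 5` with 8 coils.  Calibration happens once per slice group; motion
between interleaves makes the merged calibration data slightly
inconsistent, which surfaces as mild ghosting in single shots.  We
accept and document this rather than guess vendor sliding-window
behavior.

## 5. Motion correction

* **Selection (8 → 6).**  Centers of mass are computed on magnitude
  images over the full frame.  The mean center over all 8 is refined by
  averaging its 4 nearest centers; the 6 images nearest the refined mean
  are kept.  Distances are Euclidean in pixels; ties break toward the
  lower repetition index.  The rule is brute-force re-implemented in the
  test suite as an independent oracle.
* **Registration.**  The retained images are registered onto the
  retained repetition whose center is closest to the refined mean (the
  most central breathing state; the protocol leaves the reference
  unspecified).  The algorithm is multi-resolution SSD demons: 3
  pyramid levels, classic demons force
  `u = diff·∇F/(|∇F|² + diff²)`, per-step cap 2 px, fluid smoothing
  `σ = 1` px, elastic smoothing `σ = 2` px, ≤ 50 iterations per level,
  fully deterministic.  The best field by SSD (including the zero
  field) is kept, so registration never increases SSD; non-convergence
  returns the best field with a flag rather than an error.
* **Averaging.**  The signed PSIR series is warped with the
  magnitude-derived fields and averaged.  Identical inputs short-circuit
  to an exact copy (floating-point summation would otherwise lose the
  last ulp).

A caveat the tests make explicit: on *static noisy* inputs an SSD-driven
non-rigid registration legitimately reduces SSD by fitting noise, and
warping with fractional displacements interpolates (hence slightly
smooths) the noise.  The final-image noise SD therefore sits at or
*below* the pure-averaging value `σ/√6`.  The averaging-statistics
oracle is tested on the selection-plus-averaging path
(`moco_average(..., register = FALSE)`); the registered path is bounded
above by the same statistics.

## 6. Metrics

* **Sharpness.**  For each pair of curve points on either side of the
  septal blood–myocardium interface, the signal profile from blood to
  myocardium is sampled at 0.1-px steps with bicubic interpolation
  (bilinear sampling measurably widens a 1-px edge: the 3 % oracle
  tolerance at `σ_b = 1` px is the reason cubic is used).  Per-profile
  sharpness is the reciprocal of the distance (mm) between the first
  80 % and first 20 % crossings of the profile's signal range; profiles
  with zero range or missing crossings are excluded.  For a
  Gaussian-blurred step edge the oracle is
  `1/(1.6832·σ_b·spacing)` from
  `Φ⁻¹(0.8) − Φ⁻¹(0.2) = 1.6832`.
* **Noise estimate.**  `Ne = sd(last − second-last retained warped
  image, within the blood ROI)/√(2·6)`: the 2 removes the doubled
  difference-image variance, the 6 accounts for the 6-image average.
  The ROI is defined on the image and applied to the difference.
* **CNRe.**  ROI-mean contrast divided by `Ne`, absolute by default.
* **Scar volume.**  Ground truth is exact mask arithmetic
  (`count × pixel area × thickness`).  Pipeline recovery segments
  within the myocardial annulus of the reference breathing state.  The
  conventional half-maximum (FWHM) mask is provided
  (`segment_scar_fwhm`), but on a registered-and-averaged image the
  residual blur pushes edge pixels below half-maximum and undercounts a
  ~180-px scar by 6–20 %.  Volume therefore uses
  `scar_area_fraction()`: intensities normalized by a robust plateau
  (median of pixels above 60 % of the regional maximum) and summed with
  an upper clamp — on a nulled background, blurring redistributes
  rather than destroys signal, so the normalized integral preserves
  area.  Scar-free slices are not searched, standing in for the reader
  knowing which slices enhance.  ROIs for CNRe are 2-px-eroded
  ground-truth masks (conservative "manual" ROIs).

## 7. bSSFP frequency response and the per-slice correction

The steady state is the fixed point of the per-TR Bloch recursion in the
frame locked to the RF phase, where the per-TR precession angle is the
effective `θ_eff = 2πf·TR − Δφ`.  The echo-time phase is also taken at
the effective frequency (receiver demodulation at the RF phase), which
makes the complex response a function of `θ_eff` alone — hence exactly
periodic in `1/TR` and exactly re-centered by the frequency-domain
correction

$$ \Delta f = \frac{\Delta\varphi - \pi}{2\pi\,\mathrm{TR}}
   \quad(\text{wrapped into one period}), $$

the package's representation of the slice-gradient correction: the
`±π/2` increments shift the passband by `∓1/(4TR)` (`∓92.25 Hz` at
`TR = 2.71 ms`), and evaluating the shifted response at `f + Δf`
reproduces the conventional alternating-RF (`Δφ = π`) response at
machine precision.  Translating the offset into a gradient moment would
require slice positions and is out of scope.  The solver is verified
against a 4000-TR time-domain iteration oracle at wrap-free frequencies
(the branch cut at `|θ_eff| = π` is a pure demodulation convention).

## 8. The synthetic world, and what a green test establishes

The phantom is an annulus-plus-disk cartoon: circular LV blood pool,
annular myocardium with slight apical taper, an angular scar sector,
seeded geometry jitter.  Motion is 2D in-plane translation (uniform in
`±1.5 px` per axis by default ≈ ±7 mm at the default 64-px/380-mm
scale) plus a low-frequency sinusoidal warp; two repetitions default to
deep-breath outliers at 4× the typical amplitude — the situation the
8 → 6 rule exists for.  Coils are 8 Gaussian lobes on a ring with
linear phase ramps and an amplitude floor that keeps the
root-sum-of-squares positive.  Noise is i.i.d. complex Gaussian in
k-space (`σ = 0.02` against a unit-scale object, single-shot blood SNR
of order 30; the unitary FFT maps it to image noise of the same σ).

Not emulated: anthropomorphic anatomy, right ventricle and papillary
muscles, through-plane motion, flow, fat, off-resonance within the
encoding, heart-rate variability, coil geometries of real arrays.  A
green end-to-end test therefore establishes the *algorithmic chain* —
encoding is invertible, calibration is consistent, selection discards
the planted outliers, registration converges, the estimators are
unbiased at the stated tolerances — on a favorable geometry; it does
not establish clinical image quality, and the cohort-level numbers of a
patient study (CNRe ≈ 25–31, sharpness ≈ 0.37 mm⁻¹) are not
reproducible from phantoms this simple, nor claimed.

## 9. Degenerate inputs and tie-breaks

All-zero images are rejected by `center_of_mass`; all-equal centers
retain the first `n_keep` repetitions; profiles without crossings are
excluded (an error only if all are); background phase (reference
magnitude below `10⁻³` of maximum) forces positive PSIR sign to avoid
salt-and-pepper signs in air; GRAPPA with `λ = 0` on singular normal
equations errors with advice rather than returning garbage; a single
coil at `R = 2` calibrates but flags `high_residual` (the physics is
underdetermined).  Every generator is a pure function of
`(config, seed)`; the paired experiment shares phantom, coils and
breathing trace across arms, and noise differs only through documented
arm-specific sub-seeds, so reports are byte-identical across reruns.

## 10. Known limitations

* GRAPPA quality at `R = 5` leans on 8 well-separated synthetic coils;
  fewer or flatter coils degrade gracefully (flagged, not fatal).
* The demons registration is SSD-based and will fit noise on static
  series (section 5); mutual-information or regularized B-spline
  registration is out of scope.
* T-GRAPPA calibration assumes the interleaved repetitions are
  motion-consistent; large inter-repetition motion leaves residual
  ghosting that the averaging suppresses but does not remove.
* The NIfTI writer covers the float32/float64 single-file subset this
  package needs; it is not a general NIfTI implementation.
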