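# smslge

Desk-scale simulation and reconstruction of **simultaneous multi-slice
(SMS) accelerated, free-breathing, motion-corrected late gadolinium
enhancement (LGE) cardiac MRI** with phase-sensitive inversion-recovery
(PSIR) reconstruction — on fully synthetic digital phantoms.

## The problem

LGE imaging is the clinical standard for myocardial scar: after a
gadolinium bolus, an inversion-recovery sequence with the inversion time
TI chosen to null healthy myocardium renders fibrotic scar bright.
Free-breathing protocols acquire N = 8 single-shot images per slice over
two RR intervals each (one IR shot, one reference shot for PSIR), then
motion-correct and average them.  Covering the ventricle with 16 slices
costs 256 heartbeats.  Exciting two slices at once (multiband 2) with
CAIPIRINHA RF phase cycling halves that to 128 heartbeats — if the two
slices can be disentangled.

This package implements the whole chain as testable components:

* **phantom** — seeded short-axis label-map phantoms (blood pool,
  myocardial annulus, scar sector), ideal IR contrast
  `s = M0 (1 - 2 e^(-TI/T1))`, respiratory motion traces with planted
  deep-breath outliers, smooth synthetic coil maps.
* **encode** — CAIPIRINHA as an in-plane problem: the phase FOV is
  doubled, slice 2's per-line phase modulation `exp(i*pi*m)` (the
  difference between the +pi/2 / −pi/2 per-TR increments of the two
  slices) shifts it by half the extended FOV, and the composite is
  undersampled with interleaved (T-GRAPPA) masks, `R = 2N` overall.
* **recon** — T-GRAPPA: merge the R interleaves into a full calibration
  k-space, fit ridge-regularized GRAPPA kernels, synthesize missing
  lines, combine coils, partition the extended FOV back into the two
  slices, and restore signal polarity with PSIR
  (`|IR| * sign(cos(arg IR - arg ref))`).
* **moco** — the 8 → 6 center-of-mass selection rule (refine the mean by
  its 4 closest points, keep the 6 closest images), multi-resolution
  demons registration onto the most central repetition, and averaging
  (magnitude-derived motion fields re-used for the PSIR series).
* **metrics** — myocardial sharpness index (reciprocal of the 80 %→20 %
  signal-drop distance along blood-to-myocardium profiles), the
  difference-image noise estimate `Ne = sd(a - b in blood ROI)/sqrt(2*6)`,
  CNR estimates, scar volume, protocol arithmetic.
* **bloch** — steady-state bSSFP frequency response under slice-specific
  RF phase cycling; the ±pi/2 increments shift the passband by
  ∓1/(4 TR) (±92.25 Hz at TR = 2.71 ms), and the equivalent per-slice
  frequency correction `(dphi - pi)/(2 pi TR)` re-centers it.

## Worked example

```r
library(smslge)
cfg <- experiment_config(list(phantom = list(n_slices = 2L,
                                             scar = list(slices = 1L))))
ex <- run_experiment(cfg)
print(ex)
```

```
lge_experiment (seed 1): 2 slices, scar truth 4.267 mL
  sms       heartbeats  16  accel 5.0 (nominal 2.50)  CNRe(b-m)  16.4  sharp 0.276 mm^-1  scar 4.091 mL
  reference heartbeats  32  accel 2.5 (nominal 2.50)  CNRe(b-m)  41.0  sharp 0.277 mm^-1  scar 4.158 mL
```

Both arms consumed the identical phantom and breathing trace.  The SMS
arm used half the heartbeats; both arms recovered the 4.267 mL
ground-truth scar within 5 % and agree with each other within 2 %.  The
CNRe gap reflects the parallel-imaging noise penalty of R = 5 vs R = 3
at this small coil array — on the emulated 16-slice clinical
prescription the counts are 128 vs 256 heartbeats at a matched nominal
in-plane acceleration of 2.5:

```r
str(protocol_counts(protocol_params())[1:3])
#> $ heartbeats           : int 128
#> $ accel_nominal_inplane: num 2.5
#> $ accel_total          : num 5
```

The bSSFP passband shift and its correction:

```r
r <- bssfp_response(list(T1 = 450, T2 = 45, TR = 2.71, TE = 1.15,
                         flip = 45, phase_increment = pi/2))
passband_center(r)        #> -92.25 Hz
gclola_offset(pi/2, 2.71) #> -92.25 Hz
```

## Command line

```sh
Rscript exec/smslge run --config inst/extdata/default_config.yaml --outdir out
Rscript exec/smslge bloch --outdir out
Rscript exec/smslge simulate --outdir out   # phantom + series as NIfTI
```

Outputs are NIfTI images (minimal built-in NIfTI-1 writer, readable by
nibabel and friends), JSON reports and CSV tables.

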