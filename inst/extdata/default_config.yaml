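# Default experiment configuration (YAML schema of experiment_config()).
# Any field may be omitted; omitted fields keep their package defaults.
# This file reproduces the built-in defaults for reference.

seed: 1

phantom:
  n_slices: 4            # desk-scale stack; the clinical prescription is 16
  matrix: [64, 64]       # (ny, nx); minimum 64 x 64
  pixel_spacing: [1.48, 1.98]   # mm (y, x)
  slice_thickness: 8     # mm, no gap
  r_blood: 0.22          # blood-pool radius, fraction of min(ny, nx)
  r_myo: 0.34            # epicardial radius
  taper: 0.2             # apical shrink across the stack
  scar:
    slices: [1, 2]       # 1-based slices carrying the scar sector
    theta: [-60, 10]     # angular sector in degrees
    transmural: 1.0      # fraction of wall depth from the endocardium

n_coils: 8
n_reps: 8                # single-shot repetitions per slice
rr_per_image: 2          # two-RR scheme: IR shot + PSIR reference shot
ti: 311.9                # ms; T1_myo * ln 2 nulls healthy myocardium
noise_sigma: 0.02        # complex noise SD per k-space sample and channel

motion:
  amplitude: 1.5         # px typical in-plane respiratory translation
  outlier_indices: [3, 6]   # repetitions forced to deep-breath states
  outlier_scale: 4
  deform_frac: 0.2       # smooth-warp amplitude relative to amplitude

arms:
  sms:                   # multiband 2, overall R 5, oversampling 2
    inplane_accel: 5
    phase_oversampling: 2
    multiband: 2
  reference:             # single band, R 3, oversampling 1.2 + crop
    inplane_accel: 3
    phase_oversampling: 1.2
    multiband: 1

grappa:
  kernel: [4, 5]         # source lines x source columns
  lambda: 1.0e-4         # ridge, relative to trace

moco:
  n_keep: 6              # retained repetitions (of n_reps)
  reg:
    levels: 3
    sigma_field: 2       # px, elastic regularization
    iterations: 50

roi_erosion: 2           # px; conservative stand-in for manual ROIs

sharpness:
  offset_px: 4           # curve distance from the blood-myo interface
  n_points: 9
  theta: [150, 210]      # septal sector in degrees
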