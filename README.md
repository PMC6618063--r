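# spiral4d

Retrospectively gated stack-of-spirals 4D flow MRI, from pulse-sequence
timing to intracardiac flow analysis, as a self-contained simulation and
processing package.

## The problem

4D flow MRI measures all three blood-velocity components in a volume,
time-resolved over the cardiac cycle, but whole-heart Cartesian protocols
take 15–40 minutes. Spiral k-space readouts traverse k-space far more
efficiently: with 10 spiral interleaves per slice-encode partition and 5 ms
readouts, a whole-heart protocol fits in 460–510 heartbeats instead of
1000+. Retrospective cardiac gating — acquiring continuously while
recording R-wave times, then sorting readouts onto a normalized average
cycle — covers the *entire* cycle, including the atrial-contraction
(A-wave) filling that prospective gating truncates and that matters for
ventricular inflow, E/A assessment, and diastole-to-systole pathline
analysis.

Validating such a sequence end to end needs ground truth no scanner can
give. `spiral4d` provides the whole chain in software:

1. **Sequence design** — slew- and amplitude-limited variable-density
   spiral interleaves under scanner gradient limits (33 mT/m, 180 T/m/s),
   plus the timing algebra: nominal temporal resolution
   `segmentation × 4 × TR`, nominal scan time
   `interleaves × slice encodes / segmentation` heartbeats.
2. **Synthetic phantom** — an analytic, *exactly divergence-free* pulsatile
   flow field in a U-bend channel (a chamber with inflow and outflow
   vessels) inside static tissue, with systolic ejection, biphasic E/A
   filling, beat-to-beat RR variability, respiratory motion and optional
   eddy-current-like background offsets.
3. **Acquisition simulation** — four-point velocity encoding
   (`φ = π v / venc` against a reference segment), non-uniform DFT sampling
   along the spiral, navigator respiratory gating (4 mm window in the
   central 25 % of slice encodes, 7 mm outside), complex Gaussian noise.
4. **Retrospective gating** — normalization of every beat onto the average
   cycle (systole kept constant, diastole stretched), binning into any
   number of frames (40 by default).
5. **Reconstruction** — Kaiser–Bessel convolution gridding with Pipe–Menon
   density compensation, deapodization, slice-direction DFT and
   slice-oversampling crop; phase-difference velocity maps.
6. **Corrections** — static-tissue detection by low temporal variance and
   subtraction of a fitted fourth-order (35-term) spatial polynomial per
   velocity component.
7. **Flow analysis** — plane flow rate/net volume/peaks, and four-component
   pathline decomposition (RK4, quadrilinear interpolation, 5 ms steps):
   direct flow, retained inflow, delayed ejection, residual volume, with
   the mass-conservation identities `inflow = direct + retained`,
   `outflow = direct + delayed` as quality control.
8. **Evaluation statistics** — least-squares regression `y = βx + α` with
   the F-test, and Bland–Altman bias ± 1.96 SD limits of agreement.

## Worked example

The full chain at a desk scale (64² matrix, 8 slices, 20 frames, ~100
accepted beats; runs in well under a minute):

```r
library(spiral4d)

par   <- sequence_params(matrix = 64, fov = 179.2, n_slices_recon = 8)
traj  <- design_spiral_interleaf(par)
spec  <- phantom_spec()              # 25 ml/cycle, RR 900 ± 50 ms
field <- make_phantom(spec)

rr <- sample_rr_intervals(spec$rr_mean, spec$rr_sd, 2000, seed = 1)
ks <- simulate_acquisition(field, traj, par, rr, seed = 2)
b  <- bin_samples(ks, gating_config(n_frames = 20,
                                    t_sys = spec$systolic_duration))
ser <- phase_difference_velocity(grid_reconstruct(b, traj))

inlet <- quantify_flow(ser, phantom_plane(field, ser, "inlet"))
print(inlet)
#> Plane flow: net volume 24.98 ml/cycle, peak 64.31 ml/s, peak velocity 0.727 m/s (20 frames)

masks <- phantom_masks(field, matrix = 64, voxel = 2.8, n_slices = 8)
segs  <- chamber_segmentations(masks$chamber, masks$chamber,
                               masks$inlet_mouth, masks$outlet_mouth,
                               ed_frame = 20, es_frame = 8)
comp <- pathline_decomposition(ser, segs)
print(comp)
#> Flow components (ml): direct 5.91, retained 6.1, delayed 6.08, residual 7.18
#>   inflow 12, outflow 12, discarded 20.7%
conservation_check(comp)$difference
#> 0.022 ml
```

The reconstructed net volume (24.98 ml) recovers the phantom's prescribed
25 ml per cycle; pathline inflow and outflow each capture the half-cycle
volume pushed through the rigid channel (12.5 ml) and agree with each other
to 0.02 ml — the mass-conservation check that makes pathline analysis a
sensitive quality probe of velocity data. The acquisition consumed 245
beats for 100 lines (navigator efficiency 0.41 under 10 mm peak-to-peak
breathing), illustrating the respiratory-gating cost the nominal scan time
excludes.

A one-shot driver with YAML configuration and a manifest is available as
`run_pipeline()`, and a thin command-line wrapper in
`inst/cli/flow4d.R` (`design | simulate | gate | recon | correct | flow |
pathlines | evaluate | run`-style subcommands).

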