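---
title: "Models and methods behind spiral4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spiral4d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spiral4d)
```

This vignette documents the models, parameter choices and numerical
decisions inside `spiral4d`, in the spirit of a methods section: what each
stage assumes, why the defaults are what they are, and what the synthetic
validation does and does not demonstrate about real data.

## Sequence model

A retrospectively cardiac-gated, four-point velocity-encoded
stack-of-spirals acquisition is modeled as follows. Each slice-encode
partition consists of `n_interleaves` rotated copies of one base spiral;
all interleaves of a partition are acquired before the next partition. One
k-space line (one interleaf at one slice encode) occupies a full heartbeat:
heart-phase slots advance every `n_flow_segments × TR` and within each slot
the reference segment and the three velocity-encoded segments are acquired
in successive TRs. The nominal temporal resolution is therefore
`segmentation_factor × 4 × TR` (48 ms at TR 12 ms) and the nominal scan
time `n_interleaves × n_encoded_slices / segmentation_factor` heartbeats
(460 for 36 slices and 510 for 40 slices at 27 % slice oversampling and 10
interleaves, with the oversampled slice count rounded to nearest).

The TR train runs continuously until the next R wave, so the final slot of
a beat may be partial. This detail matters: if acquisition stopped at the
last *complete* slot, the final ~50 ms of diastole would never be sampled
and the reconstruction would extrapolate the atrial-wave peak into the gap,
biasing net volumes upward by several percent. Simulating the partial slot
reproduces the scanner's behavior and removes the bias.

### Spiral design

The base interleaf is designed by numerically integrating the spiral
dynamics in the angle variable at one tenth of the gradient raster (1 µs
steps, classical RK4), choosing at each instant the largest angular
acceleration compatible with the slew limit and switching to a
constant-speed regime once the readout speed reaches the gradient-amplitude
limit. The radius law is `dr/dθ = n_interleaves · d(r) / (2π FOV)`, where
`d(r)` is a two-zone variable-density profile: Nyquist spacing out to
`core_fraction × kmax` (default 0.2), then a linear taper to an
undersampling factor `taper_to` at the edge (default 1, i.e. fully
sampled). The published protocol states only that a standard
variable-density spiral was used; the two-zone law is this package's
concrete choice and both parameters are exposed. A 0.995 safety factor on
both limits absorbs discretization error so that the sampled waveforms
satisfy the limits exactly. Design stops when the radius reaches
`kmax = 1/(2·voxel)`; if that happens after `readout_duration`, a typed
error is raised (the protocol's 5 ms limit is a hard off-resonance
constraint, not something to silently exceed).

## The flow phantom

The phantom is a rigid U-bend channel: two straight limbs along +y joined
by a half-torus bend in the x–y plane, embedded in an elliptic-cylinder
"body" of static tissue, in air. In the bend the velocity is purely
azimuthal, `v = u(s, z) ê_φ` with `s` the in-plane distance from the bend
axis; any such field has zero divergence identically, and the matched
Poiseuille-like limbs (quartic profile `(1 − (ρ/a)²)²`, continuous normal
velocity at the junction) keep the combined field exactly divergence-free.
This exactness is the point: pathline inflow/outflow conservation then
tests the *processing chain*, not the phantom. An ellipsoid-chamber
geometry was considered and rejected because no closed-form through-flow
field is exactly divergence-free on it; the bend region plays the chamber
role and its mouth plane carries the inlet/outlet labels.

The spatial field carries unit flux, so the waveform *is* the
instantaneous flux in ml/s: a raised-cosine systolic lobe over
`systolic_duration` (default 360 ms = 40 % of the 900 ms mean RR), an
E-wave lobe in early diastole and an A-wave lobe in the final
`a_wave_fraction` (default 15 %) of the cycle, with an E:A volume split of
70/30. Because the channel is rigid, flux is instantaneously equal
everywhere along it; the per-cycle volume is split evenly between systole
and diastole so that pathline inflow (diastolic entry) and outflow
(systolic exit) are both half the stroke volume — the conservation target.
Defaults: 25 ml/cycle (peak flux ~80 ml/s, peak speed 0.82 m/s, safely
under the 120 cm/s venc), lumen radius 9 mm, bend radius 40 mm, RR
900 ± 50 ms truncated at 3.5 SD, 10 mm peak-to-peak sinusoidal breathing
with a 4 s period, and complex k-space noise of 3 fluid-voxel units per
sample, which lands the reconstructed magnitude SNR in the tens, typical
of 1.5 T 4D flow.

Beat-to-beat variability warps the waveform exactly as the gating model
assumes (systole fixed, diastole stretched), so the phantom and the
retrospective sorter share their physiological model; mismatch between the
two is a real-data effect deliberately not simulated.

### What the phantom does not emulate

Rigid walls (no chamber compliance, so inflow and outflow are simultaneous
rather than phase-separated), no T1/T2 relaxation or fat signal, no
off-resonance or concomitant-gradient phase, no coil sensitivities or
parallel imaging, no intra-readout motion (each 2–5 ms readout sees a
frozen field), no turbulence or intravoxel dephasing. Passing the
end-to-end tests therefore demonstrates correctness of trajectory design,
sampling, gating, gridding, phase-difference processing, background
correction and pathline bookkeeping — not robustness to off-resonance
blurring or motion artifacts.

## Acquisition and navigator

Each readout's signal is the exact non-uniform DFT of
`m(r) · exp(iπ(v_d(r, t) + b_d(r))/venc)` over the voxel grid, evaluated
at the readout's center time, plus complex white Gaussian noise. The
navigator is evaluated once per beat; a rejected beat re-queues its line
immediately. "Central 25 % of k-space" is interpreted as the quarter of
slice-encode partitions with smallest |kz|: every spiral readout starts at
the in-plane center, so only the slice-encode direction distinguishes
center from periphery in a stack of spirals. Acquisition fails loudly if
the acceptance efficiency drops below a configurable floor (default 5 %).

## Retrospective gating

Times since the R wave map onto the average cycle by the
systole-constant/diastole-stretch rule; the systole/diastole boundary
`t_sys` is not published, so it defaults to 40 % of the mean RR and is
configurable in ms (the phantom's own systolic duration is the natural
choice in simulation). Two binning rules are provided. `nearest` assigns
each readout wholly to the frame bin containing its normalized time, with
complex averaging of duplicates. With 48 ms slots and 20–40 frames this
warps the effective time axis (some field times counted twice, others
dropped) and measurably biases time-integrated quantities — about +6 % on
net volume in the default conditions. The default rule `linear` therefore
distributes each readout between the two nearest frame centers with
inverse-distance weights, which is what "combining the acquired cycles
into an arbitrary number of fully sampled datasets" requires in practice;
it reduces the net-volume bias to well under 1 %. Bins that still receive
no data are completed per line by linear interpolation between the nearest
filled frames (cyclically); `nearest`-copy and `none` are available. The
raw (pre-completion) fill fraction is always reported. Note that at 40
frames the raw fill fraction is necessarily ~0.45, not ~1: each line is
sampled every 48 ms, i.e. ~19 times per 900 ms cycle, so 40 frames
oversample the acquired temporal grid about two-fold and roughly half the
bins are interpolated by construction.

## Reconstruction

Standard convolution gridding per frame, segment and slice encode:
Kaiser–Bessel kernel (width 4 grid cells, Beatty β), 1.5× oversampled
grid, density compensation by Pipe–Menon iteration (25 iterations of
`w ← w / (A A^T w)` with the gridding operator `A`, then rescaling by the
kernel-autocorrelation integral so the weights are physical k-space area
elements; analytic `|k| d|k|` annulus weights are the `radial`
alternative), centered FFT, deapodization by the closed-form kernel
transform, voxel-area scaling, explicit inverse DFT along the slice
encodes and cropping of the oversampled slices. The half-voxel offset of
the voxel-center convention is folded into the sample phases before
gridding. The acquired slice-encode count is parity-matched to the
reconstructed slice count so the crop lands on coincident voxel centers.
For Cartesian trajectories the same interface dispatches to an exact
inverse DFT. Velocities come from
`v_d = venc · arg(S_d S_ref*) / π`; no phase unwrapping is attempted
(phantoms are designed below venc) and out-of-range velocities simply wrap.

The gridded reconstruction is validated against a direct (matrix) DFT
evaluation of the same density-compensated adjoint, not against a
pseudo-inverse: with a disk-limited spiral the corner spatial frequencies
are unconstrained and a least-squares inversion is ill-posed, whereas the
direct summation isolates exactly the interpolation error gridding
introduces (NRMSE ≈ 3 % on 32² grids, dominated by FOV-edge
deapodization). A note on the point-spread sanity check: disk-limited
coverage has a jinc point spread whose first ring is 13 % of the peak, so
peak-to-sidelobe ratios above ~7.6 are unattainable without windowing; the
test asserts > 5.

## Background correction

Static tissue is detected as voxels with time-averaged magnitude at or
above 10 % of the maximum whose temporal speed SD falls at or below the
25th percentile of above-floor voxels (both thresholds configurable; the
published method says only "low temporal variance", and speed SD was
chosen over per-component or magnitude variance as the most direct motion
surrogate). One degree-4 polynomial per velocity component — all 35
monomials with total degree ≤ 4, coordinates normalized to [−1, 1] for
conditioning — is fitted by OLS to the *time-averaged* velocity of masked
voxels and subtracted from every frame: eddy-current offsets are modeled
as time-invariant, matching a single-subtraction correction. Rank
deficiency (fewer than 35 usable voxels, or voxels confined to too few
planes — degree 4 in z needs at least five distinct slices) raises a typed
error rather than a silent pseudo-inverse.

## Pathline analysis

Classical RK4 with quadrilinear (trilinear × linear-in-time, cyclic)
interpolation and a 5 ms step, forward from end diastole (t = 0, the R
wave) through systole to end systole, and backward from end diastole
through diastole to the previous end systole using cycle periodicity.
Seeds sit at every end-diastolic chamber voxel center (configurable k³
subdivision), each carrying voxel volume / seeds-per-voxel. A chamber
boundary crossing is labeled by the nearest voxel of the labeled inlet or
outlet region; if neither is within 1.5 voxel diagonals the crossing
counts as myocardium and the pathline is discarded. Positions leaving the
volume see zero velocity and are flagged, never raised. The four
components follow from (entered through inlet) × (left through outlet),
and the bookkeeping identity
`direct + retained + delayed + residual + discarded = seeded volume`
closes to floating-point precision by construction. Peak velocity in plane
quantification is the through-plane component maximum (the clinical
venc-direction convention), not the speed maximum.

## Problem sizes and verification scale

The package's own verification runs at deliberately desk-sized versions of
the protocol: unit tests use a 32² matrix with 4–6 slices and 6
interleaves; the end-to-end checks use a 64² matrix, 8 slices, 10
interleaves and 20 frames (about 250 simulated beats), where the full
chain recovers the ground-truth velocity field with a fluid-region RMSE
under 5 % of peak speed and the prescribed stroke volume within 3 %; the
pathline conservation ensemble uses eight rasterized phantoms with stroke
volumes 18–32 ml and 0.02 m/s velocity noise, on which the
inflow-vs-outflow regression slope stays within [0.95, 1.05]. The
full-protocol geometry (100² × 36–40 slices, 40 frames) runs through the
identical code paths and is exercised for trajectory design and timing,
where it reproduces the published protocol numbers exactly.

## Known limitations

Gridding accuracy is reported against the direct adjoint, not against a
regularized inverse NUFFT; no SENSE/parallel imaging, off-resonance
correction, or concomitant-field correction is implemented (the latter two
are scanner-side or unnecessary at these readout lengths); the Cartesian
acquisition path is a fully sampled reference reconstruction, not a
SENSE-2 simulation; the phantom's rigid geometry makes end-diastolic and
end-systolic segmentations identical, so segmentation-misregistration
effects on the flow components are not represented; and HDF5 container
interchange is replaced by R-native RDS plus NIfTI/CSV/JSON, which
round-trip losslessly within R but require conversion for Python tooling.
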