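---
title: "Simulating and analysing triaxial OPM-MEG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing triaxial OPM-MEG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`opmsim` models a wearable magnetoencephalography (MEG) system built from
64 triaxial optically pumped magnetometers (OPMs, 192 channels), and
implements the analysis chain such systems are validated with: phantom
(known-source) protocols, preprocessing, scalar LCMV beamforming with
pseudo-T/pseudo-Z imaging and virtual electrodes, and Hilbert-envelope
time-frequency analysis. Everything runs on synthetic data; every
simulator emits its ground truth so each analysis stage can be checked
against an oracle.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical choices, in that order.

## Forward models

**Phantom coil.** The phantom is a single-turn isosceles triangular coil
(5 mm base, 45 mm height, area $1.125\times 10^{-4}\,\mathrm{m}^2$)
driven with a 17 Hz sinusoidal current. Its field is computed with the
exact finite-segment Biot–Savart formula for the closed three-segment
polyline; the implementation is validated against adaptive discretisation
of the line integral (relative error $<10^{-8}$) and against the
point-dipole approximation $m = IA$ at ten coil extents (within 2%).
`place_phantom_coil()` mounts the coil the way the physical device is
mounted: in an empty sensor slot of the helmet, normal along the local
radial direction, centroid 45 mm radially inward of the slot sensor. With
a 1 mA drive this produces ~213 pT at the best-coupled channel, matching
the 20–200 pT operating range of the protocols over 0.01–1 mA.

**Neural sources.** Brain sources are current dipoles in a homogeneous
conducting sphere (Sarvas closed form, volume currents included). The
sphere (default: origin-centred, radius 9 cm) is the minimal standard MEG
volume conductor; no realistic cortical geometry is attempted, so
simulated localisation accuracy should be read as a best case for the
array geometry and noise level, not as a claim about anatomical accuracy.
Radial moments are externally silent in a sphere, which is why lead
fields and the beamformer work in the two-dimensional tangential moment
space. The tangential basis at each voxel is built by Gram–Schmidt from
the +z axis, falling back to +x within ~1° of the pole.

**Helmet.** `build_synthetic_helmet()` places sensors on an equal-area
(Fibonacci) lattice over a spherical cap of radius
`head_radius + standoff` (defaults 9 cm + 1.5 cm) extending 120° from the
vertex, one radial and two tangential axes per sensor. The seed only
rotates the lattice azimuthally, so helmets are reproducible and
differently seeded helmets are statistically equivalent. The default
64-sensor lattice keeps sensors ≥ 3.5 cm apart.

## Sensor model

Each triaxial sensor converts the true field at its cell into measured
outputs per operating mode:

* **Open loop.** The zero-field resonance gives a Lorentzian gain
  $G(|B|) = \gamma^2/(\gamma^2 + |B|^2)$ in the quasi-static field
  magnitude, applied to all three axes; $|B|$ is estimated by low-passing
  the field magnitude at 1 Hz (`dc_cutoff`), separating the slow
  background from MEG-band signal. Cross-axis projection error (CAPE) is
  modelled as a bilinear leakage of the two orthogonal background
  components, $\mathrm{cape} \cdot B_{b,y}B_{b,z}/\gamma$ onto the x
  axis (cyclically for y, z). Outputs beyond the ±1.5 nT dynamic range
  are clamped and flagged *railed* (a data flag, not an error, so
  downstream segment accounting still works).
* **Closed loop.** On-board coils null the cell field; under the ideal
  loop (default, `loop_bandwidth = Inf`) the output equals the true
  field exactly for fields within the ±50 nT coil range, beyond which
  samples are flagged out-of-range. A finite loop bandwidth applies a
  single-pole tracking model and passes the residual through the
  open-loop transfer.

The resonance half-width $\gamma$ (default 10 nT) and the CAPE
coefficient (default 0.1) are *placeholders with the right orders of
magnitude*: the physical values for commercial sensors are not public.
Consequently the package treats open-loop degradation only qualitatively
(monotone amplitude loss with background field, errors growing with the
swept range) and never asserts a specific open-loop percent error.
Closed-loop behaviour, by contrast, is parameter-free under the ideal
loop and is tested quantitatively.

Sensor noise is white with density 15 fT/√Hz (per-sample sd
`noise_density * sqrt(sample_rate/2)`), the band-median figure for
triaxial OPMs; no 1/f shoulder is modelled, so low-frequency artefact
rejection is exercised only by the simulated background excursions, not
by realistic drift.

## Synthetic sessions

**Visuo-motor paradigm.** 60 "circles" trials (1 s stimulus), 120
"faces" (0.5 s), 25 "catch" (0.8 s), pseudo-randomised, each followed by
a rest of 1.25 ± 0.2 s (uniform jitter; the distribution is a modelling
choice — only mean ± half-width are specified by the paradigm). Catch
trials are given the same jittered rest as the other trial types, which
reproduces the expected 396 s total session duration. Default sources:
left-sensorimotor beta (13–30 Hz) desynchronisation tied to catch
trials, a primary-visual 52–65 Hz synchronisation tied to circles, and a
fusiform evoked response peaking 0.17 s after face onset.

Oscillatory sources are band-passed Gaussian noise with a multiplicative
envelope (raised-cosine 0.1 s ramps; `erd`: 1 → 1−depth in the effect
window; `ers`: 1 → 1+depth). Evoked sources are Gaussian-windowed
cosines (σ = 40 ms, 10 Hz) peaking at the configured latency. These are
the minimal processes with the assumed spectral structure; they do not
model trial-to-trial latency jitter, 1/f brain noise, or correlated
background brain activity, so beamformer tests here probe geometry and
sensor noise, not physiological confounds. Baseline moments default to
10 nAm, a typical scale for focal cortical responses; at the default
geometry this yields ~1.6 pT at the best-coupled channel, i.e.
band-limited amplitude SNR of roughly 3–6 depending on band.

**Phantom protocols.** `linearity`: 8 drive amplitudes
(0.01–1 mA) × 8 repeats = 64 bursts; the 9-value amplitude list printed
for the hardware protocol is reconciled with its own "8 values × 8
repeats = 64" count by dropping 0.08 mA (configurable).
`background_sweep`: 1 mA drive, 81 background levels from 0 to 8 nT in
0.1 nT steps × 5 bursts = 405 bursts, background uniform and vertical.
(81 levels, 0.0–8.0 inclusive, is the reading of "stepped from 0 to
8 nT in 0.1 nT steps" consistent with 405 = 81 × 5.) Each burst is 2 s
of drive — exactly 34 cycles of 17 Hz, an integer DFT bin — followed by
1 s at zero current.

**Sitting-to-standing.** 8 s trials cued by alternating stand/sit
triggers; bilateral sensorimotor beta sources desynchronise during the
0–4 s movement window while a smooth 2 nT background excursion
(raised-cosine up 1 s / hold 2 s / down 1 s) is applied along a
per-sensor random direction, drawn once per session. The per-sensor
directions stand in for the unknown field gradients a moving helmet
sweeps through; they are not a model of rigid head motion. 2 nT exceeds
the ±1.5 nT open-loop dynamic range, so open-loop runs rail on many
channels while closed-loop runs do not — the behaviour the protocol is
designed to show. The default of 20 trials keeps a simulated session
near 3 minutes.

## Preprocessing

Bad channels are flagged by band-averaged (3–100 Hz) noise density
exceeding the channel median by 5 scaled MADs, or falling below a dead
floor (10⁻¹⁶ T/√Hz); bad trials by maximum absolute amplitude exceeding
the trial median by 6 scaled MADs. The thresholds replace the visual
inspection a human operator would do; they are declared defaults, not
values inferred from data, and the null false-positive rates (≤1% of
channels, ≤2% of trials) are pinned by Monte-Carlo tests.

Filters are zero-phase forward–backward Butterworth IIR: a 4th-order
1–150 Hz band-pass and 2nd-order notches (±2 Hz) at 50/100/150 Hz.
Homogeneous field correction (HFC) projects out the three spatially
uniform field components: with N the 192 × 3 orientation matrix,
$P = I - N(N^\top N)^{-1}N^\top$; P is symmetric, idempotent, exactly
annihilates uniform fields, and removes only ~0.1% of a central dipolar
topography on the default helmet. Gradient terms are deliberately not
included. Epoch windows are half-open `[t0, t1)` with floor rounding,
stated once and used everywhere.

## Beamforming

Covariance is estimated from band-passed, concatenated trials and
regularised by diagonal loading with 1% of its largest eigenvalue. Per
voxel the source orientation maximising output power is the
smallest-eigenvalue eigenvector of the 2 × 2 matrix
$L^\top C^{-1} L$ over the two tangential lead fields, and the weight is
the unit-gain LCMV solution $w = C^{-1}l/(l^\top C^{-1}l)$.

Two normalisations were genuinely open choices:

* **pseudo-T** = $(P_a - P_c)/(P_a + P_c)$ over active/control windows.
  This bounded, noise-estimator-free form was chosen because it needs no
  separate noise covariance and is comparable across runs; it is
  antisymmetric under window swap by construction.
* **pseudo-Z** = trial-averaged beamformed amplitude at a latency,
  normalised by the projected noise sd under a scaled-identity noise
  model, $\sigma^2 = \mathrm{reg\_fraction}\cdot\lambda_{max}$. Under
  pure noise with ~100+ trials its null 95th percentile sits below 3,
  which is what the null test pins.

Weights are computed once per band/window definition and reused for
images and virtual electrodes. Virtual-electrode sign is fixed by the
unit-gain constraint. Localisation tests place the source on a grid
voxel; at band SNR ≥ 5 the peak voxel matches to within one 4 mm grid
step in ≥ 95% of seeds, and disjoint-seed repeats agree to ≤ 8 mm with
trial-averaged envelope correlations ≥ 0.9 — the synthetic analogue of
between-run repeatability tables for a real system.

## Spectral analysis

Envelopes are magnitudes of the FFT-based analytic signal after
zero-phase band-passing, with 0.25 s reflection padding to limit edge
artefacts (edges are excluded from assertions). The time-frequency
spectrogram uses overlapping 5-Hz bands stepped by 2.5 Hz spanning
1–150 Hz (clipped at Nyquist); band widths are a configurable choice —
only "overlapping bands" is inherent to the method. Baseline correction
is relative *amplitude* change against the control-window mean,
$(E(t)-\bar E_c)/\bar E_c$; bands with zero control power are marked
invalid rather than infinite. A raw 60-trial null TFS has pointwise sd
≈ 0.52/√60 ≈ 0.07, so pointwise null values of ±0.2 are expected at the
extremes; the package applies no hidden smoothing, and an optional
moving-average smoother (`smooth`, seconds) is exposed on
`hilbert_envelope()` for timecourse comparisons.

## Phantom analysis

Burst amplitudes are exact-bin DFT magnitudes at 17 Hz with the 2/N
scaling (a pure sinusoid of amplitude A reports A; the convention is
recorded in the output so tables are comparable across sample rates).
Linearity is summarised by least squares of closed-loop against
open-loop amplitudes. Background error statistics subtract each
channel's mean zero-background amplitude and pool the *absolute* percent
deviations (a signed option exists) over the 10 best-coupled channels —
selected once from zero-background amplitudes — and all nonzero levels.
Pooling across levels (rather than averaging per level first) is the
chosen reading of "all the measurements"; at the default noise level the
ideal closed loop yields mean errors of ~0.01%, comfortably inside the
0.5% figure reported for real closed-loop hardware, because the only
error source is the sensor noise floor.

## Problem sizes and determinism

The shipped tests run the full protocol counts where those are the point
(64 and 405 bursts on the 192-channel array) and deliberately reduced
problems elsewhere: localisation properties use 25-trial sessions and a
4 mm region-of-interest grid around the seeded source (the beamformer
scan is linear in voxels, so a whole-sphere grid changes cost, not
correctness); Monte-Carlo nulls use 16-sensor arrays. All randomness
flows through explicit integer seeds; identical seeds give bit-identical
recordings, schedules, and pipeline artefacts.

## Known limitations

* Spherical conductor and point dipoles only; no anatomy, no
  co-registration error model.
* Open-loop constants (γ, CAPE coefficient) are plausible placeholders,
  so open-loop *percentages* are not comparable to hardware figures.
* White sensor noise only; no 1/f, no cross-sensor noise correlation, no
  gain drift or calibration error.
* Background excursions are per-sensor random directions, not a rigid
  motion model; movement artefact (as opposed to operating range) is not
  simulated.
* The ideal closed loop is noiseless feedback; real loops add loop noise
  and finite bandwidth (the single-pole option models only the latter).
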