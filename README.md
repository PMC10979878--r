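# opmsim

Simulation and source analysis for triaxial OPM-MEG arrays.

Optically pumped magnetometers (OPMs) make wearable magnetoencephalography
(MEG) possible, but the sensors only respond linearly in a narrow field
window (about ±1.5 nT). Background fields — and any head movement through
a static field — push open-loop sensors out of that window, suppressing
gain and leaking orthogonal field components into the measured axis
(cross-axis projection error). Closed-loop operation nulls the field at
each vapour cell with on-board coils, extending the usable range to the
±50 nT coil limit. Validating such a system hinges on phantom
experiments with known sources and on source-level analyses (beamformer
images, virtual electrodes, envelope spectrograms) that must be
reproducible run to run.

`opmsim` provides that whole chain as a tested R package, end to end on
synthetic data:

* **Forward models** — exact Biot–Savart fields of a triangular phantom
  coil; current dipoles in a homogeneous conducting sphere (Sarvas
  formula); uniform background fields; lead fields for a 64-sensor
  (192-channel) triaxial helmet.
* **Sensor model** — open-loop Lorentzian gain suppression
  `G(|B|) = γ²/(γ²+|B|²)`, cross-axis projection error, ±1.5 nT dynamic
  range with railing flags, ideal (or finite-bandwidth) closed loop with
  a ±50 nT coil range, and 15 fT/√Hz white sensor noise.
* **Session generators** — a pseudo-randomised visuo-motor paradigm
  (60/120/25 trials, jittered rests, ~396 s), phantom linearity
  (8 amplitudes × 8 repeats) and background-sweep (81 levels 0–8 nT × 5
  bursts) protocols with 17 Hz, 2 s drive bursts, and an 8 s-trial
  sitting-to-standing task with ~2 nT movement excursions. Ground truth
  is emitted with every recording.
* **Analysis** — bad-channel/trial rejection, zero-phase notch and
  1–150 Hz band-pass filters, homogeneous field correction, scalar LCMV
  beamforming (1% diagonal loading, tangential orientation
  optimisation), pseudo-T and pseudo-Z images on a 4 mm grid, virtual
  electrodes, Hilbert-envelope time-frequency spectrograms, and phantom
  linearity / background-error statistics.

## Worked example: does closed-loop operation change the measurement?

Simulate the phantom linearity protocol (zero background field) in both
operating modes, extract the 17 Hz amplitude of every burst on every
channel, and regress closed-loop against open-loop measurements; then
run the 0–8 nT background sweep in closed-loop mode and summarise the
error relative to the zero-background amplitude:

```r
library(opmsim)

helmet   <- build_synthetic_helmet(n_sensors = 64, head_radius = 0.09,
                                   standoff = 0.015, seed = 1)
open_p   <- sensor_model_params(loop_mode = "open")
closed_p <- sensor_model_params(loop_mode = "closed")

rec_open   <- simulate_phantom_protocol(helmet, "linearity", open_p,   seed = 1)
rec_closed <- simulate_phantom_protocol(helmet, "linearity", closed_p, seed = 2)
rec_open
#> <opm_recording> 192 ch x 72000 samples (192.0 s @ 375 Hz), 64 triggers

fit <- linearity_comparison(extract_burst_amplitudes(rec_open),
                            extract_burst_amplitudes(rec_closed))
cat(sprintf("slope = %.4f, intercept = %.2f fT, R^2 = %.6f\n",
            fit$slope, fit$intercept * 1e15, fit$r_squared))
#> slope = 1.0001, intercept = -0.06 fT, R^2 = 0.999999

rec_sweep <- simulate_phantom_protocol(helmet, "background_sweep",
                                       closed_p, seed = 3)
st <- background_error_stats(extract_burst_amplitudes(rec_sweep), top_k = 10)
cat(sprintf("closed-loop sweep error: %.3f +/- %.3f %% over %d channels\n",
            st$mean_percent, st$sd_percent, length(st$channels)))
#> closed-loop sweep error: 0.011 +/- 0.009 % over 10 channels
```

Read-out: in zero background the two modes measure the same fields (unit
slope, femtotesla intercept), and under the ideal closed loop the 17 Hz
phantom amplitude is immune to backgrounds up to 8 nT — the residual
~0.01% error is just the sensor noise floor at the DFT bin. Re-running
the sweep in open-loop mode instead shows amplitudes collapsing with
increasing background (gain suppression plus railing beyond ±1.5 nT).

Neural-session analyses follow the same pattern; see the vignette
(`vignettes/opm-simulation-methods.Rmd`) and `run_pipeline()` with the
bundled configs under `inst/extdata/configs/` for full
simulate → preprocess → beamform → spectrogram runs.

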