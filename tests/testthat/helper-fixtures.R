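# Shared fixtures and small oracles. Everything is generated in code; the
# cache avoids rebuilding helmets and lead fields across tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_helmet <- function() cached("helmet64", build_synthetic_helmet(64))

small_helmet <- function() cached("helmet16", build_synthetic_helmet(16))

default_sphere <- function() conductor_sphere(c(0, 0, 0), 0.09)

# Canonical left-sensorimotor test source position (on a 4-mm lattice).
MOTOR_POS <- c(-0.04, 0.01, 0.055)

motor_grid <- function() cached("motor_grid",
  make_source_grid(default_sphere(), 0.004, centre = MOTOR_POS,
                   half_width = 0.012))

motor_leadfields <- function() cached("motor_lf",
  build_lead_fields(default_helmet(), motor_grid(), default_sphere()))

# Exact-bin 17-Hz amplitude of a vector (oracle for burst extraction).
amp17 <- function(x, fs = 375) {
  N <- length(x)
  k <- round(17 * N / fs)
  (2 / N) * Mod(sum(x * exp(-2i * pi * k * (seq_len(N) - 1) / N)))
}

# Band-pass a whole recording in place (used to prepare band-limited
# epochs the way the analysis pipeline does).
bandpass_recording <- function(rec, band) {
  rec$data <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(signal::butter(4, band / (rec$sample_rate / 2),
                                    type = "pass"), x)))
  rec
}

# One beta-ERD localisation run on the default helmet: simulate a
# catch-trial session, beamform on the motor ROI grid, return the image,
# peak and (optionally) the trial-averaged beta envelope at the peak.
beta_localisation_run <- function(seed, n_catch = 25, amplitude = 20e-9,
                                  with_envelope = FALSE,
                                  modulation_depth = 0.5) {
  sched <- make_visuomotor_schedule(seed = seed, n_circles = 0,
                                    n_faces = 0, n_catch = n_catch)
  src <- list(beta = source_spec(
    current_dipole(MOTOR_POS, c(0, 1, 0)), effect = "erd",
    trial_type = "catch", band = c(13, 30),
    baseline_amplitude = amplitude, modulation_depth = modulation_depth,
    effect_window = c(-0.3, 0.5)))
  rec <- simulate_visuomotor_session(default_helmet(), sched, src,
                                     sensor_model_params(loop_mode = "closed"),
                                     seed = seed)
  rec <- bandpass_recording(rec, c(13, 30))
  ep <- segment_trials(rec, 3L, c(-0.3, 1.7))
  ep$band <- c(13, 30)
  model <- lcmv_weights(compute_covariance(ep), motor_leadfields())
  img <- pseudo_t_image(ep, model, active = c(-0.3, 0.3),
                        control = c(0.8, 1.4))
  pk <- peak_voxel(img, "min")
  out <- list(image = img, peak = pk,
              error_mm = 1000 * sqrt(sum((pk$position - MOTOR_POS)^2)))
  if (with_envelope) {
    ve <- virtual_electrode(ep, model, pk$position)
    out$envelope <- hilbert_envelope(ve, c(13, 30), smooth = 0.2)$envelope
  }
  out
}

# Minimal virtual-electrode object for spectral tests.
make_ve <- function(timecourse, fs, t0 = 0) {
  tc <- if (is.matrix(timecourse)) timecourse else matrix(timecourse, 1)
  structure(list(timecourse = tc, average = colMeans(tc),
                 times = t0 + (seq_len(ncol(tc)) - 1) / fs,
                 voxel = c(0, 0, 0), voxel_index = 1L, band = NULL,
                 sample_rate = fs),
            class = "virtual_electrode")
}

# Band-limited Gaussian trials (trials x samples) with a multiplicative
# envelope profile shared across trials.
band_noise_trials <- function(n_trials, n_samples, fs, band, envelope = 1,
                              seed = 1) {
  set.seed(seed)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  t(vapply(seq_len(n_trials), function(i) {
    x <- signal::filtfilt(bf, stats::rnorm(n_samples + 2 * fs))
    x <- x[fs + seq_len(n_samples)]
    (x / stats::sd(x)) * envelope
  }, numeric(n_samples)))
}
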