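# Synthetic-session generators: trial schedules and end-to-end recordings
# for the visuo-motor paradigm, the phantom protocols, and the
# sitting-to-standing task. Every generator emits ground truth alongside
# the recording so downstream stages always have an oracle.

TRIGGER_CODES <- c(circles = 1L, faces = 2L, catch = 3L,
                   stand = 4L, sit = 5L, phantom_on = 6L)

#' Generate the pseudo-randomised visuo-motor trial schedule
#'
#' Default counts and timings follow the reference paradigm: 60 circles
#' trials (1 s stimulus), 120 faces trials (0.5 s) and 25 catch trials
#' (0.8 s), each followed by a rest period of 1.25 s jittered uniformly by
#' +/- `jitter` seconds, in pseudo-random order. With the defaults the
#' expected total duration is 396.25 s.
#'
#' @param seed Integer seed; the schedule is exactly reproducible per seed.
#' @param n_circles,n_faces,n_catch Trial counts.
#' @param rest_mean Mean rest duration, seconds (default 1.25).
#' @param jitter Half-width of the uniform rest jitter, seconds
#'   (default 0.2; 0 disables jitter).
#' @return Object of class `trial_schedule`: data frame `events` with
#'   columns `onset`, `trial_type`, `stim_duration`, `rest_duration`,
#'   `trigger_code`, plus `total_duration` (end time of the last event).
#' @export
make_visuomotor_schedule <- function(seed = 1, n_circles = 60,
                                     n_faces = 120, n_catch = 25,
                                     rest_mean = 1.25, jitter = 0.2) {
  set.seed(derive_seed(seed, 11L))
  types <- sample(c(rep("circles", n_circles), rep("faces", n_faces),
                    rep("catch", n_catch)))
  stim <- c(circles = 1, faces = 0.5, catch = 0.8)[types]
  rest <- rest_mean + stats::runif(length(types), -jitter, jitter)
  onset <- cumsum(c(0, (stim + rest)[-length(types)]))
  ev <- data.frame(onset = onset, trial_type = types,
                   stim_duration = unname(stim), rest_duration = rest,
                   trigger_code = TRIGGER_CODES[types], row.names = NULL)
  structure(list(events = ev,
                 total_duration = sum(stim + rest), seed = seed),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d events, %.2f s total\n",
              nrow(x$events), x$total_duration))
  print(table(x$events$trial_type))
  invisible(x)
}

#' Current dipole source
#'
#' @param position 3-vector, metres (must lie inside the conductor sphere
#'   used for simulation).
#' @param moment Moment direction, 3-vector (scaled internally by the
#'   source amplitude; only the tangential part radiates in a sphere).
#' @return Object of class `current_dipole`.
#' @export
current_dipole <- function(position, moment) {
  structure(list(position = as.numeric(position),
                 moment = as.numeric(moment)),
            class = "current_dipole")
}

#' Specify a simulated neural source
#'
#' Oscillatory sources are band-limited Gaussian processes whose envelope
#' is modulated around trials of `trial_type`; evoked sources are
#' deterministic damped oscillations peaking `evoked_latency` seconds after
#' each trigger.
#'
#' @param dipole A [current_dipole()].
#' @param effect "erd" (amplitude drop in the effect window), "ers"
#'   (amplitude increase) or "evoked".
#' @param trial_type Trial type whose triggers drive the modulation
#'   ("circles", "faces", "catch", "stand", "sit").
#' @param band Length-2 Hz interval of the oscillatory carrier (within
#'   1-150 Hz); ignored for evoked sources.
#' @param baseline_amplitude Source strength, ampere-metres: RMS moment of
#'   the baseline oscillation, or peak moment of the evoked wavelet.
#' @param modulation_depth Fractional amplitude change in the effect window
#'   (0..1).
#' @param effect_window Length-2 seconds interval relative to the trigger.
#' @param evoked_latency Evoked peak latency, seconds after the trigger.
#' @param evoked_freq,evoked_sigma Carrier frequency (Hz) and Gaussian
#'   width (s) of the evoked wavelet.
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(dipole, effect = c("erd", "ers", "evoked"),
                        trial_type, band = c(13, 30),
                        baseline_amplitude = 10e-9,
                        modulation_depth = 0.5,
                        effect_window = c(0, 0.6),
                        evoked_latency = 0.17,
                        evoked_freq = 10, evoked_sigma = 0.04) {
  effect <- match.arg(effect)
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must be in [0, 1]")
  if (effect != "evoked" && (band[1] < 1 || band[2] > 150))
    stop("band must lie within [1, 150] Hz")
  structure(list(dipole = dipole, effect = effect, trial_type = trial_type,
                 band = band, baseline_amplitude = baseline_amplitude,
                 modulation_depth = modulation_depth,
                 effect_window = effect_window,
                 evoked_latency = evoked_latency,
                 evoked_freq = evoked_freq, evoked_sigma = evoked_sigma),
            class = "source_spec")
}

#' Default visuo-motor source set
#'
#' Three canonical sources: a left-sensorimotor beta (13-30 Hz) ERD tied to
#' catch trials, a primary-visual 52-65 Hz ERS tied to circles trials, and
#' a right-fusiform evoked response (peak 0.17 s) tied to faces trials.
#' Amplitudes default to 10 nAm, a typical scale for focal cortical
#' responses.
#'
#' @param amplitude Baseline amplitude for all three sources, ampere-metres.
#' @return List of [source_spec()] objects.
#' @export
default_visuomotor_sources <- function(amplitude = 10e-9) {
  list(
    beta_motor = source_spec(
      current_dipole(c(-0.04, 0.01, 0.055), c(0, 1, 0)),
      effect = "erd", trial_type = "catch", band = c(13, 30),
      baseline_amplitude = amplitude, modulation_depth = 0.5,
      effect_window = c(-0.3, 0.5)),
    gamma_visual = source_spec(
      current_dipole(c(0.005, -0.065, 0.015), c(1, 0, 0)),
      effect = "ers", trial_type = "circles", band = c(52, 65),
      baseline_amplitude = amplitude, modulation_depth = 1,
      effect_window = c(0, 1)),
    evoked_fusiform = source_spec(
      current_dipole(c(0.035, -0.05, -0.01), c(0, 1, 0)),
      effect = "evoked", trial_type = "faces", band = c(2, 40),
      baseline_amplitude = amplitude, evoked_latency = 0.17))
}

# Unit-RMS band-limited Gaussian carrier.
oscillatory_carrier <- function(n, fs, band, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- bandpass_vec(x, band, fs)
  x / stats::sd(x)
}

# Multiplicative envelope: 1 at baseline, 1 -/+ depth inside the effect
# window of each trial, with raised-cosine ramps.
modulation_envelope <- function(n, fs, trigger_samples, effect_window,
                                depth, effect, ramp = 0.1) {
  box <- numeric(n)
  w0 <- round(effect_window[1] * fs)
  w1 <- round(effect_window[2] * fs)
  for (s in trigger_samples) {
    i0 <- max(1L, s + w0)
    i1 <- min(n, s + w1)
    if (i1 >= i0) box[i0:i1] <- 1
  }
  nr <- max(1L, round(ramp * fs))
  kern <- 0.5 - 0.5 * cos(pi * seq_len(nr) / (nr + 1))
  kern <- c(kern, rev(kern)) / sum(c(kern, rev(kern)))
  box <- stats::filter(c(rep(box[1], nr), box, rep(box[n], nr)), kern,
                       sides = 2)[nr + seq_len(n)]
  box[is.na(box)] <- 0
  if (effect == "erd") 1 - depth * box else 1 + depth * box
}

# Deterministic evoked wavelet train (peak `latency` after each trigger).
evoked_waveform <- function(n, fs, trigger_samples, latency, freq, sigma) {
  w <- numeric(n)
  t_rel <- seq(-0.2, 0.8, by = 1 / fs)
  wl <- exp(-(t_rel - latency)^2 / (2 * sigma^2)) *
    cos(2 * pi * freq * (t_rel - latency))
  for (s in trigger_samples) {
    idx <- s + round(t_rel * fs)
    keep <- idx >= 1 & idx <= n
    w[idx[keep]] <- w[idx[keep]] + wl[keep]
  }
  w
}

# Moment timecourse (A m) for one source given the schedule triggers.
source_waveform <- function(spec, n, fs, trigger_samples, seed) {
  if (spec$effect == "evoked") {
    spec$baseline_amplitude *
      evoked_waveform(n, fs, trigger_samples, spec$evoked_latency,
                      spec$evoked_freq, spec$evoked_sigma)
  } else {
    carrier <- oscillatory_carrier(n, fs, spec$band, seed)
    env <- modulation_envelope(n, fs, trigger_samples, spec$effect_window,
                               spec$modulation_depth, spec$effect)
    spec$baseline_amplitude * carrier * env
  }
}

# Channel topography (192-vector) of a unit tangential moment at the
# source, T per A m.
source_topography <- function(spec, array, sphere) {
  pos <- spec$dipole$position
  radial <- pos - sphere$centre
  m <- spec$dipole$moment
  m_t <- m - sum(m * unitv(radial)) * unitv(radial)   # tangential part
  if (vnorm(m_t) < 1e-12)
    stop("source moment is purely radial (externally silent)")
  B <- dipole_field_sphere(pos, unitv(m_t), sphere,
                           channel_positions(array))
  rowSums(B * channel_orientations(array))
}

#' Simulate a visuo-motor OPM-MEG session
#'
#' Builds the continuous true fields from the configured sources, passes
#' them through the sensor model, adds sensor noise, and attaches trigger
#' channels (one code per trial type; 6 codes are defined in total).
#'
#' @param array A [sensor_array()].
#' @param schedule A [make_visuomotor_schedule()] schedule.
#' @param sources List of [source_spec()]; defaults to
#'   [default_visuomotor_sources()].
#' @param params A [sensor_model_params()].
#' @param seed Integer seed (noise and carrier streams).
#' @param sphere Conductor sphere (default radius 0.09 m at the origin).
#' @param lead_in,lead_out Quiet padding before the first / after the last
#'   trial, seconds.
#' @return An [opm_recording()]; `$truth` holds per-source waveforms,
#'   envelopes and dipole positions.
#' @export
simulate_visuomotor_session <- function(array, schedule,
                                        sources = default_visuomotor_sources(),
                                        params = sensor_model_params(),
                                        seed = 1,
                                        sphere = conductor_sphere(),
                                        lead_in = 2, lead_out = 2) {
  fs <- params$sample_rate
  n <- ceiling((schedule$total_duration + lead_in + lead_out) * fs)
  ev <- schedule$events
  trig_samples <- 1L + floor((ev$onset + lead_in) * fs)
  triggers <- data.frame(code = ev$trigger_code, sample = trig_samples,
                         label = ev$trial_type)
  total <- matrix(0, n_channels(array), n)
  truth <- list(sources = list(), schedule = schedule, sphere = sphere)
  for (nm in names(sources)) {
    spec <- sources[[nm]]
    topo <- source_topography(spec, array, sphere)
    ts <- trig_samples[ev$trial_type == spec$trial_type]
    w <- source_waveform(spec, n, fs, ts,
                         derive_seed(seed, 100L + match(nm, names(sources))))
    total <- total + outer(topo, w)
    truth$sources[[nm]] <- list(position = spec$dipole$position,
                                waveform = w, topography = topo,
                                spec = spec)
  }
  sim <- simulate_sensor_outputs(total, NULL, array, params, seed = seed)
  opm_recording(sim$data, fs, array, triggers, flags = sim$railed,
                truth = truth,
                meta = list(kind = "visuomotor", seed = seed,
                            loop_mode = params$loop_mode))
}

#' Simulate a phantom protocol recording
#'
#' Two protocols mirror the reference phantom experiments, with a 17-Hz
#' sinusoidal drive applied for 2 s followed by 1 s at zero current
#' (an integer 34 cycles per burst):
#' \describe{
#'   \item{linearity}{8 drive amplitudes (0.01-1 mA), each repeated 8
#'     times in cyclic order: 64 bursts, in nominally zero background.}
#'   \item{background_sweep}{1 mA drive; 5 bursts at each of 81 uniform
#'     vertical background levels from 0 to 8 nT in 0.1 nT steps:
#'     405 bursts.}
#' }
#' A trigger (code 6) marks each phantom-active period; for the sweep the
#' commanded background level per sample is recorded in
#' `$truth$background_nT`.
#'
#' @param array A [sensor_array()].
#' @param protocol "linearity" or "background_sweep".
#' @param params A [sensor_model_params()] (open or closed loop).
#' @param seed Integer noise seed.
#' @param coil A [triangular_coil()] already placed in the helmet, or
#'   `NULL` to mount the default coil via [place_phantom_coil()].
#' @param slot_sensor Helmet slot used when `coil` is `NULL`.
#' @param amplitudes_mA Drive amplitudes for the linearity protocol (8
#'   levels by default).
#' @param n_repeats Repeats per amplitude (linearity).
#' @param sweep_levels_nT Background levels for the sweep (81 by default).
#' @param bursts_per_level Bursts per background level (sweep).
#' @param background_direction Unit 3-vector of the uniform background
#'   (default vertical).
#' @param burst_duration,gap_duration Seconds of drive / zero current.
#' @return An [opm_recording()]; `$truth$bursts` tabulates burst onsets and
#'   levels.
#' @export
simulate_phantom_protocol <- function(array,
                                      protocol = c("linearity",
                                                   "background_sweep"),
                                      params = sensor_model_params(),
                                      seed = 1,
                                      coil = NULL, slot_sensor = 1L,
                                      amplitudes_mA = c(0.01, 0.02, 0.05,
                                                        0.1, 0.2, 0.5,
                                                        0.8, 1),
                                      n_repeats = 8,
                                      sweep_levels_nT = seq(0, 8, by = 0.1),
                                      bursts_per_level = 5,
                                      background_direction = c(0, 0, 1),
                                      burst_duration = 2,
                                      gap_duration = 1) {
  protocol <- tryCatch(match.arg(protocol),
                       error = function(e) stop("unknown protocol name"))
  fs <- params$sample_rate
  if (is.null(coil)) coil <- place_phantom_coil(array, slot_sensor)
  # burst drive levels (A) and background levels (T), one row per burst
  if (protocol == "linearity") {
    drive <- rep(amplitudes_mA, times = n_repeats) * 1e-3
    bg <- rep(0, length(drive))
  } else {
    drive <- rep(1e-3, length(sweep_levels_nT) * bursts_per_level)
    bg <- rep(sweep_levels_nT, each = bursts_per_level) * 1e-9
  }
  nb <- length(drive)
  spb <- round((burst_duration + gap_duration) * fs)
  nsb <- round(burst_duration * fs)
  n <- nb * spb
  onsets <- (seq_len(nb) - 1L) * spb + 1L
  # per-sample drive current and background magnitude
  t_burst <- (seq_len(nsb) - 1) / fs
  sine <- sin(2 * pi * 17 * t_burst)
  drive_t <- numeric(n)
  bg_t <- numeric(n)
  for (b in seq_len(nb)) {
    idx <- onsets[b]:(onsets[b] + nsb - 1L)
    drive_t[idx] <- drive[b] * sine
    # background holds through burst and following gap
    bg_t[onsets[b]:(onsets[b] + spb - 1L)] <- bg[b]
  }
  # rank-1 structure: per-channel topographies x shared timecourses
  topo <- rowSums(triangle_coil_field(triangular_coil(coil$vertices, 1),
                                      channel_positions(array)) *
                    channel_orientations(array))        # T per A
  bg_proj <- as.numeric(channel_orientations(array) %*%
                          unitv(background_direction)) # per T of background
  out <- matrix(0, n_channels(array), n)
  railed <- NULL
  transfer <- if (params$loop_mode == "open") open_loop_transfer else
    closed_loop_transfer
  for (sid in sensor_ids(array)) {
    rows <- triad_rows(array, sid)
    tot <- outer(topo[rows], drive_t) + outer(bg_proj[rows], bg_t)
    res <- transfer(field_state(tot, outer(bg_proj[rows], bg_t)), params)
    out[rows, ] <- res$measured
    if (any(res$railed)) {
      if (is.null(railed)) railed <- matrix(FALSE, nrow(out), n)
      railed[rows, res$railed] <- TRUE
    }
  }
  if (params$noise_density > 0) {
    sd_noise <- params$noise_density * sqrt(fs / 2)
    set.seed(derive_seed(seed, 7L))
    out <- out + matrix(stats::rnorm(length(out), sd = sd_noise),
                        nrow(out), n)
  }
  triggers <- data.frame(code = TRIGGER_CODES[["phantom_on"]],
                         sample = onsets, label = "phantom_on")
  level <- if (protocol == "linearity") drive * 1e3 else bg * 1e9
  bursts <- data.frame(burst_index = seq_len(nb), onset_sample = onsets,
                       level = level,
                       level_unit = if (protocol == "linearity") "mA"
                       else "nT",
                       drive_A = drive)
  opm_recording(out, fs, array, triggers, flags = railed,
                truth = list(bursts = bursts, coil = coil,
                             background_nT = bg_t * 1e9,
                             topography_per_A = topo),
                meta = list(kind = paste0("phantom_", protocol),
                            seed = seed, loop_mode = params$loop_mode))
}

#' Simulate a sitting-to-standing session
#'
#' Trials last 8 s, cued alternately by "stand" (code 4) and "sit" (code 5)
#' triggers. During the first 4 s of every trial a smooth background-field
#' excursion of magnitude `field_excursion` is applied along a per-sensor
#' random direction (drawn once per session), emulating head movement
#' through the remnant field of the shielded room; a bilateral
#' sensorimotor beta ERD is active over the same window.
#'
#' @param array A [sensor_array()].
#' @param n_trials Number of 8-s trials (>= 1).
#' @param field_excursion Peak background excursion, tesla (default 2e-9:
#'   movement through a 2-3 nT remnant field exceeds the 1.5 nT open-loop
#'   dynamic range).
#' @param params A [sensor_model_params()].
#' @param seed Integer seed.
#' @param sphere Conductor sphere.
#' @param amplitude Beta source baseline amplitude, ampere-metres.
#' @param modulation_depth Beta ERD depth during movement.
#' @return An [opm_recording()] with truth (source waveforms, positions,
#'   excursion profile, per-sensor directions).
#' @export
simulate_sit_to_stand_session <- function(array, n_trials = 20,
                                          field_excursion = 2e-9,
                                          params = sensor_model_params(),
                                          seed = 1,
                                          sphere = conductor_sphere(),
                                          amplitude = 10e-9,
                                          modulation_depth = 0.5) {
  if (!is_number(n_trials) || n_trials < 1)
    stop("invalid parameter: n_trials must be >= 1")
  fs <- params$sample_rate
  trial_len <- 8
  lead_in <- 2
  n <- ceiling((n_trials * trial_len + 2 * lead_in) * fs)
  onsets <- 1L + floor((lead_in + (seq_len(n_trials) - 1) * trial_len) * fs)
  codes <- rep(c(TRIGGER_CODES[["stand"]], TRIGGER_CODES[["sit"]]),
               length.out = n_trials)
  triggers <- data.frame(code = codes, sample = onsets,
                         label = ifelse(codes == 4L, "stand", "sit"))
  # movement excursion profile: raised-cosine up (1 s), hold (2 s), down (1 s)
  prof <- numeric(n)
  t_seg <- (seq_len(round(4 * fs)) - 1) / fs
  bump <- ifelse(t_seg < 1, 0.5 - 0.5 * cos(pi * t_seg),
                 ifelse(t_seg < 3, 1, 0.5 - 0.5 * cos(pi * (4 - t_seg))))
  for (s in onsets) {
    idx <- s:(min(n, s + length(bump) - 1L))
    prof[idx] <- bump[seq_along(idx)]
  }
  set.seed(derive_seed(seed, 31L))
  sids <- sensor_ids(array)
  dirs <- matrix(stats::rnorm(3 * length(sids)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rownames(dirs) <- as.character(sids)
  ori <- channel_orientations(array)
  bg_proj <- numeric(n_channels(array))
  for (i in seq_along(sids)) {
    rows <- triad_rows(array, sids[i])
    bg_proj[rows] <- ori[rows, , drop = FALSE] %*% dirs[i, ]
  }
  # bilateral sensorimotor beta sources, ERD during the 0-4 s movement
  sources <- list(
    beta_left = source_spec(current_dipole(c(-0.04, 0.01, 0.055), c(0, 1, 0)),
                            effect = "erd", trial_type = "move",
                            band = c(13, 30),
                            baseline_amplitude = amplitude,
                            modulation_depth = modulation_depth,
                            effect_window = c(0, 4)),
    beta_right = source_spec(current_dipole(c(0.04, 0.01, 0.055), c(0, 1, 0)),
                             effect = "erd", trial_type = "move",
                             band = c(13, 30),
                             baseline_amplitude = amplitude,
                             modulation_depth = modulation_depth,
                             effect_window = c(0, 4)))
  total <- outer(bg_proj, field_excursion * prof)
  background <- total
  truth <- list(sources = list(), sphere = sphere,
                excursion_profile = prof, sensor_directions = dirs,
                field_excursion = field_excursion)
  for (nm in names(sources)) {
    spec <- sources[[nm]]
    topo <- source_topography(spec, array, sphere)
    w <- source_waveform(spec, n, fs, onsets,
                         derive_seed(seed, 200L + match(nm, names(sources))))
    total <- total + outer(topo, w)
    truth$sources[[nm]] <- list(position = spec$dipole$position,
                                waveform = w, topography = topo, spec = spec)
  }
  sim_seedable <- simulate_sensor_outputs(total, background, array, params,
                                          seed = seed)
  opm_recording(sim_seedable$data, fs, array, triggers,
                flags = sim_seedable$railed, truth = truth,
                meta = list(kind = "sit_to_stand", seed = seed,
                            loop_mode = params$loop_mode))
}
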