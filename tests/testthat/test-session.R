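test_that("visuo-motor schedules have exact counts and arithmetic", {
  for (seed in c(1, 7, 123)) {
    s <- make_visuomotor_schedule(seed = seed)
    counts <- table(s$events$trial_type)
    expect_equal(unname(counts[c("circles", "faces", "catch")]),
                 c(60, 120, 25), ignore_attr = TRUE)
    ev <- s$events
    expect_true(all(diff(ev$onset) > 0))
    expect_equal(ev$onset[-1],
                 (ev$onset + ev$stim_duration + ev$rest_duration)[-nrow(ev)],
                 tolerance = 1e-12)
    expect_true(all(abs(ev$rest_duration - 1.25) <= 0.2 + 1e-12))
    expect_equal(s$total_duration,
                 sum(ev$stim_duration + ev$rest_duration))
  }
  expect_identical(make_visuomotor_schedule(seed = 4),
                   make_visuomotor_schedule(seed = 4))
})

test_that("disabling jitter makes circles trials exactly 2.25 s", {
  s <- make_visuomotor_schedule(seed = 1, jitter = 0)
  circ <- s$events[s$events$trial_type == "circles", ]
  expect_true(all(circ$stim_duration + circ$rest_duration == 2.25))
  expect_equal(s$total_duration, 396.25)
})

test_that("phantom linearity protocol produces 64 seed-independent bursts", {
  h <- small_helmet()
  p <- sensor_model_params(loop_mode = "closed")
  rec1 <- simulate_phantom_protocol(h, "linearity", p, seed = 1)
  rec2 <- simulate_phantom_protocol(h, "linearity", p, seed = 2)
  expect_equal(nrow(rec1$truth$bursts), 64)
  expect_equal(sum(rec1$triggers$code == 6), 64)
  expect_identical(rec1$truth$bursts, rec2$truth$bursts)
  expect_error(simulate_phantom_protocol(h, "nonsense", p),
               "unknown protocol")
})

test_that("zero-amplitude bursts contain background and noise only", {
  h <- small_helmet()
  p <- sensor_model_params(loop_mode = "closed")
  rec <- simulate_phantom_protocol(h, "linearity", p, seed = 3,
                                   amplitudes_mA = c(0, 1), n_repeats = 2)
  tab <- extract_burst_amplitudes(rec)
  a0 <- tab$amplitude_17Hz[tab$level == 0]
  a1 <- tab$amplitude_17Hz[tab$level == 1]
  noise_bin_sd <- 15e-15 * sqrt(p$sample_rate / 2) * sqrt(2 / 750)
  expect_lt(max(a0), 10 * noise_bin_sd)
  expect_gt(max(a1), 100 * max(a0))
})

test_that("visuo-motor sessions are deterministic and spectrally faithful", {
  h <- small_helmet()
  sched <- make_visuomotor_schedule(seed = 2, n_circles = 12, n_faces = 0,
                                    n_catch = 0)
  src <- list(gamma = source_spec(
    current_dipole(c(0.005, -0.065, 0.015), c(1, 0, 0)), effect = "ers",
    trial_type = "circles", band = c(52, 65), baseline_amplitude = 50e-9,
    modulation_depth = 1, effect_window = c(0, 1)))
  p <- sensor_model_params(loop_mode = "closed")
  rec <- simulate_visuomotor_session(h, sched, src, p, seed = 2)
  rec2 <- simulate_visuomotor_session(h, sched, src, p, seed = 2)
  expect_identical(rec$data, rec2$data)
  # best channel's stimulus-window spectrum peaks inside 52-65 Hz
  topo <- rec$truth$sources$gamma$topography
  bc <- which.max(abs(topo))
  ep <- segment_trials(rec, 1L, c(0, 1))
  x <- as.numeric(t(ep$data[, bc, ]))
  L <- length(x)
  freqs <- (seq_len(L %/% 2) - 1) * p$sample_rate / L
  pw <- Mod(stats::fft(x - mean(x))[seq_len(L %/% 2)])^2
  fpk <- freqs[freqs > 5][which.max(pw[freqs > 5])]
  expect_gte(fpk, 52)
  expect_lte(fpk, 65)
})

test_that("null sources give a null pseudo-T contrast", {
  # modulation depth 0: the active/control contrast should sit at the
  # noise floor of the pseudo-T statistic (~3 null sd = 0.2 here)
  run <- beta_localisation_run(seed = 21, modulation_depth = 0)
  expect_lt(max(abs(run$image$values)), 0.2)
})

test_that("sit-to-stand excursions rail open-loop but not closed-loop", {
  h <- small_helmet()
  po <- sensor_model_params(loop_mode = "open")
  pc <- sensor_model_params(loop_mode = "closed")
  rec_o <- simulate_sit_to_stand_session(h, n_trials = 3, params = po,
                                         seed = 4)
  expect_false(is.null(rec_o$flags))
  expect_gt(sum(rowSums(rec_o$flags) > 0), 0)
  rec_c <- simulate_sit_to_stand_session(h, n_trials = 3, params = pc,
                                         seed = 4)
  expect_null(rec_c$flags)
  expect_error(simulate_sit_to_stand_session(h, n_trials = 0, params = pc),
               "invalid parameter")
})

test_that("zero excursion makes open and closed loop agree within noise", {
  h <- small_helmet()
  po <- sensor_model_params(loop_mode = "open")
  pc <- sensor_model_params(loop_mode = "closed")
  rec_o <- simulate_sit_to_stand_session(h, n_trials = 2,
                                         field_excursion = 0, params = po,
                                         seed = 6)
  rec_c <- simulate_sit_to_stand_session(h, n_trials = 2,
                                         field_excursion = 0, params = pc,
                                         seed = 6)
  # same seed -> same noise stream; residual is the pT-scale gain error
  expect_lt(max(abs(rec_o$data - rec_c$data)), 1e-15)
  expect_null(rec_o$flags)
})

test_that("ground truth is emitted alongside every simulated recording", {
  h <- small_helmet()
  rec <- simulate_sit_to_stand_session(h, n_trials = 2,
                                       params = sensor_model_params(
                                         loop_mode = "closed"), seed = 1)
  expect_named(rec$truth$sources, c("beta_left", "beta_right"))
  expect_length(rec$truth$sources$beta_left$waveform, ncol(rec$data))
  expect_equal(dim(rec$truth$sensor_directions),
               c(length(opmsim:::sensor_ids(h)), 3))
  p <- sensor_model_params(loop_mode = "closed")
  ph <- simulate_phantom_protocol(h, "linearity", p, seed = 1)
  expect_s3_class(ph$truth$coil, "triangular_coil")
  expect_equal(nrow(ph$truth$bursts), 64)
})
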