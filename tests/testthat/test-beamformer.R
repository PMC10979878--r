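fs <- 375

# Small epochs of white channel noise.
white_epochs <- function(n_trials, nch, ns, sd = 1e-13, seed = 1) {
  set.seed(seed)
  opm_epochs(array(stats::rnorm(n_trials * nch * ns, sd = sd),
                   c(n_trials, nch, ns)), c(0, ns / fs), fs)
}

test_that("white-noise covariance is diagonal and regularisation shifts the spectrum", {
  ep <- white_epochs(10, 12, 6 * fs, sd = 1e-13, seed = 2)
  m <- compute_covariance(ep, reg_fraction = 0.01)
  s2 <- 1e-26
  expect_equal(mean(diag(m$covariance)), s2, tolerance = 0.05)
  off <- m$covariance[upper.tri(m$covariance)]
  expect_lt(max(abs(off)), 0.05 * s2)
  # exact spectral identities of diagonal loading
  e0 <- eigen(m$covariance, symmetric = TRUE, only.values = TRUE)$values
  e1 <- eigen(m$covariance_reg, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(e1), 1.01 * max(e0), tolerance = 1e-12)
  expect_equal(min(e1), min(e0) + 0.01 * max(e0), tolerance = 1e-12)
})

test_that("duplicating every trial leaves the covariance unchanged", {
  ep <- white_epochs(6, 8, 400, seed = 3)
  dup <- ep
  dup$data <- opmsim:::abind_trials(ep$data, ep$data)
  c1 <- compute_covariance(ep)$covariance
  c2 <- compute_covariance(dup)$covariance
  expect_equal(c2, c1, tolerance = 1e-10)
})

test_that("LCMV weights satisfy unit gain and the power identity", {
  h <- small_helmet()
  sph <- default_sphere()
  grid <- make_source_grid(sph, 0.008, centre = c(-0.03, 0, 0.05),
                           half_width = 0.016)
  lf <- build_lead_fields(h, grid, sph)
  ep <- white_epochs(8, n_channels(h), 2 * fs, seed = 4)
  model <- lcmv_weights(compute_covariance(ep), lf)
  Ci <- solve(model$covariance_reg)
  for (v in seq(1, nrow(grid$positions), by = 7)) {
    # recover the tangential coefficients of the stored orientation
    tb <- lf$tangentials[v, , ]                 # 2 x 3, orthonormal rows
    l <- lf$L[, , v] %*% (tb %*% model$orientations[v, ])
    w <- model$weights[v, ]
    expect_equal(as.numeric(w %*% l), 1, tolerance = 1e-8)
    # output power equals 1 / (l' C^-1 l)
    expect_equal(as.numeric(t(w) %*% model$covariance_reg %*% w),
                 as.numeric(1 / (t(l) %*% Ci %*% l)), tolerance = 1e-8)
  }
})

test_that("identity covariance aligns weights with the lead field", {
  h <- small_helmet()
  sph <- default_sphere()
  grid <- make_source_grid(sph, 0.008, centre = c(0, 0.02, 0.05),
                           half_width = 0.008)
  lf <- build_lead_fields(h, grid, sph)
  model <- structure(list(covariance = diag(n_channels(h)),
                          covariance_reg = diag(n_channels(h)),
                          lambda_max = 1, reg_fraction = 0,
                          band = NULL, window = c(0, 1)),
                     class = "beamformer_model")
  model <- lcmv_weights(model, lf)
  for (v in seq_len(nrow(grid$positions))) {
    tb <- lf$tangentials[v, , ]
    l <- as.numeric(lf$L[, , v] %*% (tb %*% model$orientations[v, ]))
    w <- model$weights[v, ]
    cosang <- sum(w * l) / sqrt(sum(w^2) * sum(l^2))
    expect_gt(cosang, 1 - 1e-10)
  }
})

test_that("a seeded dipole is localised to within one grid step at SNR >= 5", {
  run <- beta_localisation_run(seed = 11)
  expect_lte(run$error_mm, 4)
  expect_lt(run$peak$value, -0.2)  # clear ERD
})

test_that("pseudo-T is null for equal windows and antisymmetric under swap", {
  ep <- white_epochs(10, n_channels(small_helmet()), 2 * fs, seed = 5)
  grid <- make_source_grid(default_sphere(), 0.008,
                           centre = c(0, 0.02, 0.05), half_width = 0.008)
  lf <- build_lead_fields(small_helmet(), grid, default_sphere())
  model <- lcmv_weights(compute_covariance(ep), lf)
  same <- pseudo_t_image(ep, model, c(0.2, 0.8), c(0.2, 0.8))
  expect_true(all(same$values == 0))
  ab <- pseudo_t_image(ep, model, c(0, 0.5), c(1, 1.5))
  ba <- pseudo_t_image(ep, model, c(1, 1.5), c(0, 0.5))
  expect_equal(ab$values, -ba$values, tolerance = 1e-14)
  expect_true(all(abs(ab$values) <= 1))
})

test_that("image values are invariant to channel reordering", {
  h <- small_helmet()
  sph <- default_sphere()
  grid <- make_source_grid(sph, 0.008, centre = c(-0.03, 0, 0.05),
                           half_width = 0.008)
  lf <- build_lead_fields(h, grid, sph)
  set.seed(6)
  ep <- white_epochs(8, n_channels(h), fs, seed = 6)
  img <- pseudo_t_image(ep, lcmv_weights(compute_covariance(ep), lf),
                        c(0, 0.4), c(0.6, 1))
  perm <- sample(n_channels(h))
  ep_p <- ep
  ep_p$data <- ep$data[, perm, , drop = FALSE]
  lf_p <- lf
  lf_p$L <- lf$L[perm, , , drop = FALSE]
  img_p <- pseudo_t_image(ep_p, lcmv_weights(compute_covariance(ep_p), lf_p),
                          c(0, 0.4), c(0.6, 1))
  expect_equal(img_p$values, img$values, tolerance = 1e-8)
})

test_that("evoked sources produce a localised pseudo-Z peak at the right latency", {
  h <- default_helmet()
  sph <- default_sphere()
  truth <- c(0.035, -0.05, -0.01)
  sched <- make_visuomotor_schedule(seed = 2, n_circles = 0, n_faces = 60,
                                    n_catch = 0)
  src <- list(ev = source_spec(current_dipole(truth, c(0, 1, 0)),
                               effect = "evoked", trial_type = "faces",
                               band = c(2, 40), baseline_amplitude = 20e-9,
                               evoked_latency = 0.17))
  rec <- simulate_visuomotor_session(h, sched, src,
                                     sensor_model_params(loop_mode = "closed"),
                                     seed = 2)
  rec <- bandpass_recording(rec, c(2, 40))
  ep <- segment_trials(rec, 2L, c(0, 1.5))
  ep$band <- c(2, 40)
  grid <- make_source_grid(sph, 0.004, centre = truth, half_width = 0.012)
  model <- lcmv_weights(compute_covariance(ep),
                        build_lead_fields(h, grid, sph))
  img <- pseudo_z_image(ep, model, 0.17)
  pk <- peak_voxel(img, "max")
  expect_lte(1000 * sqrt(sum((pk$position - truth)^2)), 4)
  # doubling the evoked amplitude doubles the peak pseudo-Z (fixed weights)
  ep2 <- ep
  ep2$data <- 2 * ep$data
  img2 <- pseudo_z_image(ep2, model, 0.17)
  expect_equal(peak_voxel(img2, "max")$value, 2 * pk$value,
               tolerance = 0.05)
  # averaged evoked response peaks within 10 ms of the seeded latency
  ve <- virtual_electrode(ep, model, pk$position)
  er <- evoked_response(ve)
  expect_lt(abs(er$times[which.max(abs(er$response))] - 0.17), 0.010)
  expect_error(pseudo_z_image(ep, model, 5), "bounds")
})

test_that("null pseudo-Z values sit at the noise floor", {
  h <- small_helmet()
  sph <- default_sphere()
  grid <- make_source_grid(sph, 0.008, centre = c(0.03, -0.04, 0),
                           half_width = 0.008)
  lf <- build_lead_fields(h, grid, sph)
  q95 <- vapply(1:20, function(s) {
    ep <- white_epochs(120, n_channels(h), 150, seed = 100 + s)
    model <- lcmv_weights(compute_covariance(ep), lf)
    img <- pseudo_z_image(ep, model, 0.2)
    stats::quantile(img$values, 0.95)
  }, 0)
  expect_lt(stats::quantile(q95, 0.95), 3)
})

test_that("virtual electrodes reconstruct source timecourses", {
  h <- default_helmet()
  sph <- default_sphere()
  # noiseless single dipole: VE at the true voxel recovers the waveform
  sched <- make_visuomotor_schedule(seed = 3, n_circles = 0, n_faces = 0,
                                    n_catch = 10)
  src <- list(beta = source_spec(current_dipole(MOTOR_POS, c(0, 1, 0)),
                                 effect = "erd", trial_type = "catch",
                                 band = c(13, 30),
                                 baseline_amplitude = 20e-9,
                                 modulation_depth = 0.5,
                                 effect_window = c(-0.3, 0.5)))
  p0 <- sensor_model_params(loop_mode = "closed", noise_density = 0)
  rec <- simulate_visuomotor_session(h, sched, src, p0, seed = 3)
  ep <- segment_trials(rec, 3L, c(-0.3, 1.7))
  ep$band <- c(13, 30)
  model <- lcmv_weights(compute_covariance(ep), motor_leadfields())
  ve <- virtual_electrode(ep, model, MOTOR_POS)
  w_true <- rec$truth$sources$beta$waveform
  trig <- trigger_samples(rec, 3L)
  s0 <- trig[1] + floor(-0.3 * fs)
  truth_trial <- w_true[s0:(s0 + dim(ep$data)[3] - 1)]
  expect_gt(abs(stats::cor(ve$timecourse[1, ], truth_trial)), 1 - 1e-6)
  # zero data give a zero timecourse
  ep0 <- ep
  ep0$data[] <- 0
  expect_true(all(virtual_electrode(ep0, model, MOTOR_POS)$timecourse == 0))
  expect_error(virtual_electrode(ep, model, c(0.5, 0.5, 0.5)), "lookup")
})

test_that("localisation comparison metrics behave", {
  run <- beta_localisation_run(seed = 13, with_envelope = TRUE)
  cmp_same <- compare_localisations(run$image, run$image, run$envelope,
                                    run$envelope, extremum = "min")
  expect_equal(cmp_same$peak_distance_mm, 0)
  expect_equal(cmp_same$correlation, 1)
  # Pearson correlation is invariant to affine scaling
  cmp_aff <- compare_localisations(run$image, run$image, run$envelope,
                                   5e3 * run$envelope + 2, extremum = "min")
  expect_equal(cmp_aff$correlation, 1)
  other <- run$image
  other$grid <- make_source_grid(default_sphere(), 0.008,
                                 centre = c(0, 0, 0.04),
                                 half_width = 0.008)
  expect_error(compare_localisations(run$image, other, run$envelope,
                                     run$envelope), "incompatible")
})
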