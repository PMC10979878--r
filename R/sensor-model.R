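# OPM sensor model: conversion of true vector fields at the vapour cell into
# measured channel outputs, in open- or closed-loop operation.
#
# Open loop: the zero-field resonance gives a Lorentzian gain
#   G(|B|) = gamma^2 / (gamma^2 + |B|^2)
# in the quasi-static field magnitude |B|, so large background fields
# suppress the measured signal. Large orthogonal background components also
# leak into the measured axis (cross-axis projection error, CAPE), modelled
# as a bilinear term. Outputs beyond the sensor dynamic range (+/- 1.5 nT)
# are clamped and flagged.
#
# Closed loop: on-board coils null the cell field continuously, so the
# (ideal) output equals the true field whenever it is within the coil range
# (+/- 50 nT); a finite loop bandwidth can be modelled with a single-pole
# tracking term.

#' Sensor-model parameters
#'
#' @param linewidth_gamma Half-width of the zero-field resonance, tesla
#'   (default 10e-9). Sets the scale of open-loop gain suppression:
#'   on-axis gain is exactly 0.5 when the quasi-static field magnitude
#'   equals `linewidth_gamma`.
#' @param cape_coefficient Dimensionless cross-axis projection error
#'   coefficient (default 0.1).
#' @param dynamic_range Open-loop linear range, tesla (default 1.5e-9).
#' @param coil_range On-board compensation coil range, tesla
#'   (default 50e-9).
#' @param loop_mode "open" or "closed".
#' @param loop_bandwidth Closed-loop tracking bandwidth, Hz; `Inf` (default)
#'   is the ideal loop.
#' @param noise_density White sensor noise density, tesla per sqrt(Hz)
#'   (default 15e-15).
#' @param sample_rate Sampling rate, Hz.
#' @param dc_cutoff Cut-off of the low-pass that estimates the quasi-static
#'   field magnitude used by the gain law, Hz (default 1).
#' @return Object of class `sensor_model_params`.
#' @export
sensor_model_params <- function(linewidth_gamma = 10e-9,
                                cape_coefficient = 0.1,
                                dynamic_range = 1.5e-9,
                                coil_range = 50e-9,
                                loop_mode = c("open", "closed"),
                                loop_bandwidth = Inf,
                                noise_density = 15e-15,
                                sample_rate = 375,
                                dc_cutoff = 1) {
  loop_mode <- match.arg(loop_mode)
  stopifnot_number(linewidth_gamma, "linewidth_gamma", positive = TRUE)
  stopifnot_number(dynamic_range, "dynamic_range", positive = TRUE)
  stopifnot_number(coil_range, "coil_range", positive = TRUE)
  if (dynamic_range >= coil_range)
    stop("dynamic_range must be smaller than coil_range")
  stopifnot_number(sample_rate, "sample_rate", positive = TRUE)
  if (!is.numeric(noise_density) || noise_density < 0)
    stop("noise_density must be >= 0")
  structure(list(linewidth_gamma = linewidth_gamma,
                 cape_coefficient = cape_coefficient,
                 dynamic_range = dynamic_range,
                 coil_range = coil_range,
                 loop_mode = loop_mode,
                 loop_bandwidth = loop_bandwidth,
                 noise_density = noise_density,
                 sample_rate = sample_rate,
                 dc_cutoff = dc_cutoff),
            class = "sensor_model_params")
}

#' True vector field state at one sensor
#'
#' Holds the total field and its slow/background part along the sensor's
#' three local axes, for a sequence of samples. The signal of interest is
#' defined componentwise as total minus background.
#'
#' @param total 3 x T matrix, tesla: total true field along the local X, Y,
#'   Z axes.
#' @param background 3 x T matrix, tesla: background (slow) part; defaults
#'   to zero.
#' @return Object of class `field_state`.
#' @export
field_state <- function(total, background = NULL) {
  total <- as.matrix(total)
  if (nrow(total) != 3) stop("total must be a 3 x T matrix")
  if (is.null(background)) background <- matrix(0, 3, ncol(total))
  background <- as.matrix(background)
  if (!all(dim(background) == dim(total)))
    stop("background must match total in shape")
  structure(list(total = total, background = background),
            class = "field_state")
}

# Quasi-static field magnitude, low-passed at params$dc_cutoff.
dc_magnitude <- function(total, params) {
  mag <- sqrt(colSums(total^2))
  lowpass1(mag, params$dc_cutoff, params$sample_rate)
}

#' Open-loop sensor transfer
#'
#' Applies the Lorentzian gain law and the CAPE cross-term to a field-state
#' sequence. Per sample and axis,
#' `out = G(|B_dc|) * B_axis + cape * B_b_orth1 * B_b_orth2 / gamma`,
#' with `G(|B|) = gamma^2 / (gamma^2 + |B|^2)` and `|B_dc|` the low-passed
#' total field magnitude. Outputs are clamped to `+/- dynamic_range`;
#' samples where any axis of the true field exceeds the dynamic range are
#' flagged `railed` (a data flag, not an error).
#'
#' @param state A [field_state()].
#' @param params [sensor_model_params()] with `loop_mode = "open"`.
#' @return List with `measured` (3 x T, tesla) and `railed` (logical T).
#' @export
open_loop_transfer <- function(state, params) {
  if (params$loop_mode != "open")
    stop("params$loop_mode must be 'open'")
  g <- params$linewidth_gamma
  B <- state$total
  Bb <- state$background
  gain <- g^2 / (g^2 + dc_magnitude(B, params)^2)
  out <- B * rep(gain, each = 3)
  # CAPE: product of the two orthogonal slow components, scaled by gamma
  out[1, ] <- out[1, ] + params$cape_coefficient * Bb[2, ] * Bb[3, ] / g
  out[2, ] <- out[2, ] + params$cape_coefficient * Bb[1, ] * Bb[3, ] / g
  out[3, ] <- out[3, ] + params$cape_coefficient * Bb[1, ] * Bb[2, ] / g
  railed <- colSums(abs(B) > params$dynamic_range) > 0
  dr <- params$dynamic_range
  out[out > dr] <- dr
  out[out < -dr] <- -dr
  list(measured = out, railed = railed)
}

#' Closed-loop sensor transfer
#'
#' Under the ideal loop (`loop_bandwidth = Inf`) the compensation coils null
#' the cell field exactly, so the output equals the true field for every
#' sample within the coil range; samples where any axis exceeds the coil
#' range are flagged out-of-range. A finite `loop_bandwidth` applies a
#' single-pole tracking model: the compensation follows the field with a
#' first-order lag and the (small) residual cell field passes through the
#' open-loop transfer.
#'
#' @param state A [field_state()].
#' @param params [sensor_model_params()] with `loop_mode = "closed"`.
#' @return List with `measured` (3 x T, tesla) and `railed` (logical T;
#'   out-of-coil-range flags).
#' @export
closed_loop_transfer <- function(state, params) {
  if (params$loop_mode != "closed")
    stop("params$loop_mode must be 'closed'")
  B <- state$total
  railed <- colSums(abs(B) > params$coil_range) > 0
  if (is.infinite(params$loop_bandwidth)) {
    return(list(measured = B, railed = railed))
  }
  comp <- t(apply(B, 1, lowpass1, fc = params$loop_bandwidth,
                  fs = params$sample_rate))
  resid <- B - comp
  op <- params
  op$loop_mode <- "open"
  res <- open_loop_transfer(field_state(resid), op)
  list(measured = comp + res$measured, railed = railed)
}

#' Simulate measured channel outputs for a whole array
#'
#' Applies the configured open- or closed-loop transfer per sensor triad in
#' the sensor-local frame, then adds independent white sensor noise with the
#' configured density (per-sample standard deviation
#' `noise_density * sqrt(sample_rate / 2)`). Channels are assumed ordered in
#' triads matching `array`.
#'
#' @param total Channels x T matrix of true total fields along each
#'   channel's sensitive axis, tesla.
#' @param background Channels x T matrix of background components (or
#'   `NULL` for zero background).
#' @param array A [sensor_array()].
#' @param params A [sensor_model_params()].
#' @param seed Integer seed for the noise stream.
#' @return List with `data` (channels x T measured fields, tesla) and
#'   `railed` (channels x T logical, or `NULL` when nothing railed).
#' @export
simulate_sensor_outputs <- function(total, background = NULL, array, params,
                                    seed = 1) {
  total <- as.matrix(total)
  if (nrow(total) != n_channels(array))
    stop("shape error: field rows must match array channels (",
         n_channels(array), ")")
  if (!is.null(background) && !all(dim(background) == dim(total)))
    stop("shape error: background must match total in shape")
  nt <- ncol(total)
  out <- matrix(0, nrow(total), nt)
  railed <- NULL
  transfer <- if (params$loop_mode == "open") open_loop_transfer else
    closed_loop_transfer
  for (sid in sensor_ids(array)) {
    rows <- triad_rows(array, sid)
    st <- field_state(total[rows, , drop = FALSE],
                      if (is.null(background)) NULL else
                        background[rows, , drop = FALSE])
    res <- transfer(st, params)
    out[rows, ] <- res$measured
    if (any(res$railed)) {
      if (is.null(railed)) railed <- matrix(FALSE, nrow(total), nt)
      railed[rows, res$railed] <- TRUE
    }
  }
  if (params$noise_density > 0) {
    sd_noise <- params$noise_density * sqrt(params$sample_rate / 2)
    set.seed(derive_seed(seed, 7L))
    out <- out + matrix(stats::rnorm(length(out), sd = sd_noise),
                        nrow(out), nt)
  }
  list(data = out, railed = railed)
}
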