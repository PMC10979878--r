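# Preprocessing: bad-channel and bad-trial rejection, zero-phase filtering,
# homogeneous field correction (HFC), trigger-based segmentation.
#
# Filter realisation: zero-phase forward-backward Butterworth IIR filters
# (signal::filtfilt); 4th-order band-pass, 2nd-order notches per direction.
# Windows are half-open [t0, t1) with 0-based sample arithmetic and floor
# rounding, stated once here and used everywhere.

bandpass_vec <- function(x, band, fs) {
  bf <- signal::butter(4, c(band[1], band[2]) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

notch_vec <- function(x, f0, fs, half_width = 2) {
  bf <- signal::butter(2, c(f0 - half_width, f0 + half_width) / (fs / 2),
                       type = "stop")
  signal::filtfilt(bf, x)
}

# Apply a per-row filter function to a channels x samples matrix.
filter_rows <- function(M, fun) {
  out <- M
  for (i in seq_len(nrow(M))) out[i, ] <- fun(M[i, ])
  out
}

# Band-limit every trial of an epochs object.
filter_epochs <- function(ep, band) {
  if (is.null(band)) return(ep)
  d <- ep$data
  bf <- signal::butter(4, c(band[1], band[2]) / (ep$sample_rate / 2),
                       type = "pass")
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      d[tr, ch, ] <- signal::filtfilt(bf, d[tr, ch, ])
  ep$data <- d
  ep$band <- band
  ep
}

# Band-averaged one-sided amplitude spectral density per channel
# (Welch periodogram, 1-s rectangular segments), tesla / sqrt(Hz).
channel_noise_density <- function(data, fs, band = c(3, 100)) {
  L <- floor(fs)
  nseg <- floor(ncol(data) / L)
  if (nseg < 1) stop("insufficient data for spectral estimation")
  freqs <- (seq_len(L %/% 2)) * fs / L
  sel <- freqs >= band[1] & freqs <= band[2]
  acc <- matrix(0, nrow(data), sum(sel))
  for (s in seq_len(nseg)) {
    seg <- data[, ((s - 1) * L + 1):(s * L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- t(stats::mvfft(t(seg)))
    # one-sided PSD, T^2/Hz
    psd <- 2 * Mod(X[, 2:(L %/% 2 + 1), drop = FALSE])^2 / (fs * L)
    acc <- acc + psd[, sel, drop = FALSE]
  }
  sqrt(rowMeans(acc) / nseg)
}

#' Detect bad channels
#'
#' Flags channels whose band-averaged (3-100 Hz) noise density exceeds the
#' channel median by `z_threshold` scaled median absolute deviations
#' (excessively noisy), or falls below `dead_floor` (not functioning).
#' The recording is not modified.
#'
#' @param rec An [opm_recording()] of at least 10 s.
#' @param z_threshold Robust z-score threshold (default 5).
#' @param dead_floor Density below which a channel counts as dead, tesla
#'   per sqrt(Hz) (default 1e-16).
#' @param band Hz interval for the density estimate.
#' @return Integer vector of bad channel indices (possibly empty).
#' @export
detect_bad_channels <- function(rec, z_threshold = 5, dead_floor = 1e-16,
                                band = c(3, 100)) {
  if (ncol(rec$data) < 10 * rec$sample_rate)
    stop("insufficient data: need at least 10 s for bad-channel detection")
  dens <- channel_noise_density(rec$data, rec$sample_rate, band)
  med <- stats::median(dens)
  mad <- stats::mad(dens)
  noisy <- dens > med + z_threshold * mad
  dead <- dens < dead_floor
  sort(unique(c(which(noisy), which(dead))))
}

#' Apply the standard filter chain
#'
#' Zero-phase notch filters at the powerline frequency and two harmonics
#' (50/100/150 Hz by default) followed by a zero-phase 1-150 Hz band-pass.
#' Triggers and flags are unchanged.
#'
#' @param rec An [opm_recording()].
#' @param band Pass band, Hz (default `c(1, 150)`).
#' @param notches Notch centre frequencies, Hz; those at or above Nyquist
#'   are an error.
#' @return The filtered [opm_recording()], with the operation appended to
#'   `meta$history`.
#' @export
apply_filters <- function(rec, band = c(1, 150), notches = c(50, 100, 150)) {
  nyq <- rec$sample_rate / 2
  if (band[2] >= nyq || any(notches + 2 >= nyq))
    stop("configuration error: sample_rate too low for requested bands")
  data <- rec$data
  for (f0 in notches) data <- filter_rows(data, function(x)
    notch_vec(x, f0, rec$sample_rate))
  data <- filter_rows(data, function(x)
    bandpass_vec(x, band, rec$sample_rate))
  rec$data <- data
  rec$meta$history <- c(rec$meta$history,
                        sprintf("filters: notch %s Hz; band-pass %g-%g Hz",
                                paste(notches, collapse = "/"),
                                band[1], band[2]))
  rec
}

# Projector onto the complement of the homogeneous-field subspace.
hfc_projector <- function(array) {
  N <- channel_orientations(array)
  if (qr(N)$rank < 3)
    stop("rank deficiency: channel orientations do not span 3 dimensions")
  diag(nrow(N)) - N %*% solve(crossprod(N), t(N))
}

#' Homogeneous field correction (HFC)
#'
#' Projects the three spatially homogeneous field components out of the
#' data: `data <- (I - N (N'N)^-1 N') data`, with `N` the 3-column matrix
#' of channel orientations. Uniform fields in any direction are removed
#' exactly; the projector is idempotent and symmetric.
#'
#' @param rec An [opm_recording()] whose array orientations have rank 3.
#' @return The corrected [opm_recording()]; the projector is stored in
#'   `meta$hfc_projector` for provenance.
#' @export
homogeneous_field_correction <- function(rec) {
  P <- hfc_projector(rec$array)
  rec$data <- P %*% rec$data
  rec$meta$hfc_projector <- P
  rec$meta$history <- c(rec$meta$history, "homogeneous field correction")
  rec
}

#' Segment a recording into trials
#'
#' Cuts half-open windows `[t0, t1)` (seconds, relative to each trigger of
#' `trigger_code`) out of the recording, with floor rounding to samples.
#' An empty trigger list yields a zero-trial epochs object.
#'
#' @param rec An [opm_recording()].
#' @param trigger_code Integer trigger code to segment on.
#' @param window Length-2 numeric, seconds relative to the trigger.
#' @return An [opm_epochs()] object (trials x channels x samples).
#' @export
segment_trials <- function(rec, trigger_code, window) {
  fs <- rec$sample_rate
  ns <- floor((window[2] - window[1]) * fs)
  offs <- floor(window[1] * fs)
  trig <- trigger_samples(rec, trigger_code)
  starts <- trig + offs
  bad <- which(starts < 1 | starts + ns - 1 > ncol(rec$data))
  if (length(bad) > 0)
    stop("truncation error: window exceeds record bounds for trial(s) ",
         paste(bad, collapse = ", "))
  d <- array(0, dim = c(length(trig), nrow(rec$data), ns))
  for (i in seq_along(trig))
    d[i, , ] <- rec$data[, starts[i]:(starts[i] + ns - 1L)]
  opm_epochs(d, window, fs, retained_trial_ids = seq_along(trig),
             array = rec$array)
}

#' Reject bad trials
#'
#' Removes trials whose maximum absolute amplitude (over channels and
#' samples) exceeds the trial median by `z_threshold` scaled median
#' absolute deviations.
#'
#' @param ep An [opm_epochs()] object with at least 3 trials.
#' @param z_threshold Robust z-score threshold (default 6).
#' @return The pruned [opm_epochs()]; retained ids in
#'   `retained_trial_ids`.
#' @export
reject_bad_trials <- function(ep, z_threshold = 6) {
  nt <- n_trials(ep)
  if (nt < 3) stop("need at least 3 trials for trial rejection")
  mx <- vapply(seq_len(nt), function(i) max(abs(ep$data[i, , ])), 0)
  keep <- mx <= stats::median(mx) + z_threshold * stats::mad(mx)
  if (!any(keep)) stop("empty result: all trials rejected")
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$retained_trial_ids <- ep$retained_trial_ids[keep]
  ep
}
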