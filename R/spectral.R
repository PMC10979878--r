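# Hilbert-envelope analysis: band envelopes of virtual-electrode data,
# trial-averaged evoked responses, and baseline-corrected time-frequency
# spectrograms (TFS).

#' Analytic signal via the FFT
#'
#' Returns `x + i H(x)` where `H` is the Hilbert transform: the FFT of `x`
#' with negative frequencies zeroed and positive frequencies doubled.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Envelope of one band-passed vector, with reflection padding (default
# 0.25 s) to limit Hilbert/filter edge artefacts.
band_envelope_vec <- function(x, band, fs, pad = 0.25) {
  np <- min(length(x) - 1L, round(pad * fs))
  xp <- c(rev(x[seq_len(np) + 1L]), x,
          rev(x[length(x) - seq_len(np)]))
  xb <- bandpass_vec(xp, band, fs)
  env <- Mod(analytic_signal(xb))
  env[np + seq_along(x)]
}

#' Hilbert envelope of a virtual electrode
#'
#' Band-passes the timecourse(s), forms the analytic signal, and takes its
#' magnitude: the envelope of oscillatory amplitude. For multi-trial input
#' the envelope is computed per trial and then averaged (the trial-averaged
#' envelope of induced activity). An optional moving-average smoothing is
#' applied to the averaged envelope.
#'
#' @param ve A [virtual_electrode()], a trials x samples matrix, or a
#'   numeric vector; `fs` must be given for plain inputs.
#' @param band Length-2 Hz interval (within Nyquist).
#' @param fs Sampling rate, Hz (taken from `ve` when available).
#' @param smooth Width of a moving-average smoother applied to the
#'   averaged envelope, seconds (0 = none).
#' @return List with `envelope` (trial-averaged), `trial_envelopes`
#'   (trials x samples), `times` (if known), `band`.
#' @export
hilbert_envelope <- function(ve, band, fs = NULL, smooth = 0) {
  times <- NULL
  if (inherits(ve, "virtual_electrode")) {
    fs <- ve$sample_rate
    times <- ve$times
    M <- ve$timecourse
  } else if (is.matrix(ve)) {
    M <- ve
  } else {
    M <- matrix(as.numeric(ve), nrow = 1)
  }
  if (is.null(fs)) stop("fs must be supplied for plain numeric input")
  if (band[2] >= fs / 2)
    stop("configuration error: band extends beyond Nyquist")
  E <- t(apply(M, 1, band_envelope_vec, band = band, fs = fs))
  if (nrow(M) == 1) E <- matrix(E, nrow = 1)
  avg <- colMeans(E)
  if (smooth > 0) {
    k <- max(1L, round(smooth * fs))
    kern <- rep(1 / k, k)
    avg <- stats::filter(c(rep(avg[1], k), avg, rep(avg[length(avg)], k)),
                         kern, sides = 2)[k + seq_along(avg)]
  }
  list(envelope = as.numeric(avg), trial_envelopes = E, times = times,
       band = band)
}

#' Trial-averaged evoked response
#'
#' Mean across trials of (band-limited) virtual-electrode timecourses.
#'
#' @param ve A [virtual_electrode()] or trials x samples matrix.
#' @param band Optional Hz interval applied (zero phase) per trial before
#'   averaging.
#' @param fs Sampling rate for matrix input.
#' @return List with `response`, `times` (if known).
#' @export
evoked_response <- function(ve, band = NULL, fs = NULL) {
  times <- NULL
  if (inherits(ve, "virtual_electrode")) {
    fs <- ve$sample_rate
    times <- ve$times
    M <- ve$timecourse
  } else M <- as.matrix(ve)
  if (!is.null(band)) {
    if (is.null(fs)) stop("fs must be supplied for matrix input")
    M <- t(apply(M, 1, bandpass_vec, band = band, fs = fs))
  }
  list(response = colMeans(M), times = times)
}

#' Default overlapping TFS band set
#'
#' 5-Hz-wide bands stepped by 2.5 Hz spanning 1-150 Hz (clipped to the
#' Nyquist frequency when needed), tiling the range with no gaps.
#'
#' @param fmin,fmax Range to span, Hz.
#' @param width Band width, Hz.
#' @param step Band step, Hz.
#' @return Two-column matrix (low, high), Hz.
#' @export
tfs_bands <- function(fmin = 1, fmax = 150, width = 5, step = 2.5) {
  lows <- seq(fmin, fmax - width, by = step)
  if (max(lows) + width < fmax) lows <- c(lows, fmax - width)
  cbind(low = lows, high = lows + width)
}

#' Baseline-corrected time-frequency spectrogram
#'
#' Per band: envelope per trial, trial average, then relative change
#' against the control-window mean:
#' `(E(t) - mean(E[control])) / mean(E[control])`. Bands whose control
#' mean is zero are marked invalid (`NA`) rather than infinite.
#'
#' @param ve A [virtual_electrode()] (broadband) with multi-trial data.
#' @param bands Two-column matrix of Hz intervals; default [tfs_bands()]
#'   clipped to Nyquist.
#' @param control_window Length-2 seconds interval inside the epoch
#'   window.
#' @return Object of class `opm_tfs`: `values` (bands x times, relative
#'   amplitude change), `bands`, `times`, `control_window`.
#' @export
time_frequency_spectrogram <- function(ve, bands = NULL, control_window) {
  if (!inherits(ve, "virtual_electrode"))
    stop("ve must be a virtual_electrode")
  fs <- ve$sample_rate
  if (is.null(bands))
    bands <- tfs_bands(fmax = min(150, 0.95 * fs / 2))
  times <- ve$times
  if (control_window[1] < times[1] ||
      control_window[2] > times[length(times)] + 1 / fs)
    stop("control window lies outside the epoch window")
  ctrl <- times >= control_window[1] & times < control_window[2]
  vals <- matrix(NA_real_, nrow(bands), length(times))
  for (b in seq_len(nrow(bands))) {
    env <- hilbert_envelope(ve, bands[b, ])$envelope
    m <- mean(env[ctrl])
    if (m > 0) vals[b, ] <- (env - m) / m
  }
  structure(list(values = vals, bands = bands, times = times,
                 control_window = control_window),
            class = "opm_tfs")
}

#' @export
print.opm_tfs <- function(x, ...) {
  cat(sprintf("<opm_tfs> %d bands x %d time points, control [%g, %g] s\n",
              nrow(x$values), ncol(x$values),
              x$control_window[1], x$control_window[2]))
  invisible(x)
}
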