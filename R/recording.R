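# The Recording container: channels x samples field data in tesla, with
# trigger events, railing flags, the sensor array, and provenance.

#' Construct a recording
#'
#' @param data Channels x samples numeric matrix, tesla.
#' @param sample_rate Sampling rate, Hz.
#' @param array The [sensor_array()] the data were "measured" with.
#' @param triggers Data frame with columns `code` (integer), `sample`
#'   (1-based onset sample index) and optionally `label`.
#' @param flags Optional channels x samples logical matrix of
#'   railed/out-of-range marks (`NULL` when clean).
#' @param truth Optional list of ground-truth quantities emitted by the
#'   simulators (source waveforms, dipole positions, background traces,
#'   burst tables) so downstream stages always have an oracle.
#' @param meta Optional named list of provenance entries (seed, loop mode,
#'   processing history).
#' @return Object of class `opm_recording`.
#' @export
opm_recording <- function(data, sample_rate, array, triggers = NULL,
                          flags = NULL, truth = NULL, meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != n_channels(array))
    stop("data rows must match the number of array channels")
  if (is.null(triggers))
    triggers <- data.frame(code = integer(), sample = integer(),
                           label = character())
  triggers <- as.data.frame(triggers)
  if (!"label" %in% names(triggers))
    triggers$label <- as.character(triggers$code)
  if (nrow(triggers) > 0 &&
      (any(triggers$sample < 1) || any(triggers$sample > ncol(data))))
    stop("trigger samples out of record bounds")
  structure(list(data = data, sample_rate = sample_rate, array = array,
                 triggers = triggers, flags = flags, truth = truth,
                 meta = meta),
            class = "opm_recording")
}

#' @export
print.opm_recording <- function(x, ...) {
  cat(sprintf(
    "<opm_recording> %d ch x %d samples (%.1f s @ %g Hz), %d triggers%s\n",
    nrow(x$data), ncol(x$data), ncol(x$data) / x$sample_rate,
    x$sample_rate, nrow(x$triggers),
    if (!is.null(x$flags)) sprintf(", %d flagged samples",
                                   sum(colSums(x$flags) > 0)) else ""))
  invisible(x)
}

#' Trigger onset samples for one code
#'
#' @param rec An [opm_recording()].
#' @param code Integer trigger code.
#' @return Integer vector of onset sample indices.
#' @export
trigger_samples <- function(rec, code) {
  rec$triggers$sample[rec$triggers$code == code]
}

#' Epoched data
#'
#' @param data Trials x channels x samples array.
#' @param window Length-2 numeric, seconds relative to the trigger
#'   (half-open interval `[t0, t1)`).
#' @param sample_rate Hz.
#' @param retained_trial_ids Integer ids of the trials present.
#' @param retained_channel_ids Integer ids of the channels present.
#' @param array Optional [sensor_array()] reference.
#' @param band Optional length-2 Hz interval describing prior filtering.
#' @return Object of class `opm_epochs`.
#' @export
opm_epochs <- function(data, window, sample_rate,
                       retained_trial_ids = seq_len(dim(data)[1]),
                       retained_channel_ids = seq_len(dim(data)[2]),
                       array = NULL, band = NULL) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, window = window, sample_rate = sample_rate,
                 retained_trial_ids = retained_trial_ids,
                 retained_channel_ids = retained_channel_ids,
                 array = array, band = band),
            class = "opm_epochs")
}

#' @export
print.opm_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<opm_epochs> %d trials x %d ch x %d samples, window [%g, %g) s\n",
              d[1], d[2], d[3], x$window[1], x$window[2]))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

epoch_times <- function(ep) {
  ep$window[1] + (seq_len(dim(ep$data)[3]) - 1) / ep$sample_rate
}
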