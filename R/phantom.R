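# Phantom analysis: per-burst 17-Hz amplitude extraction, open-vs-closed
# linearity comparison, and background-field error statistics.

#' Extract per-burst 17-Hz amplitudes
#'
#' Segments the recording into phantom-active periods using the trigger
#' signal and computes, per burst and channel, the discrete Fourier
#' magnitude at the 17-Hz bin, scaled (2/N convention) so that a pure
#' sinusoid of amplitude A reports A. The burst length must hold an
#' integer number of 17-Hz cycles (2 s = 34 cycles), which puts the drive
#' exactly on a DFT bin.
#'
#' @param rec A phantom [opm_recording()].
#' @param trigger_code Trigger marking burst onsets (default 6,
#'   "phantom_on").
#' @param burst_length Seconds of drive per burst (default 2).
#' @param drive_freq Drive frequency, Hz (default 17).
#' @return A `burst_amplitude_table` data frame with columns
#'   `channel_id`, `burst_index`, `condition` ("open"/"closed"), `level`,
#'   `level_unit`, `amplitude_17Hz` (tesla).
#' @export
extract_burst_amplitudes <- function(rec, trigger_code = 6L,
                                     burst_length = 2, drive_freq = 17) {
  fs <- rec$sample_rate
  N <- round(burst_length * fs)
  k <- drive_freq * N / fs
  if (abs(k - round(k)) > 1e-9)
    stop("burst_length must hold an integer number of drive cycles")
  k <- round(k)
  onsets <- trigger_samples(rec, trigger_code)
  if (length(onsets) == 0) stop("no phantom-active triggers found")
  if (any(onsets + N - 1L > ncol(rec$data)))
    stop("truncation error: burst extends past the end of the record")
  nch <- nrow(rec$data)
  phasor <- exp(-2i * pi * k * (seq_len(N) - 1) / N)
  amp <- matrix(0, nch, length(onsets))
  for (b in seq_along(onsets)) {
    seg <- rec$data[, onsets[b]:(onsets[b] + N - 1L), drop = FALSE]
    amp[, b] <- (2 / N) * Mod(seg %*% phasor)
  }
  cond <- if (identical(rec$meta$loop_mode, "closed")) "closed" else "open"
  lev <- rec$truth$bursts$level
  lev_unit <- rec$truth$bursts$level_unit
  if (is.null(lev)) {
    lev <- rep(NA_real_, length(onsets))
    lev_unit <- NA_character_
  }
  out <- data.frame(
    channel_id = rep(seq_len(nch), times = length(onsets)),
    burst_index = rep(seq_along(onsets), each = nch),
    condition = cond,
    level = rep(lev, each = nch),
    level_unit = if (length(lev_unit) == 1) lev_unit else
      rep(lev_unit, each = nch),
    amplitude_17Hz = as.numeric(amp))
  class(out) <- c("burst_amplitude_table", "data.frame")
  out
}

#' Open- vs closed-loop linearity comparison
#'
#' Pairs burst amplitudes by (channel, burst) across the two conditions
#' and fits closed-loop amplitude against open-loop amplitude by least
#' squares. In low background fields the two operating modes measure the
#' same field, so the fit should sit on the line of equality.
#'
#' @param table_open,table_closed `burst_amplitude_table`s from the two
#'   conditions of the same protocol.
#' @return List with `slope`, `intercept` (tesla), `r_squared`, and the
#'   paired data frame `pairs` (columns `open`, `closed`).
#' @export
linearity_comparison <- function(table_open, table_closed) {
  key_o <- paste(table_open$channel_id, table_open$burst_index)
  key_c <- paste(table_closed$channel_id, table_closed$burst_index)
  if (length(key_o) != length(key_c) || !setequal(key_o, key_c))
    stop("pairing error: tables do not share (channel, burst) keys")
  m <- match(key_o, key_c)
  pairs <- data.frame(open = table_open$amplitude_17Hz,
                      closed = table_closed$amplitude_17Hz[m])
  fit <- stats::lm(closed ~ open, data = pairs)
  # identical tables fit perfectly; summary.lm warns about that, harmlessly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       pairs = pairs)
}

#' Background-field error statistics
#'
#' For the `top_k` channels with the largest zero-background amplitude,
#' subtracts each channel's mean zero-background amplitude (the best
#' assessment of the true value) from every measurement and reports the
#' percent deviation pooled over channels, bursts and nonzero background
#' levels:
#' `error = 100 * |A(level) - mean A(0)| / mean A(0)` (absolute by
#' default; `signed = TRUE` keeps the sign).
#'
#' @param table A sweep `burst_amplitude_table` (must include
#'   zero-background bursts).
#' @param top_k Number of best-coupled channels to pool (default 10).
#' @param signed Keep the sign of the deviation instead of its magnitude.
#' @return List with `mean_percent`, `sd_percent`, `channels` (selected
#'   channel ids), and `errors` (data frame of per-measurement percent
#'   errors).
#' @export
background_error_stats <- function(table, top_k = 10, signed = FALSE) {
  nch <- length(unique(table$channel_id))
  if (top_k > nch)
    stop("parameter error: top_k exceeds the number of channels")
  zero <- table[table$level == 0, ]
  if (nrow(zero) == 0)
    stop("table includes no zero-background bursts")
  base <- tapply(zero$amplitude_17Hz, zero$channel_id, mean)
  sel <- as.integer(names(sort(base, decreasing = TRUE)[seq_len(top_k)]))
  nonzero <- table[table$level != 0 & table$channel_id %in% sel, ]
  a0 <- base[as.character(nonzero$channel_id)]
  err <- 100 * (nonzero$amplitude_17Hz - a0) / a0
  if (!signed) err <- abs(err)
  list(mean_percent = mean(err), sd_percent = stats::sd(err),
       channels = sel,
       errors = data.frame(channel_id = nonzero$channel_id,
                           burst_index = nonzero$burst_index,
                           level = nonzero$level, percent_error = err,
                           row.names = NULL))
}
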