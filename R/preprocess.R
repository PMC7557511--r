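#' Butterworth band-pass filtering
#'
#' Applies a Butterworth band-pass per channel, replicating the acquisition
#' chain that keeps facial-EMG content in the 50-500 Hz range. Offline the
#' filter runs forward-backward (zero phase), so epochs are not shifted by
#' group delay; set `zero_phase = FALSE` for the causal single-pass variant
#' used by the online simulator.
#'
#' With a 1000 Hz sampling rate the nominal 500 Hz upper edge sits exactly at
#' Nyquist, where a band-pass design is degenerate (and near-Nyquist designs
#' are numerically fragile). When `high >= 0.999 * Nyquist` the filter is
#' therefore realized as the high-pass at `low` alone; any smaller `high`
#' gives a true band-pass.
#'
#' @param rec `emg_recording`.
#' @param low,high Band edges in Hz; `0 < low < high <= Nyquist`.
#' @param order Butterworth order (default 4).
#' @param zero_phase Forward-backward filtering if `TRUE` (default).
#' @return Filtered `emg_recording`; the applied filter is recorded in the
#'   `filters` metadata.
#' @export
apply_bandpass <- function(rec, low = 50, high = 500, order = 4,
                           zero_phase = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- nyquist(rec)
  if (low <= 0 || low >= high) stop("need 0 < low < high", call. = FALSE)
  if (high > nyq) {
    stop("band edge ", high, " Hz is above the Nyquist frequency (", nyq,
         " Hz)", call. = FALSE)
  }
  if (low >= nyq) {
    stop("band edge ", low, " Hz is at/above the Nyquist frequency (", nyq,
         " Hz)", call. = FALSE)
  }
  filt <- design_bandpass(low, high, order, rec$sampling_rate)
  rec$signal <- filter_rows(rec$signal, filt, zero_phase)
  rec$filters <- c(rec$filters, list(list(
    kind = "bandpass", low = low, high = high, order = order,
    zero_phase = zero_phase)))
  rec
}

design_bandpass <- function(low, high, order, fs) {
  nyq <- fs / 2
  if (high >= 0.999 * nyq) {
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  }
}

#' Mains notch filtering
#'
#' Second-order IIR notch (constrained biquad with zeros on the unit circle
#' at the notch frequency) applied per channel, zero phase by default.
#' Default 50 Hz targets mains interference; `q` is the quality factor, i.e.
#' notch centre / -3 dB bandwidth, so q = 30 gives a ~1.7 Hz-wide notch.
#'
#' @param rec `emg_recording`.
#' @param freq Notch frequency in Hz, below Nyquist.
#' @param q Quality factor (> 0), default 30.
#' @param zero_phase Forward-backward filtering if `TRUE` (default).
#' @return Filtered `emg_recording`.
#' @export
apply_notch <- function(rec, freq = 50, q = 30, zero_phase = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- nyquist(rec)
  if (freq <= 0 || freq >= nyq) {
    stop("notch frequency must lie in (0, ", nyq, ") Hz (below Nyquist)",
         call. = FALSE)
  }
  if (q <= 0) stop("q must be > 0", call. = FALSE)
  filt <- design_notch(freq, q, rec$sampling_rate)
  rec$signal <- filter_rows(rec$signal, filt, zero_phase)
  rec$filters <- c(rec$filters, list(list(
    kind = "notch", freq = freq, q = q, zero_phase = zero_phase)))
  rec
}

# Standard audio-EQ-cookbook notch biquad.
design_notch <- function(freq, q, fs) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

filter_rows <- function(x, filt, zero_phase) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (zero_phase) {
      signal::filtfilt(filt, x[i, ])
    } else {
      as.numeric(signal::filter(filt, x[i, ]))
    }
  }
  out
}

#' Cut labeled action epochs out of a recording
#'
#' Extracts one epoch per event, spanning `[onset, onset + action_s)`; the
#' label and session/trial provenance are carried over from the event table.
#' No baseline correction is applied.
#'
#' @param rec `emg_recording` or `emg_dataset`.
#' @param timeline `trial_timeline`; `action_s` fixes the epoch length.
#' @return List of `emg_epoch` objects, one per event (possibly empty). Each
#'   epoch holds `signal` (channels x window samples), `label`,
#'   `sampling_rate`, `session`, `trial`.
#' @export
#' @examples
#' ds <- synthesize_dataset(session_plan(1, 1), seed = 1)
#' ep <- extract_epochs(ds)
#' length(ep); dim(ep[[1]]$signal)  # 4 trials, 4 x 1500
extract_epochs <- function(rec, timeline = trial_timeline()) {
  if (inherits(rec, "emg_dataset")) rec <- rec$recording
  stopifnot(inherits(rec, "emg_recording"))
  n_win <- round(timeline$action_s * rec$sampling_rate)
  ev <- rec$events
  if (nrow(ev) == 0) return(list())
  lapply(seq_len(nrow(ev)), function(i) {
    on <- ev$onset_sample[i]
    if (on < 1 || on + n_win - 1 > ncol(rec$signal)) {
      stop("epoch window for trial ", i, " lies outside the recording",
           call. = FALSE)
    }
    structure(
      list(signal = rec$signal[, on + seq_len(n_win) - 1L, drop = FALSE],
           label = ev$label[i], sampling_rate = rec$sampling_rate,
           session = if ("session" %in% names(ev)) ev$session[i] else NA,
           trial = if ("trial" %in% names(ev)) ev$trial[i] else i),
      class = "emg_epoch"
    )
  })
}

#' Offline preprocessing chain
#'
#' Convenience wrapper: band-pass then notch, both zero phase, with the
#' defaults of the acquisition chain (50-500 Hz band, order 4, 50 Hz notch at
#' q = 30).
#'
#' @inheritParams apply_bandpass
#' @param notch_freq,q Notch parameters; set `notch_freq = NULL` to skip.
#' @return Filtered `emg_recording`.
#' @export
preprocess_recording <- function(rec, low = 50, high = 500, order = 4,
                                 notch_freq = 50, q = 30, zero_phase = TRUE) {
  rec <- apply_bandpass(rec, low, high, order, zero_phase)
  if (!is.null(notch_freq)) rec <- apply_notch(rec, notch_freq, q, zero_phase)
  rec
}
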