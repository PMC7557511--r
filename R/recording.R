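#' Recording configuration
#'
#' Describes the acquisition montage the decoder expects: scalp electrodes
#' close to the facial musculature sampled at 1000 Hz. The four recording
#' channels default to F7/F8/FC5/FC6 (10-20 positions over the left/right
#' inferior frontal and fronto-central scalp); CPz serves as reference and
#' AFz as ground. Reference and ground are metadata only -- no re-referencing
#' is performed.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Ordered, duplicate-free character vector of channel names.
#' @param reference,ground Electrode names kept as metadata.
#' @return An object of class `emg_config`.
#' @export
recording_config <- function(sampling_rate = 1000,
                             channels = c("F7", "F8", "FC5", "FC6"),
                             reference = "CPz", ground = "AFz") {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number", call. = FALSE)
  }
  if (length(channels) == 0 || anyDuplicated(channels)) {
    stop("channels must be non-empty and duplicate-free", call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate, channels = channels,
         reference = reference, ground = ground),
    class = "emg_config"
  )
}

#' Trial timeline
#'
#' One trial lasts `prep_s + action_s + break_s` seconds: a preparation cue,
#' the facial-action hold, and a break. Defaults reproduce the 3.5 s trial
#' (1 s + 1.5 s + 1 s); the 1.5 s action segment is the unit of feature
#' extraction and of each online control decision.
#'
#' @param prep_s,action_s,break_s Segment durations in seconds, all > 0.
#' @return An object of class `trial_timeline`.
#' @export
trial_timeline <- function(prep_s = 1.0, action_s = 1.5, break_s = 1.0) {
  if (any(c(prep_s, action_s, break_s) <= 0)) {
    stop("all timeline durations must be > 0", call. = FALSE)
  }
  structure(
    list(prep_s = prep_s, action_s = action_s, break_s = break_s,
         total_s = prep_s + action_s + break_s),
    class = "trial_timeline"
  )
}

#' Session plan for the offline protocol
#'
#' The offline protocol records `n_sessions` sessions; within each session
#' every one of the four actions is performed `trials_per_action` times, in
#' randomized order. Defaults give 10 x 6 = 60 trials per action and 240
#' trials in total.
#'
#' @param n_sessions Number of sessions (> 0).
#' @param trials_per_action Trials of each action per session (> 0).
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(n_sessions = 10, trials_per_action = 6) {
  if (n_sessions < 1 || trials_per_action < 1) {
    stop("n_sessions and trials_per_action must both be >= 1", call. = FALSE)
  }
  structure(
    list(n_sessions = as.integer(n_sessions),
         trials_per_action = as.integer(trials_per_action),
         trials_per_action_total = as.integer(n_sessions * trials_per_action)),
    class = "session_plan"
  )
}

#' Multi-channel EMG recording container
#'
#' Bundles a channels x samples signal matrix with its sampling rate, an
#' event table marking action-window onsets, and the acquisition config.
#' Events carry `onset_sample` (1-based index of the first action sample),
#' `duration_samples` and `label`, plus session/trial provenance when the
#' recording comes from [synthesize_dataset()].
#'
#' @param signal Numeric matrix, channels x samples; row names are channel
#'   names (filled from `config` if absent).
#' @param sampling_rate Sampling rate in Hz.
#' @param events Data frame with columns `onset_sample`, `duration_samples`,
#'   `label` (and optionally `session`, `trial`); may be empty.
#' @param config An `emg_config` (optional metadata).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, sampling_rate, events = NULL, config = NULL) {
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (is.null(events)) {
    events <- data.frame(onset_sample = integer(), duration_samples = integer(),
                         label = character())
  }
  if (!is.null(config) && is.null(rownames(signal))) {
    rownames(signal) <- config$channels
  }
  if (nrow(events) > 0) {
    if (is.unsorted(events$onset_sample)) {
      events <- events[order(events$onset_sample), , drop = FALSE]
    }
    last <- events$onset_sample + events$duration_samples - 1L
    if (any(events$onset_sample < 1L) || any(last > ncol(signal))) {
      stop("event window extends outside the recording", call. = FALSE)
    }
  }
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         events = events, config = config, filters = list()),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) x %d samples @ %g Hz, %d event(s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate, nrow(x$events)))
  if (length(x$filters)) {
    cat("  filters applied:", paste(vapply(x$filters, `[[`, "", "kind"),
                                    collapse = ", "), "\n")
  }
  invisible(x)
}

nyquist <- function(rec_or_fs) {
  fs <- if (inherits(rec_or_fs, "emg_recording")) rec_or_fs$sampling_rate else rec_or_fs
  fs / 2
}
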