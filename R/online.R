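#' Map a recognized facial action to a prosthesis command
#'
#' The command mapping: raising the brow opens the hand, furrowing the brow
#' closes it, a left smirk rotates the wrist to the right and a right smirk
#' rotates it to the left. The mapping is a bijection over the four actions.
#'
#' @param action One of [action_classes()] (vectorized).
#' @return Character vector of commands: `hand_open`, `hand_close`,
#'   `wrist_rotate_right`, `wrist_rotate_left`.
#' @export
action_to_command <- function(action) {
  map <- c(raising_brow = "hand_open", furrowing_brow = "hand_close",
           left_smirking = "wrist_rotate_right",
           right_smirking = "wrist_rotate_left")
  bad <- setdiff(unique(action), names(map))
  if (length(bad) > 0) {
    stop("unknown facial action(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[action])
}

#' 2-DOF prosthesis state
#'
#' The prosthesis has two degrees of freedom: a hand that is either open or
#' closed, and a wrist orientation on a bounded discrete range of rotation
#' steps (default -2..+2, rightward positive). The state only changes when a
#' command is delivered and otherwise holds its previous gesture.
#'
#' @param hand `"open"` or `"closed"`.
#' @param wrist Integer orientation step within `bounds`.
#' @param bounds Length-2 integer vector, inclusive wrist range.
#' @return Object of class `prosthesis_state`.
#' @export
prosthesis_state <- function(hand = "open", wrist = 0L, bounds = c(-2L, 2L)) {
  hand <- match.arg(hand, c("open", "closed"))
  stopifnot(bounds[1] <= bounds[2], wrist >= bounds[1], wrist <= bounds[2])
  structure(list(hand = hand, wrist = as.integer(wrist),
                 bounds = as.integer(bounds)),
            class = "prosthesis_state")
}

#' Advance the prosthesis state machine by one command
#'
#' Hand commands set the hand field (idempotently); wrist commands move the
#' orientation one step and saturate at the bounds. A `NULL` command leaves
#' the state untouched.
#'
#' @param state `prosthesis_state`.
#' @param cmd A command from [action_to_command()], or `NULL`.
#' @return The new `prosthesis_state`.
#' @export
step_prosthesis <- function(state, cmd) {
  stopifnot(inherits(state, "prosthesis_state"))
  if (is.null(cmd)) return(state)
  switch(cmd,
    hand_open = { state$hand <- "open" },
    hand_close = { state$hand <- "closed" },
    wrist_rotate_right = {
      state$wrist <- min(state$wrist + 1L, state$bounds[2]) },
    wrist_rotate_left = {
      state$wrist <- max(state$wrist - 1L, state$bounds[1]) },
    stop("unknown command: ", cmd, call. = FALSE)
  )
  state
}

# Predict actions from a feature matrix with either a fitted classifier or a
# plain function(features) -> labels (used for stub/chance baselines).
predict_actions <- function(classifier, features) {
  if (is.function(classifier)) classifier(features)
  else predict(classifier, features)
}

#' Stream decisions over consecutive 1.5 s windows
#'
#' Online decoding: each cued action window is filtered causally (single-pass
#' band-pass + notch, the real-time counterpart of the offline zero-phase
#' chain), reduced to its FFT band-energy features and classified; one
#' decision is emitted at the end of each window. Each window is processed
#' in isolation, so a decision depends only on that window's samples.
#' Windows are taken from the recording's events when present, otherwise the
#' stream is tiled with non-overlapping windows from the first sample.
#'
#' A decision's `confidence` is the mean distance of the two outputs from
#' the 0.5 threshold, scaled to \[0, 1\]. Windows are flagged
#' `low_confidence` when that distance falls below 0.1 or when the window is
#' degenerate (zero feature energy, e.g. an all-zero signal), since the
#' classifier's output is then meaningless extrapolation.
#'
#' @param stream `emg_recording`.
#' @param classifier `facemyo_classifier`, or a function mapping a feature
#'   matrix to labels.
#' @param window_s Decision-window length in seconds (default 1.5).
#' @param band,order,notch_freq,q Causal preprocessing parameters.
#' @param bands Feature bands.
#' @return Data frame: `window`, `onset_sample`, `truth` (`NA` when the
#'   stream has no events), `prediction`, `confidence`, `low_confidence`.
#' @export
stream_decide <- function(stream, classifier, window_s = 1.5,
                          band = c(50, 500), order = 4,
                          notch_freq = 50, q = 30,
                          bands = default_bands()) {
  stopifnot(inherits(stream, "emg_recording"))
  fs <- stream$sampling_rate
  n_win <- round(window_s * fs)
  if (ncol(stream$signal) < n_win) {
    stop("stream is shorter than one decision window", call. = FALSE)
  }
  if (nrow(stream$events) > 0) {
    onsets <- stream$events$onset_sample
    truths <- stream$events$label
  } else {
    onsets <- seq(1L, ncol(stream$signal) - n_win + 1L, by = n_win)
    truths <- rep(NA_character_, length(onsets))
  }
  bp <- design_bandpass(band[1], band[2], order, fs)
  nf <- if (!is.null(notch_freq)) design_notch(notch_freq, q, fs) else NULL
  feats <- matrix(NA_real_, length(onsets),
                  length(bands) * nrow(stream$signal))
  conf <- numeric(length(onsets))
  for (w in seq_along(onsets)) {
    win <- stream$signal[, onsets[w] + seq_len(n_win) - 1L, drop = FALSE]
    for (i in seq_len(nrow(win))) {
      y <- as.numeric(signal::filter(bp, win[i, ]))
      if (!is.null(nf)) y <- as.numeric(signal::filter(nf, y))
      win[i, ] <- y
    }
    ep <- structure(list(signal = win, label = NA_character_,
                         sampling_rate = fs), class = "emg_epoch")
    feats[w, ] <- fft_band_energy(ep, bands)
  }
  preds <- predict_actions(classifier, feats)
  degenerate <- rowSums(feats) == 0
  if (inherits(classifier, "facemyo_classifier")) {
    O <- classifier_outputs(classifier, feats)
    conf <- rowMeans(abs(2 * O - 1))
  } else {
    conf <- rep(NA_real_, length(onsets))
  }
  data.frame(window = seq_along(onsets), onset_sample = onsets,
             truth = truths, prediction = preds, confidence = conf,
             low_confidence = (!is.na(conf) & conf < 0.1) | degenerate)
}

#' Simulate one cued drinking-task session
#'
#' Synthesizes the cued EMG stream for a preset action sequence (one trial
#' per cue, using the same per-class profiles as the offline generator),
#' decodes it window by window with [stream_decide()], maps each decision to
#' its prosthesis command and advances the hand/wrist state machine. The
#' default sequence is one drinking cycle: open the hand, close it around
#' the cup, tip the wrist right to drink, rotate back left.
#'
#' Session accuracy is the percentage of decisions matching the preset
#' sequence; the task is complete when every decision was correct (the
#' prosthesis then traversed exactly the intended gesture trajectory).
#'
#' @param classifier `facemyo_classifier` or stub function.
#' @param sequence Preset action sequence (labels from [action_classes()]).
#' @param timeline `trial_timeline` for each cue.
#' @param config `emg_config`.
#' @param seed Integer seed for the synthesized stream.
#' @param asymmetry,band_contrast,baseline_rms,action_rms Generator
#'   parameters, as in [synthesize_dataset()].
#' @param initial_state Starting `prosthesis_state`.
#' @return Object of class `facemyo_online`: `decisions` (data frame with
#'   truth, prediction, command and the resulting hand/wrist state per
#'   window), `accuracy` (percent), `completed` flag and the final state.
#' @export
run_drinking_task <- function(classifier,
                              sequence = c("raising_brow", "furrowing_brow",
                                           "left_smirking", "right_smirking"),
                              timeline = trial_timeline(),
                              config = recording_config(), seed = 1,
                              asymmetry = 2.0, band_contrast = 0.3,
                              baseline_rms = 0.1, action_rms = 1.0,
                              initial_state = prosthesis_state()) {
  if (length(sequence) == 0) stop("sequence must be non-empty", call. = FALSE)
  lapply(sequence, assert_action)
  set.seed(as.integer(seed))
  n_trial <- round(timeline$total_s * config$sampling_rate)
  sig <- matrix(0, length(config$channels), n_trial * length(sequence),
                dimnames = list(config$channels, NULL))
  events <- vector("list", length(sequence))
  for (i in seq_along(sequence)) {
    prof <- make_action_profile(sequence[i], asymmetry = asymmetry,
                                band_contrast = band_contrast,
                                baseline_rms = baseline_rms,
                                action_rms = action_rms, config = config)
    trial <- synthesize_trial(prof, timeline, config, seed = NULL)
    off <- (i - 1L) * n_trial
    sig[, off + seq_len(n_trial)] <- trial$signal
    events[[i]] <- data.frame(onset_sample = off + trial$events$onset_sample,
                              duration_samples = trial$events$duration_samples,
                              label = sequence[i])
  }
  stream <- emg_recording(sig, config$sampling_rate, do.call(rbind, events),
                          config)
  dec <- stream_decide(stream, classifier, window_s = timeline$action_s)
  dec$command <- action_to_command(dec$prediction)
  state <- initial_state
  hand <- character(nrow(dec)); wrist <- integer(nrow(dec))
  for (i in seq_len(nrow(dec))) {
    state <- step_prosthesis(state, dec$command[i])
    hand[i] <- state$hand
    wrist[i] <- state$wrist
  }
  dec$hand <- hand
  dec$wrist <- wrist
  correct <- dec$prediction == dec$truth
  structure(
    list(decisions = dec, accuracy = 100 * mean(correct),
         completed = all(correct), final_state = state,
         sequence = sequence, seed = seed),
    class = "facemyo_online"
  )
}

#' @export
print.facemyo_online <- function(x, ...) {
  cat(sprintf("<facemyo_online> %d decision(s), accuracy %.1f%%, task %s\n",
              nrow(x$decisions), x$accuracy,
              if (x$completed) "completed" else "not completed"))
  invisible(x)
}
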