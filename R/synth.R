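#' Spatial-spectral profile of one facial action
#'
#' The generator emulates what the decoder actually consumes from facial-EMG
#' recordings: per-channel amplitude (laterality) and the distribution of
#' signal power over the three analysis bands 64-128, 128-256 and 256-500 Hz.
#' Each action gets a profile of per-channel gains and per-band power
#' fractions:
#'
#' * `left_smirking` boosts the left-hemisphere channels (F7, FC5) by the
#'   `asymmetry` ratio; `right_smirking` is its exact mirror under the swap
#'   F7<->F8, FC5<->FC6. Both share the same band fractions.
#' * `raising_brow` and `furrowing_brow` are bilateral (all gains equal) and
#'   differ spectrally: the brow raise leans toward the low band, the furrow
#'   toward the high band, and `band_contrast` widens that split. With the
#'   shift `d = band_contrast / 2`, raising has fractions
#'   `(0.40 + d, 0.35, 0.25 - d)` and furrowing `(0.25 - d, 0.35, 0.40 + d)`,
#'   so their L1 distance is `2 * (0.15 + band_contrast)`.
#'
#' The profile also carries the baseline (rest) noise RMS and the overall
#' action RMS in the same arbitrary amplitude units.
#'
#' @param action One of [action_classes()].
#' @param asymmetry Left/right gain ratio for the smirk classes (>= 1).
#' @param band_contrast Extra spectral separation between the two brow
#'   classes (>= 0, <= 0.5 so fractions stay in \[0, 1\]).
#' @param baseline_rms RMS of the rest-state noise floor.
#' @param action_rms RMS of the action-window EMG burst on a unit-gain
#'   channel.
#' @param config `emg_config` naming the channels (defaults to the
#'   F7/F8/FC5/FC6 montage).
#' @return An object of class `action_profile` with fields `action`, `gains`
#'   (named per channel), `band_fractions` (sums to 1), `bands`,
#'   `baseline_rms`, `action_rms`.
#' @export
#' @examples
#' p <- make_action_profile("left_smirking", asymmetry = 2)
#' p$gains["F7"] / p$gains["F8"]  # == 2
make_action_profile <- function(action, asymmetry = 2.0, band_contrast = 0.3,
                                baseline_rms = 0.1, action_rms = 1.0,
                                config = recording_config()) {
  assert_action(action)
  if (asymmetry < 1) stop("asymmetry must be >= 1", call. = FALSE)
  if (band_contrast < 0 || band_contrast > 0.5) {
    stop("band_contrast must lie in [0, 0.5]", call. = FALSE)
  }
  ch <- config$channels
  left <- intersect(c("F7", "FC5"), ch)
  right <- intersect(c("F8", "FC6"), ch)
  gains <- stats::setNames(rep(1, length(ch)), ch)
  d <- band_contrast / 2
  fractions <- switch(action,
    left_smirking  = { gains[left] <- asymmetry; c(0.40, 0.40, 0.20) },
    right_smirking = { gains[right] <- asymmetry; c(0.40, 0.40, 0.20) },
    raising_brow   = c(0.40 + d, 0.35, 0.25 - d),
    furrowing_brow = c(0.25 - d, 0.35, 0.40 + d)
  )
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  structure(
    list(action = action, gains = gains, band_fractions = fractions,
         bands = default_bands(), baseline_rms = baseline_rms,
         action_rms = action_rms, asymmetry = asymmetry,
         band_contrast = band_contrast),
    class = "action_profile"
  )
}

# Band-limited Gaussian noise: white noise whose spectrum is zeroed outside
# [low, high) and which is rescaled to exactly the requested RMS. Frequency-
# domain construction keeps the power strictly inside the band (no filter
# skirts), which is what makes the generator's spectral contract testable.
band_noise <- function(n, fs, low, high, rms) {
  if (rms <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)          # frequency of each bin after folding
  keep <- f_fold >= low & f_fold < high
  keep[1] <- FALSE                   # never keep DC
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- sqrt(mean(y^2))
  if (s == 0) return(numeric(n))
  y * (rms / s)
}

# Raised-cosine on/off ramps (default 100 ms) applied to the action window so
# that the burst switches on smoothly and filter transients stay small.
onset_envelope <- function(n, fs, ramp_s = 0.1) {
  nr <- min(floor(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[n - nr + seq_len(nr)] <- rev(ramp)
  }
  env
}

#' Synthesize one trial of facial-action EMG
#'
#' Generates a prep / action / break trial for one action. The prep and break
#' segments contain only the baseline noise floor; during the action window
#' each channel additionally receives band-limited Gaussian noise in the
#' three analysis bands, scaled so the per-band power matches the profile's
#' band fractions and the channel's gain, and shaped by 100 ms raised-cosine
#' onset/offset ramps. One event marks the action onset.
#'
#' @param profile `action_profile` from [make_action_profile()].
#' @param timeline `trial_timeline`.
#' @param config `emg_config`; its channels must match the profile's gains.
#' @param seed Integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream (used by [synthesize_dataset()]).
#' @return An `emg_recording` of one trial with a single event.
#' @export
synthesize_trial <- function(profile, timeline = trial_timeline(),
                             config = recording_config(), seed = NULL) {
  stopifnot(inherits(profile, "action_profile"),
            inherits(timeline, "trial_timeline"))
  if (!setequal(names(profile$gains), config$channels)) {
    stop("profile channels do not match the recording config", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || seed != round(seed)) {
      stop("seed must be an integer (or NULL to use the current RNG state)",
           call. = FALSE)
    }
    set.seed(as.integer(seed))
  }
  fs <- config$sampling_rate
  if (fs < 2 * max(unlist(profile$bands))) {
    stop("sampling rate must exceed twice the highest synthesized frequency",
         call. = FALSE)
  }
  n_prep <- round(timeline$prep_s * fs)
  n_act <- round(timeline$action_s * fs)
  n_break <- round(timeline$break_s * fs)
  n_tot <- n_prep + n_act + n_break
  env <- onset_envelope(n_act, fs)
  sig <- matrix(0, nrow = length(config$channels), ncol = n_tot,
                dimnames = list(config$channels, NULL))
  for (ch in config$channels) {
    base <- if (profile$baseline_rms > 0) {
      stats::rnorm(n_tot, sd = profile$baseline_rms)
    } else numeric(n_tot)
    burst <- numeric(n_act)
    g <- profile$gains[[ch]]
    if (g > 0 && profile$action_rms > 0) {
      for (b in seq_along(profile$bands)) {
        frac <- profile$band_fractions[b]
        if (frac <= 0) next
        rms_b <- profile$action_rms * g * sqrt(frac)
        burst <- burst + band_noise(n_act, fs, profile$bands[[b]][1],
                                    profile$bands[[b]][2], rms_b)
      }
    }
    base[n_prep + seq_len(n_act)] <- base[n_prep + seq_len(n_act)] + burst * env
    sig[ch, ] <- base
  }
  events <- data.frame(onset_sample = n_prep + 1L,
                       duration_samples = n_act,
                       label = profile$action)
  emg_recording(sig, fs, events, config)
}

#' Synthesize a full offline dataset
#'
#' Emits the complete offline protocol as one continuous recording: for each
#' session, `trials_per_action` trials of each of the four actions in a
#' randomized order, each trial following `timeline`. Returns the recording
#' (with one event per trial) plus a label table. Fully deterministic under
#' `seed`.
#'
#' @param plan `session_plan`.
#' @param timeline `trial_timeline`.
#' @param config `emg_config`.
#' @param seed Integer seed.
#' @param asymmetry,band_contrast,baseline_rms,action_rms Passed to
#'   [make_action_profile()] for every class.
#' @return An object of class `emg_dataset`: list with `recording`
#'   (`emg_recording`), `labels` (data frame: `onset_sample`,
#'   `duration_samples`, `label`, `session`, `trial`), `profiles`, `plan`,
#'   `timeline`, `seed`.
#' @export
#' @examples
#' ds <- synthesize_dataset(session_plan(1, 1), seed = 1)
#' nrow(ds$labels)  # 4 trials
synthesize_dataset <- function(plan = session_plan(),
                               timeline = trial_timeline(),
                               config = recording_config(), seed = 1,
                               asymmetry = 2.0, band_contrast = 0.3,
                               baseline_rms = 0.1, action_rms = 1.0) {
  stopifnot(inherits(plan, "session_plan"))
  set.seed(as.integer(seed))
  profiles <- lapply(action_classes(), make_action_profile,
                     asymmetry = asymmetry, band_contrast = band_contrast,
                     baseline_rms = baseline_rms, action_rms = action_rms,
                     config = config)
  names(profiles) <- action_classes()
  n_trial <- round(timeline$total_s * config$sampling_rate)
  seq_per_session <- rep(action_classes(), each = plan$trials_per_action)
  n_per_session <- length(seq_per_session)
  n_total <- plan$n_sessions * n_per_session
  sig <- matrix(0, nrow = length(config$channels), ncol = n_total * n_trial,
                dimnames = list(config$channels, NULL))
  labels <- vector("list", n_total)
  k <- 0L
  for (s in seq_len(plan$n_sessions)) {
    order_s <- sample(seq_per_session)
    for (a in order_s) {
      k <- k + 1L
      trial <- synthesize_trial(profiles[[a]], timeline, config, seed = NULL)
      off <- (k - 1L) * n_trial
      sig[, off + seq_len(n_trial)] <- trial$signal
      labels[[k]] <- data.frame(
        onset_sample = off + trial$events$onset_sample,
        duration_samples = trial$events$duration_samples,
        label = a, session = s, trial = k)
    }
  }
  labels <- do.call(rbind, labels)
  rec <- emg_recording(sig, config$sampling_rate, labels, config)
  structure(
    list(recording = rec, labels = labels, profiles = profiles, plan = plan,
         timeline = timeline, config = config, seed = seed),
    class = "emg_dataset"
  )
}

#' Inject a sinusoidal mains-interference tone
#'
#' Adds a fixed-frequency sinusoid (50 Hz mains by default) with a random
#' phase per channel to every sample of the recording, leaving everything
#' else untouched. Used to exercise the notch filter.
#'
#' @param rec `emg_recording`.
#' @param freq Interference frequency in Hz, must be below Nyquist.
#' @param amplitude Peak amplitude of the tone; 0 returns the input exactly.
#' @param seed Integer seed for the per-channel phases.
#' @return The recording with the tone added.
#' @export
inject_interference <- function(rec, freq = 50, amplitude = 1, seed = 1) {
  stopifnot(inherits(rec, "emg_recording"))
  if (freq <= 0 || freq >= nyquist(rec)) {
    stop("interference frequency must lie in (0, ", nyquist(rec),
         ") Hz (below Nyquist)", call. = FALSE)
  }
  if (amplitude == 0) return(rec)
  set.seed(as.integer(seed))
  n <- ncol(rec$signal)
  t <- (seq_len(n) - 1) / rec$sampling_rate
  for (i in seq_len(nrow(rec$signal))) {
    phase <- stats::runif(1, 0, 2 * pi)
    rec$signal[i, ] <- rec$signal[i, ] + amplitude * sin(2 * pi * freq * t + phase)
  }
  rec
}
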