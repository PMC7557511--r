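#' Default analysis bands
#'
#' The decoder summarizes each channel by the signal energy in three
#' frequency bands. The nominal bands are 64-128, 128-256 and 256-512 Hz; at
#' a 1000 Hz sampling rate the top edge is capped at the 500 Hz Nyquist
#' frequency, so the default third band is 256-500 Hz. Bands are half-open
#' `[low, high)` so the shared edges at 128 and 256 Hz are never counted
#' twice.
#'
#' @return List of three `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(c(64, 128), c(128, 256), c(256, 500))
}

band_names <- function(bands) {
  vapply(bands, function(b) paste0(b[1], "-", b[2], "Hz"), "")
}

validate_bands <- function(bands, fs) {
  edges <- unlist(bands)
  if (any(edges <= 0) || any(edges > fs / 2)) {
    stop("band edges must lie in (0, Nyquist = ", fs / 2, " Hz]",
         call. = FALSE)
  }
  for (b in bands) if (b[1] >= b[2]) stop("band low must be < high", call. = FALSE)
  lows <- vapply(bands, `[`, 0, 1)
  highs <- vapply(bands, `[`, 0, 2)
  if (is.unsorted(lows, strictly = TRUE) || any(highs[-length(bands)] > lows[-1])) {
    stop("bands must be ascending and non-overlapping", call. = FALSE)
  }
  invisible(bands)
}

#' FFT band-energy features
#'
#' The primary feature set: per channel, the discrete Fourier transform of
#' the raw (unwindowed, untapered) epoch is taken and, for each band, the
#' squared coefficient magnitudes are summed over the positive-frequency bins
#' whose frequency lies in `[low, high)` -- the band energy
#' `P = sum_i y_i^2` with `y_i` the DFT coefficient magnitudes of that band.
#' With the three default bands and four channels this yields the
#' 12-dimensional feature vector fed to the classifier.
#'
#' Energies use the raw, unnormalized DFT coefficients; the convention is
#' irrelevant downstream because features are z-scored before training.
#'
#' @param epoch `emg_epoch` (channels x samples).
#' @param bands List of `c(low, high)` pairs, default [default_bands()].
#' @return Named numeric vector of length `channels x bands`, channel-major
#'   (the three band energies of channel 1, then channel 2, ...). Names are
#'   `"<channel>.<low>-<high>Hz"`.
#' @export
#' @examples
#' ds <- synthesize_dataset(session_plan(1, 1), seed = 1)
#' fft_band_energy(extract_epochs(ds)[[1]])
fft_band_energy <- function(epoch, bands = default_bands()) {
  stopifnot(inherits(epoch, "emg_epoch"))
  n <- ncol(epoch$signal)
  if (n < 2) stop("epoch must contain at least 2 samples", call. = FALSE)
  fs <- epoch$sampling_rate
  validate_bands(bands, fs)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2                     # one-sided spectrum
  channels <- rownames(epoch$signal)
  out <- numeric(0)
  for (i in seq_len(nrow(epoch$signal))) {
    mags2 <- Mod(stats::fft(epoch$signal[i, ]))^2
    e <- vapply(bands, function(b) {
      sum(mags2[half & freqs >= b[1] & freqs < b[2]])
    }, 0)
    names(e) <- paste(channels[i], band_names(bands), sep = ".")
    out <- c(out, e)
  }
  out
}

#' Wavelet subband-energy features
#'
#' Comparison feature set: per channel, a `level`-deep discrete wavelet
#' transform (Mallat pyramid, Daubechies-5 by default, periodized) is applied
#' to the epoch and the energies (sums of squared coefficients) of the
#' detail subbands are returned. Detail level j covers roughly
#' `fs / 2^(j+1) .. fs / 2^j` Hz; subbands are ordered coarsest first
#' (D3, D2, D1 at level 3 ~ 62-125, 125-250, 250-500 Hz), mirroring the
#' ascending-frequency layout of [fft_band_energy()].
#'
#' @param epoch `emg_epoch`.
#' @param wavelet Wavelet name; only `"db5"` is built in.
#' @param level Decomposition depth (default 3).
#' @return Named numeric vector of length `channels x level`, channel-major.
#' @export
wt_band_energy <- function(epoch, wavelet = "db5", level = 3) {
  stopifnot(inherits(epoch, "emg_epoch"))
  n <- ncol(epoch$signal)
  channels <- rownames(epoch$signal)
  out <- numeric(0)
  for (i in seq_len(nrow(epoch$signal))) {
    dec <- dwt_periodized(epoch$signal[i, ], wavelet, level)
    e <- rev(vapply(dec$details, function(d) sum(d^2), 0))  # coarse first
    names(e) <- paste(channels[i], paste0("D", rev(seq_len(level))), sep = ".")
    out <- c(out, e)
  }
  out
}

#' Assemble the feature table for a set of epochs
#'
#' @param epochs List of `emg_epoch` objects.
#' @param method `"fft"` for the FFT band energies (the primary features) or
#'   `"wt"` for the wavelet subband energies.
#' @param bands Bands for the FFT method.
#' @param wavelet,level Wavelet options for the WT method.
#' @return List with `features` (numeric matrix, one row per epoch, columns
#'   named as in the per-epoch extractors) and `labels` (character vector),
#'   rows in epoch order.
#' @export
#' @examples
#' ds <- synthesize_dataset(session_plan(2, 1), seed = 1)
#' ft <- build_feature_table(extract_epochs(ds))
#' dim(ft$features)
build_feature_table <- function(epochs, method = c("fft", "wt"),
                                bands = default_bands(),
                                wavelet = "db5", level = 3) {
  method <- match.arg(method)
  if (length(epochs) == 0) stop("no epochs supplied", call. = FALSE)
  fs <- vapply(epochs, `[[`, 0, "sampling_rate")
  if (length(unique(fs)) != 1) {
    stop("epochs have mixed sampling rates", call. = FALSE)
  }
  rows <- lapply(epochs, function(ep) {
    if (method == "fft") fft_band_energy(ep, bands)
    else wt_band_energy(ep, wavelet, level)
  })
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  list(features = features,
       labels = vapply(epochs, `[[`, "", "label"))
}
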