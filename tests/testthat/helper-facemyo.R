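# Shared fixtures, built in code and cached for the duration of the run.
.fixtures <- new.env(parent = emptyenv())

# Full default offline dataset -> preprocessed epochs + FFT/WT feature tables.
default_features <- function() {
  if (is.null(.fixtures$ft)) {
    ds <- synthesize_dataset(seed = 401)
    rec <- preprocess_recording(ds$recording)
    ep <- extract_epochs(rec)
    .fixtures$dataset <- ds
    .fixtures$epochs <- ep
    .fixtures$ft <- build_feature_table(ep, method = "fft")
    .fixtures$ftw <- build_feature_table(ep, method = "wt")
  }
  list(dataset = .fixtures$dataset, epochs = .fixtures$epochs,
       fft = .fixtures$ft, wt = .fixtures$ftw)
}

# A trained production classifier on the default dataset.
default_classifier <- function() {
  if (is.null(.fixtures$clf)) {
    ft <- default_features()$fft
    .fixtures$clf <- fit_classifier(ft$features, ft$labels, seed = 402,
                                    config = training_config(max_epochs = 100))
  }
  .fixtures$clf
}

# Random epoch of white noise for feature-property tests.
random_epoch <- function(n = 256, channels = c("F7", "F8", "FC5", "FC6"),
                         fs = 1000) {
  sig <- matrix(rnorm(length(channels) * n), length(channels), n,
                dimnames = list(channels, NULL))
  structure(list(signal = sig, label = "raising_brow", sampling_rate = fs),
            class = "emg_epoch")
}

# Single-channel epoch from an explicit vector.
epoch_from <- function(x, fs = 1000, channel = "F7") {
  structure(list(signal = matrix(x, 1, dimnames = list(channel, NULL)),
                 label = "raising_brow", sampling_rate = fs),
            class = "emg_epoch")
}

# Brute-force DFT band energy: direct O(n^2) summation, independent of fft().
brute_band_energy <- function(x, fs, low, high) {
  n <- length(x)
  total <- 0
  for (k in 0:(n - 1)) {
    f <- k * fs / n
    if (f > fs / 2 || f < low || f >= high) next
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    total <- total + re^2 + im^2
  }
  total
}

# Random small network plus a random batch, for gradient checks.
random_problem <- function(layout = c(3, 4, 2), n = 5, seed = 1) {
  set.seed(seed)
  net <- init_network(layout, seed = seed)
  # perturb away from the symmetric init so derivatives are generic
  net$b1 <- rnorm(layout[2], sd = 0.3)
  net$b2 <- rnorm(layout[3], sd = 0.3)
  X <- matrix(rnorm(n * layout[1]), n, layout[1])
  Y <- matrix(runif(n * layout[3]), n, layout[3])
  list(net = net, X = X, Y = Y)
}

# Central finite-difference gradient of E(Q), the independent oracle for the
# back-propagated Jacobian.
fd_gradient <- function(net, X, Y, h = 1e-6) {
  q <- facemyo:::pack_params(net)
  vapply(seq_along(q), function(p) {
    qp <- q; qp[p] <- qp[p] + h
    qm <- q; qm[p] <- qm[p] - h
    (mse_error(facemyo:::unpack_params(net, qp), X, Y)$E -
       mse_error(facemyo:::unpack_params(net, qm), X, Y)$E) / (2 * h)
  }, 0)
}
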