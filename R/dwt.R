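# Periodized discrete wavelet transform (Mallat pyramid).
#
# Only the Daubechies-5 analysis pair is shipped; its 10 scaling
# coefficients are the published constants. The highpass is the quadrature
# mirror g[k] = (-1)^k h[L-1-k].
db5_filters <- function() {
  h <- c( 1.60102397974192928e-01,
          6.03829269797189649e-01,
          7.24308528437772936e-01,
          1.38428145901320743e-01,
         -2.42294887066382025e-01,
         -3.22448695846383748e-02,
          7.75714938400457188e-02,
         -6.24149021279827437e-03,
         -1.25807519990819988e-02,
          3.33572528547377125e-03)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  list(h = h, g = g)
}

# One analysis level with periodic (circular) extension. Odd-length inputs
# are zero-padded by one sample first; since the pad adds no energy and the
# periodized filter bank is orthonormal on even lengths, the pyramid
# conserves energy exactly at any input length.
dwt_level <- function(x, h, g) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, 0); n <- n + 1L }
  L <- length(h)
  nk <- n / 2
  a <- numeric(nk); d <- numeric(nk)
  idx0 <- 2 * (seq_len(nk) - 1)              # start sample of each output
  for (m in seq_len(L)) {
    xi <- x[(idx0 + m - 1) %% n + 1]
    a <- a + h[m] * xi
    d <- d + g[m] * xi
  }
  list(approx = a, detail = d)
}

#' Periodized Daubechies wavelet decomposition
#'
#' Mallat pyramid with circular boundary handling: each level splits the
#' current approximation into a half-rate approximation (lowpass) and detail
#' (highpass) using the Daubechies-5 analysis pair. Odd-length signals are
#' zero-padded by one sample at the affected level, which keeps the
#' transform exactly energy-preserving (Parseval) for any input length.
#'
#' @param x Numeric vector.
#' @param wavelet Wavelet name; only `"db5"` is available.
#' @param level Number of levels (>= 1). The signal must be long enough that
#'   every level has at least as many samples as the filter length.
#' @return List with `details` (list of detail coefficient vectors, finest
#'   D1 first) and `approx` (final approximation).
#' @export
#' @examples
#' x <- sin(2 * pi * 7 * (0:127) / 128)
#' dec <- dwt_periodized(x, level = 3)
#' sum(unlist(lapply(dec$details, function(d) sum(d^2)))) + sum(dec$approx^2)
#' sum(x^2)  # equal: the transform is orthonormal
dwt_periodized <- function(x, wavelet = "db5", level = 3) {
  if (wavelet != "db5") {
    stop("only the db5 wavelet is available", call. = FALSE)
  }
  if (level < 1) stop("level must be >= 1", call. = FALSE)
  filt <- db5_filters()
  if (length(x) < 2^level) {
    stop("signal too short for a level-", level, " decomposition",
         call. = FALSE)
  }
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    dec <- dwt_level(a, filt$h, filt$g)
    details[[j]] <- dec$detail
    a <- dec$approx
  }
  names(details) <- paste0("D", seq_len(level))
  list(details = details, approx = a)
}
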