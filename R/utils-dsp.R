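#' @useDynLib eegmci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif median sd var cor quantile rbinom
NULL

#' Zero-phase FIR filtering in the frequency domain
#'
#' Applies a zero-phase band-pass (or band-stop) filter to each row of a
#' channels x samples matrix. The transfer function is real and even
#' (hence zero-phase) with raised-cosine transition bands; the signal is
#' reflection-padded before the FFT to suppress circular edge effects.
#'
#' Transition bandwidths follow the convention of windowed-sinc EEG filters:
#' at the low edge `max(0.25 * low, 0.05)` Hz capped at the edge itself, and
#' 25% of the high edge capped at the distance to Nyquist.
#'
#' @param x numeric vector or channels x samples matrix
#' @param fs sampling rate in Hz
#' @param low,high band edges in Hz; `low = 0` gives a low-pass, `high = Inf`
#'   (or `>= fs/2`) a high-pass
#' @param stop if `TRUE`, invert the response (band-stop / notch)
#' @return filtered object of the same shape as `x`
#' @export
fir_zerophase <- function(x, fs, low = 0, high = Inf, stop = FALSE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (n < 4L) stop("signal too short to filter")
  # reflection padding: one signal length on each side (capped)
  npad <- min(n - 1L, n)
  xp <- cbind(x[, npad:1, drop = FALSE], x, x[, n:(n - npad + 1L), drop = FALSE])
  np <- ncol(xp)
  freqs <- (seq_len(np) - 1L) / np * fs
  freqs <- pmin(freqs, fs - freqs)            # two-sided -> folded frequency
  H <- rep(1, np)
  nyq <- fs / 2
  if (low > 0) {
    tw <- min(max(0.25 * low, 0.05), low)
    H <- H * .raised_cosine_edge(freqs, low - tw, low, rising = TRUE)
  }
  if (is.finite(high) && high < nyq) {
    tw <- min(0.25 * high, nyq - high)
    H <- H * .raised_cosine_edge(freqs, high, high + tw, rising = FALSE)
  }
  if (stop) H <- 1 - H
  Xf <- t(apply(xp, 1L, fft))
  if (nrow(xp) == 1L) Xf <- matrix(fft(xp[1L, ]), nrow = 1L)
  Yf <- sweep(Xf, 2L, H, `*`)
  y <- t(apply(Yf, 1L, function(z) Re(fft(z, inverse = TRUE)) / np))
  if (nrow(xp) == 1L) y <- matrix(Re(fft(Yf[1L, ], inverse = TRUE)) / np, nrow = 1L)
  out <- y[, (npad + 1L):(npad + n), drop = FALSE]
  if (vec) out[1L, ] else out
}

# smooth 0->1 (rising) or 1->0 (falling) raised-cosine ramp between f0 and f1
.raised_cosine_edge <- function(f, f0, f1, rising = TRUE) {
  if (f1 <= f0) {
    r <- as.numeric(f >= f1)
  } else {
    t <- pmin(pmax((f - f0) / (f1 - f0), 0), 1)
    r <- 0.5 - 0.5 * cos(pi * t)
  }
  if (rising) r else 1 - r
}

# Band-filtered analytic signals for several bands from one forward FFT.
# Returns a list (one complex channels x samples matrix per band): the real
# part is the zero-phase band-filtered signal, Arg() the instantaneous phase.
# `bands` is a list of c(low, high); low = 0 / high >= fs/2 disable an edge.
.band_analytic <- function(x, fs, bands) {
  nc <- nrow(x); n <- ncol(x)
  npad <- min(n - 1L, n)
  xp <- cbind(x[, npad:1, drop = FALSE], x, x[, n:(n - npad + 1L), drop = FALSE])
  np <- ncol(xp)
  Xf <- matrix(0 + 0i, nc, np)
  for (ch in seq_len(nc)) Xf[ch, ] <- fft(xp[ch, ])
  freqs <- (seq_len(np) - 1L) / np * fs
  folded <- pmin(freqs, fs - freqs)
  nyq <- fs / 2
  # analytic weights: double positive frequencies, zero negative ones
  h <- numeric(np)
  if (np %% 2L == 0L) {
    h[c(1L, np / 2L + 1L)] <- 1
    h[2L:(np / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((np + 1L) / 2L)] <- 2
  }
  keep <- (npad + 1L):(npad + n)
  lapply(bands, function(band) {
    H <- rep(1, np)
    if (band[1L] > 0) {
      tw <- min(max(0.25 * band[1L], 0.05), band[1L])
      H <- H * .raised_cosine_edge(folded, band[1L] - tw, band[1L], rising = TRUE)
    }
    if (is.finite(band[2L]) && band[2L] < nyq) {
      tw <- min(0.25 * band[2L], nyq - band[2L])
      H <- H * .raised_cosine_edge(folded, band[2L], band[2L] + tw, rising = FALSE)
    }
    W <- H * h
    out <- matrix(0 + 0i, nc, n)
    for (ch in seq_len(nc)) {
      y <- fft(Xf[ch, ] * W, inverse = TRUE) / np
      out[ch, ] <- y[keep]
    }
    out
  })
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric vector
#' @return complex vector `x + i * H(x)`
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Hamming-windowed, overlapping-segment averaged one-sided PSD for each row
#' of a channels x samples matrix. Density scaling: integrating the returned
#' density over frequency (rectangle rule, bin width `fs/nfft`) recovers
#' signal power (Parseval).
#'
#' @param x channels x samples matrix (or vector)
#' @param fs sampling rate Hz
#' @param window_sec segment length in seconds
#' @param overlap fraction of overlap between segments in `[0, 1)`
#' @return list with `freq` (Hz grid) and `density` (channels x bins, power/Hz)
#' @export
welch_psd_matrix <- function(x, fs, window_sec = 1, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  nwin <- round(window_sec * fs)
  if (nwin > n) stop("Welch window longer than the signal")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0L, nwin - 1L) / (nwin - 1L))
  u <- sum(w^2) * fs                       # window power normalisation
  nfreq <- nwin %/% 2L + 1L
  dens <- matrix(0, nrow = nrow(x), ncol = nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nwin - 1L), drop = FALSE]
    seg <- sweep(seg, 2L, w, `*`)
    Sf <- t(apply(seg, 1L, fft))
    if (nrow(seg) == 1L) Sf <- matrix(fft(seg[1L, ]), nrow = 1L)
    P <- (Mod(Sf[, seq_len(nfreq), drop = FALSE])^2) / u
    # fold negative frequencies into one-sided density (not DC / Nyquist)
    inner <- 2L:(nfreq - if (nwin %% 2L == 0L) 1L else 0L)
    P[, inner] <- 2 * P[, inner]
    dens <- dens + P
  }
  dens <- dens / length(starts)
  list(freq = (seq_len(nfreq) - 1L) * fs / nwin, density = dens)
}

# Welch cross-spectral matrices for all channels at once.
# Returns list(freq, S) where S is [nchan, nchan, nfreq] complex.
welch_csd <- function(x, fs, window_sec = 1, overlap = 0.5) {
  n <- ncol(x)
  nc <- nrow(x)
  nwin <- round(window_sec * fs)
  if (nwin > n) stop("Welch window longer than the signal")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  if (length(starts) < 2L)
    stop("magnitude-squared coherence needs at least 2 Welch segments")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0L, nwin - 1L) / (nwin - 1L))
  nfreq <- nwin %/% 2L + 1L
  nseg <- length(starts)
  # per-channel segment FFTs: channels x segments x frequency bins
  F <- array(0 + 0i, dim = c(nc, nseg, nfreq))
  for (si in seq_len(nseg)) {
    seg <- sweep(x[, starts[si]:(starts[si] + nwin - 1L), drop = FALSE], 2L, w, `*`)
    for (ch in seq_len(nc)) F[ch, si, ] <- fft(seg[ch, ])[seq_len(nfreq)]
  }
  S <- array(0 + 0i, dim = c(nc, nc, nfreq))
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      cs <- colMeans(F[i, , ] * Conj(F[j, , ]))
      S[i, j, ] <- cs
      S[j, i, ] <- Conj(cs)
    }
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nwin, S = S)
}
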