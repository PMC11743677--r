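#' Band-filter an epoch
#'
#' Zero-phase FIR band-pass restricted to one analysis band
#' (`"full"` = [0.5, 45) Hz).
#'
#' @param epoch an `eeg_epoch`
#' @param band band name in [eeg_bands] or `c(low, high)`
#' @return filtered `eeg_epoch`
#' @export
band_filter <- function(epoch, band) {
  if (is.character(band)) band <- eeg_bands[[match.arg(band, names(eeg_bands))]]
  if (band[1L] < 0 || band[2L] > epoch$fs / 2)
    stop("band must lie within [0, fs/2)")
  out <- epoch
  out$data <- fir_zerophase(epoch$data, epoch$fs, low = band[1L], high = band[2L])
  out
}

.connectivity_matrix <- function(values, measure, band_name, channel_names) {
  dimnames(values) <- list(channel_names, channel_names)
  structure(list(measure = measure, band = band_name, values = values),
            class = "connectivity_matrix")
}

#' Pearson correlation connectivity
#'
#' Product-moment correlation for every unordered channel pair; symmetric
#' with unit diagonal. Zero-variance channels give `NA` entries.
#'
#' @param epoch an `eeg_epoch` (optionally band-filtered)
#' @param band_name label stored with the matrix
#' @return a `connectivity_matrix`
#' @export
pearson_connectivity <- function(epoch, band_name = "full") {
  x <- t(epoch$data)
  sds <- apply(x, 2L, sd)
  r <- suppressWarnings(cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  .connectivity_matrix(r, "pearson", band_name, epoch$channel_names)
}

#' Phase lag index
#'
#' Band-filters the epoch, extracts instantaneous phases via the analytic
#' signal, and for each pair computes `|mean(sign(sin(phase difference)))|`,
#' discarding 5% of samples at each edge. Zero for identical signals or any
#' phase difference centred symmetrically around 0 or pi; 1 for perfect
#' locking away from 0/pi.
#'
#' @param epoch an `eeg_epoch`
#' @param band band name or `c(low, high)`; `NULL` to skip filtering
#' @param band_name label stored with the matrix (defaults to `band` when
#'   that is a name)
#' @return a `connectivity_matrix`
#' @export
pli <- function(epoch, band = "full",
                band_name = if (is.character(band)) band else "custom") {
  if (is.character(band)) band <- eeg_bands[[match.arg(band, names(eeg_bands))]]
  if (is.null(band)) band <- c(0, Inf)
  a <- .band_analytic(epoch$data, epoch$fs, list(band))[[1L]]
  .pli_from_analytic(a, band_name, epoch$channel_names)
}

.pli_from_analytic <- function(a, band_name, channel_names) {
  nc <- nrow(a)
  n <- ncol(a)
  trim <- max(1L, floor(0.05 * n))
  keep <- (trim + 1L):(n - trim)
  ak <- a[, keep, drop = FALSE]
  ph <- Arg(ak)
  amp_ok <- rowSums(Mod(ak) > 0) > 0
  v <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      if (!amp_ok[i] || !amp_ok[j]) { v[i, j] <- v[j, i] <- NA_real_; next }
      v[i, j] <- v[j, i] <- abs(mean(sign(sin(ph[i, ] - ph[j, ]))))
    }
  }
  diag(v) <- 0
  .connectivity_matrix(v, "pli", band_name, channel_names)
}

#' Magnitude-squared coherence
#'
#' Welch-averaged coherence `|S_xy|^2 / (S_xx S_yy)` per pair, averaged over
#' the in-band frequency bins. Requires at least 2 Welch segments (a single
#' segment makes the estimator identically 1).
#'
#' @param epoch an `eeg_epoch`
#' @param band band name or `c(low, high)` selecting the bins to average
#' @param window_sec,overlap Welch parameters
#' @return a `connectivity_matrix`
#' @export
msc <- function(epoch, band = "full", window_sec = 1, overlap = 0.5) {
  band_name <- if (is.character(band)) band else "custom"
  est <- welch_csd(epoch$data, epoch$fs, window_sec, overlap)
  .msc_from_csd(est, if (is.character(band)) band_name else band,
                epoch$channel_names)
}

.msc_from_csd <- function(est, band, channel_names) {
  band_name <- if (is.character(band)) band else "custom"
  if (is.character(band)) band <- eeg_bands[[match.arg(band, names(eeg_bands))]]
  idx <- .band_bins(est$freq, band)
  if (!length(idx)) stop("band contains no coherence bins")
  nc <- dim(est$S)[1L]
  v <- matrix(0, nc, nc)
  auto <- vapply(seq_len(nc), function(ch) Re(est$S[ch, ch, ]),
                 numeric(dim(est$S)[3L]))
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      num <- Mod(est$S[i, j, idx])^2
      den <- auto[idx, i] * auto[idx, j]
      coh <- ifelse(den > 0, num / den, NA_real_)
      v[i, j] <- v[j, i] <- mean(coh)
    }
  }
  .connectivity_matrix(v, "msc", band_name, channel_names)
}

#' Vectorize a connectivity matrix
#'
#' Strict upper triangle in row-major channel order: for 16 channels,
#' 120 features named `{measure}_{band}__{chA}-{chB}`.
#'
#' @param cm a `connectivity_matrix`
#' @return named numeric vector
#' @export
vectorize_connectivity <- function(cm) {
  v <- cm$values
  nc <- nrow(v)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]   # row-major
  out <- v[idx]
  names(out) <- paste0(cm$measure, "_", cm$band, "__",
                       rownames(v)[idx[, 1L]], "-", colnames(v)[idx[, 2L]])
  out
}

#' All connectivity features of one epoch
#'
#' Pearson, PLI and MSC over the six bands (delta..gamma, full), each
#' vectorized over the 120 channel pairs: 2160 named features. Pearson is
#' computed on band-filtered signals so all three measures share the band
#' structure; the band filter and analytic signal are obtained from a single
#' shared FFT per epoch.
#'
#' @param epoch an `eeg_epoch`
#' @param window_sec,overlap Welch parameters for MSC
#' @return named numeric vector of length 2160
#' @export
connectivity_features <- function(epoch, window_sec = 1, overlap = 0.5) {
  bands <- names(eeg_bands)
  analytic <- .band_analytic(epoch$data, epoch$fs, eeg_bands[bands])
  est <- welch_csd(epoch$data, epoch$fs, window_sec, overlap)
  out <- numeric(0)
  for (b in bands) {
    a <- analytic[[b]]
    filt <- epoch
    filt$data <- Re(a)
    out <- c(out,
             vectorize_connectivity(pearson_connectivity(filt, band_name = b)),
             vectorize_connectivity(.pli_from_analytic(a, b, epoch$channel_names)),
             vectorize_connectivity(.msc_from_csd(est, b, epoch$channel_names)))
  }
  out
}
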