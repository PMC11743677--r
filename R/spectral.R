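#' Analysis frequency bands (half-open intervals, Hz)
#'
#' delta [0.5,4), theta [4,8), alpha [8,13), beta [13,30), gamma [30,45),
#' and `full` = [0.5,45) (union of the five).
#' @export
eeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 45), full = c(0.5, 45))

#' Welch PSD of an epoch
#'
#' @param epoch an `eeg_epoch`
#' @param window_sec Welch segment length, s (default 1; use 2 for 20-s
#'   subject-level spectra)
#' @param overlap overlap fraction (default 0.5)
#' @return object of class `psd_estimate`: list with `freq` and channels x
#'   bins `density` (power per Hz), plus channel names
#' @export
welch_psd <- function(epoch, window_sec = 1, overlap = 0.5) {
  est <- welch_psd_matrix(epoch$data, epoch$fs, window_sec, overlap)
  structure(list(freq = est$freq, density = est$density,
                 channel_names = epoch$channel_names),
            class = "psd_estimate")
}

# indices of PSD bins inside a half-open band [low, high)
.band_bins <- function(freq, band) {
  which(freq >= band[1L] & freq < band[2L])
}

#' Band power from a PSD estimate
#'
#' Rectangle-rule integral of the density over the half-open band.
#'
#' @param psd a `psd_estimate`
#' @param band length-2 numeric `c(low, high)` or a name in [eeg_bands]
#' @return named numeric, one power per channel
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) band <- eeg_bands[[match.arg(band, names(eeg_bands))]]
  idx <- .band_bins(psd$freq, band)
  if (!length(idx)) stop("band [", band[1L], ", ", band[2L],
                         ") contains no PSD bins")
  df <- psd$freq[2L] - psd$freq[1L]
  p <- rowSums(psd$density[, idx, drop = FALSE]) * df
  names(p) <- psd$channel_names
  p
}

#' Band powers for all five analysis bands
#'
#' @param psd a `psd_estimate`
#' @return channels x 5 matrix (delta..gamma)
#' @export
band_power_set <- function(psd) {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  out <- matrix(0, nrow = length(psd$channel_names), ncol = length(bands),
                dimnames = list(psd$channel_names, bands))
  for (b in bands) out[, b] <- band_power(psd, b)
  out
}

#' Spectral power ratios
#'
#' Per channel: Ratio1 = delta/alpha, Ratio2 = theta/alpha,
#' Ratio3 = delta/(alpha+beta), Ratio4 = theta/(alpha+beta),
#' Ratio5 = (delta+theta)/(alpha+beta+gamma). A zero denominator yields `NA`
#' for that ratio (flagged missing, excluded by downstream selection).
#'
#' @param bp channels x 5 band-power matrix from [band_power_set]
#' @return channels x 5 matrix of ratios
#' @export
psd_ratios <- function(bp) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- cbind(ratio1 = safe_div(bp[, "delta"], bp[, "alpha"]),
               ratio2 = safe_div(bp[, "theta"], bp[, "alpha"]),
               ratio3 = safe_div(bp[, "delta"], bp[, "alpha"] + bp[, "beta"]),
               ratio4 = safe_div(bp[, "theta"], bp[, "alpha"] + bp[, "beta"]),
               ratio5 = safe_div(bp[, "delta"] + bp[, "theta"],
                                 bp[, "alpha"] + bp[, "beta"] + bp[, "gamma"]))
  rownames(out) <- rownames(bp)
  out
}

#' Spectral entropy of the in-band PSD
#'
#' Shannon entropy (natural log) of the in-band density values normalised to
#' probabilities: `E = -sum p_i log p_i`, so `0 <= E <= log(N)` for `N`
#' in-band bins. All-zero in-band density yields `NA`.
#'
#' @param psd a `psd_estimate`
#' @param band band name or `c(low, high)`
#' @return named numeric per channel
#' @export
psd_entropy <- function(psd, band) {
  if (is.character(band)) band <- eeg_bands[[match.arg(band, names(eeg_bands))]]
  idx <- .band_bins(psd$freq, band)
  if (!length(idx)) stop("band contains no PSD bins")
  d <- psd$density[, idx, drop = FALSE]
  tot <- rowSums(d)
  e <- vapply(seq_len(nrow(d)), function(ch) {
    if (tot[ch] <= 0) return(NA_real_)
    p <- d[ch, ] / tot[ch]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  names(e) <- psd$channel_names
  e
}

#' Interhemispheric asymmetry
#'
#' `IA = log10(power_left) - log10(power_right)` for a homologous channel
#' pair within one band; antisymmetric under pair swap. Nonpositive power
#' yields `NA`.
#'
#' @param bp channels x 5 band-power matrix from [band_power_set]
#' @param pair character vector `c(left, right)` of channel names
#' @param band one of delta/theta/alpha/beta/gamma
#' @return scalar IA value
#' @export
interhemispheric_asymmetry <- function(bp, pair, band) {
  band <- match.arg(band, colnames(bp))
  if (!all(pair %in% rownames(bp)))
    stop("channel pair not present: ", paste(setdiff(pair, rownames(bp)), collapse = ", "))
  l <- bp[pair[1L], band]; r <- bp[pair[2L], band]
  if (!is.finite(l) || !is.finite(r) || l <= 0 || r <= 0) return(NA_real_)
  log10(l) - log10(r)
}

#' All spectral features of one epoch
#'
#' 16 channels x 5 ratios + 16 channels x 5 band entropies + 8 pairs x 5
#' band asymmetries = 200 named features.
#'
#' @param epoch an `eeg_epoch`
#' @param window_sec,overlap Welch parameters (see [welch_psd])
#' @return named numeric vector of length 200
#' @export
spectral_features <- function(epoch, window_sec = 1, overlap = 0.5) {
  psd <- welch_psd(epoch, window_sec, overlap)
  bp <- band_power_set(psd)
  bands <- colnames(bp)
  ratios <- psd_ratios(bp)
  out_r <- as.vector(ratios)
  names(out_r) <- paste0(rep(colnames(ratios), each = nrow(ratios)), "__",
                         rep(rownames(ratios), ncol(ratios)))
  ent <- vapply(bands, function(b) psd_entropy(psd, b),
                numeric(length(psd$channel_names)))
  out_e <- as.vector(ent)
  names(out_e) <- paste0("psde_", rep(bands, each = nrow(ent)), "__",
                         rep(psd$channel_names, length(bands)))
  pairs <- eeg_pairs_1020[vapply(eeg_pairs_1020, function(p)
    all(p %in% rownames(bp)), logical(1))]
  out_a <- numeric(0)
  for (b in bands) {
    v <- vapply(pairs, function(p) interhemispheric_asymmetry(bp, p, b), numeric(1))
    names(v) <- paste0("ia_", b, "__",
                       vapply(pairs, function(p) paste(p, collapse = "-"), ""))
    out_a <- c(out_a, v)
  }
  c(out_r, out_e, out_a)
}
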