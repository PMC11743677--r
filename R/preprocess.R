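#' Preprocessing configuration
#'
#' Defaults follow the standard clinical resting-EEG chain: average
#' re-reference, zero-phase FIR band-pass 0.1-70 Hz, 50 Hz notch,
#' down-sampling to 250 Hz, segmentation into non-overlapping 2-s epochs.
#'
#' @param bandpass_low,bandpass_high band-pass edges, Hz
#' @param notch_freq power-line frequency, Hz (width 2 Hz band-stop)
#' @param target_fs output sampling rate, Hz
#' @param epoch_length epoch duration, s
#' @param segment_length analysed segment duration, s
#' @param reject_threshold optional absolute-amplitude epoch rejection, uV
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(bandpass_low = 0.1, bandpass_high = 70,
                              notch_freq = 50, target_fs = 250,
                              epoch_length = 2, segment_length = 20,
                              reject_threshold = NULL) {
  if (!(bandpass_low > 0 && bandpass_low < bandpass_high))
    stop("need 0 < bandpass_low < bandpass_high")
  if (bandpass_high >= target_fs / 2)
    stop("bandpass_high must be below the target Nyquist frequency")
  k <- segment_length / epoch_length
  if (abs(k - round(k)) > 1e-9)
    stop("epoch_length must divide segment_length exactly")
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch_freq = notch_freq, target_fs = target_fs,
                 epoch_length = epoch_length, segment_length = segment_length,
                 reject_threshold = reject_threshold),
            class = "preprocess_config")
}

#' Preprocess a recording
#'
#' Processing order: average re-reference -> zero-phase FIR band-pass ->
#' zero-phase notch -> integer-factor down-sampling. The band-pass high
#' cutoff must lie below the target Nyquist, so the band-pass doubles as the
#' anti-aliasing filter and decimation is exact.
#'
#' @param recording an `eeg_recording` (>= 2 channels)
#' @param config a `preprocess_config`
#' @return preprocessed `eeg_recording` at `target_fs`
#' @export
preprocess <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs < 2 * config$bandpass_high)
    stop("sampling rate too low for the requested band-pass")
  if (nrow(recording$data) < 2L)
    stop("average reference requires at least 2 channels")
  factor <- fs / config$target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs must be an integer multiple of target_fs")
  factor <- as.integer(round(factor))

  x <- recording$data
  x <- sweep(x, 2L, colMeans(x))                       # average reference
  x <- fir_zerophase(x, fs, low = config$bandpass_low,
                     high = config$bandpass_high)      # band-pass
  if (!is.null(config$notch_freq) && is.finite(config$notch_freq)) {
    x <- fir_zerophase(x, fs, low = config$notch_freq - 1,
                       high = config$notch_freq + 1, stop = TRUE)
  }
  if (factor > 1L) x <- x[, seq(1L, ncol(x), by = factor), drop = FALSE]
  eeg_recording(recording$subject_id, recording$group,
                recording$channel_names, config$target_fs, x)
}

#' Segment a recording into non-overlapping epochs
#'
#' @param recording a (preprocessed) `eeg_recording`
#' @param config a `preprocess_config`; uses `epoch_length` and, if set,
#'   `reject_threshold` (epochs with any `abs(sample)` above it are dropped)
#' @return list of `eeg_epoch` objects, in temporal order
#' @export
segment_epochs <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  nsamp <- ncol(recording$data)
  len <- as.integer(round(config$epoch_length * recording$fs))
  if (nsamp < len) stop("recording shorter than one epoch")
  n_ep <- nsamp %/% len
  out <- vector("list", n_ep)
  kept <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    d <- recording$data[, idx, drop = FALSE]
    if (!is.null(config$reject_threshold) &&
        max(abs(d)) > config$reject_threshold) {
      message(sprintf("epoch %d of %s rejected (|amplitude| > %g uV)",
                      i, recording$subject_id, config$reject_threshold))
      next
    }
    kept[i] <- TRUE
    out[[i]] <- structure(
      list(subject_id = recording$subject_id, group = recording$group,
           epoch_index = i, channel_names = recording$channel_names,
           fs = recording$fs, data = d),
      class = "eeg_epoch")
  }
  out[kept]
}

#' Select the cleanest contiguous segment of a longer recording
#'
#' Automated stand-in for manual segment selection: returns the contiguous
#' window of `segment_length` seconds minimising the maximum absolute
#' amplitude (evaluated on a 1-s grid of candidate starts).
#'
#' @param recording an `eeg_recording`
#' @param config a `preprocess_config`
#' @return an `eeg_recording` of `segment_length` seconds
#' @export
select_segment <- function(recording, config = preprocess_config()) {
  len <- as.integer(round(config$segment_length * recording$fs))
  nsamp <- ncol(recording$data)
  if (nsamp < len) stop("recording shorter than segment_length")
  if (nsamp == len) return(recording)
  starts <- unique(c(seq(1L, nsamp - len + 1L, by = as.integer(recording$fs)),
                     nsamp - len + 1L))
  peak <- vapply(starts, function(s)
    max(abs(recording$data[, s:(s + len - 1L)])), numeric(1))
  s <- starts[which.min(peak)]
  eeg_recording(recording$subject_id, recording$group, recording$channel_names,
                recording$fs, recording$data[, s:(s + len - 1L), drop = FALSE])
}
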