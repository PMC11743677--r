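#' Write an EEG recording to an EDF file
#'
#' Minimal European Data Format (EDF, 16-bit) writer. One data record per
#' second; physical calibration chosen per channel from the sample range, so
#' the round-trip error is bounded by one quantization step
#' (`(physmax - physmin) / 65535`).
#'
#' @param recording an `eeg_recording`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nchan <- nrow(data)
  nsamp <- ncol(data)
  rec_dur <- 1L                         # seconds per data record
  spr <- as.integer(fs)                 # samples per record per channel
  nrec <- nsamp %/% spr
  if (nrec * spr != nsamp)
    stop("recording length must be a whole number of 1-s data records")

  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  pad <- function(x, n) {
    x <- substr(trimws(as.character(x)), 1L, n)
    formatC(x, width = n, flag = "-")
  }
  num <- function(x, n) pad(formatC(x, format = "g", digits = 8), n)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8L),
    pad(paste("X X X", recording$subject_id), 80L),
    pad(paste("Startdate X X X", "eegmci"), 80L),
    pad("01.01.00", 8L), pad("00.00.00", 8L),
    pad(256L * (1L + nchan), 8L),
    pad("", 44L),
    pad(nrec, 8L),
    num(rec_dur, 8L),
    pad(nchan, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, n) writeChar(paste0(vapply(vals, pad, "", n = n), collapse = ""), con, eos = NULL)
  field(recording$channel_names, 16L)                    # label
  field(rep("AgAgCl electrode", nchan), 80L)             # transducer
  field(rep("uV", nchan), 8L)                            # physical dimension
  field(vapply(pmin_, function(v) formatC(v, format = "g", digits = 8), ""), 8L)
  field(vapply(pmax_, function(v) formatC(v, format = "g", digits = 8), ""), 8L)
  field(rep(dmin, nchan), 8L)
  field(rep(dmax, nchan), 8L)
  field(rep("", nchan), 80L)                             # prefiltering
  field(rep(spr, nchan), 8L)
  field(rep("", nchan), 32L)                             # reserved

  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nchan)) {
      dig <- round((data[ch, idx] - pmin_[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EEG recording from an EDF file
#'
#' @param path EDF file path
#' @param expected_channels optional character vector; if given, the file must
#'   contain exactly these channels (error names any missing ones)
#' @param group group label to attach (`"SMCI"`, `"PMCI"` or `"unknown"`)
#' @return an `eeg_recording`
#' @export
read_recording <- function(path, expected_channels = NULL, group = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < n) stop("EDF parse error: truncated header")
    trimws(raw)
  }
  rd(8L)                                # version
  subject_field <- rd(80L)
  rd(80L); rd(8L); rd(8L)
  hdr_bytes <- suppressWarnings(as.integer(rd(8L)))
  if (is.na(hdr_bytes)) stop("EDF parse error: non-numeric 'header bytes' field")
  rd(44L)
  nrec <- suppressWarnings(as.integer(rd(8L)))
  if (is.na(nrec) || nrec < 1L) stop("EDF parse error: invalid 'number of data records' field")
  rec_dur <- suppressWarnings(as.numeric(rd(8L)))
  if (is.na(rec_dur) || rec_dur <= 0) stop("EDF parse error: invalid 'record duration' field")
  nchan <- suppressWarnings(as.integer(rd(4L)))
  if (is.na(nchan) || nchan < 1L) stop("EDF parse error: invalid 'number of signals' field")

  fld <- function(n) vapply(seq_len(nchan), function(i) rd(n), "")
  labels <- fld(16L)
  fld(80L); fld(8L)
  pmin_ <- suppressWarnings(as.numeric(fld(8L)))
  pmax_ <- suppressWarnings(as.numeric(fld(8L)))
  dmin <- suppressWarnings(as.integer(fld(8L)))
  dmax <- suppressWarnings(as.integer(fld(8L)))
  if (anyNA(c(pmin_, pmax_, dmin, dmax)))
    stop("EDF parse error: non-numeric calibration field (physical/digital min/max)")
  fld(80L)
  spr <- suppressWarnings(as.integer(fld(8L)))
  if (anyNA(spr)) stop("EDF parse error: invalid 'samples per record' field")
  fld(32L)

  if (!is.null(expected_channels)) {
    missing <- setdiff(expected_channels, labels)
    if (length(missing))
      stop("EDF file is missing expected channel(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(spr)) != 1L)
    stop("EDF parse error: heterogeneous samples-per-record not supported")
  spr1 <- spr[1L]
  fs <- spr1 / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, nrow = nchan, ncol = nrec * spr1)
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = nchan * spr1, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < nchan * spr1) stop("EDF parse error: truncated data record")
    blk <- matrix(block, nrow = spr1, ncol = nchan)
    idx <- ((r - 1L) * spr1 + 1L):(r * spr1)
    data[, idx] <- (t(blk) - dmin) * gain + pmin_
  }
  subject_id <- sub("^X X X ?", "", subject_field)
  if (!nzchar(subject_id)) subject_id <- "unknown"
  eeg_recording(subject_id = subject_id, group = group,
                channel_names = labels, fs = fs, data = data)
}
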