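#' Coarse-grain a signal
#'
#' Non-overlapping block means of length `scale`; element `j` is the mean of
#' block `[(j-1)*scale + 1, j*scale]`. Scale 1 is the identity.
#'
#' @param x numeric vector
#' @param scale positive integer
#' @return numeric vector of length `floor(length(x)/scale)`
#' @export
coarse_grain <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be >= 1")
  if (scale > length(x)) stop("scale exceeds signal length")
  if (scale == 1L) return(x)
  nb <- length(x) %/% scale
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of ordinal
#' patterns of `m`-length delay vectors; bounded by `log(factorial(m))`.
#' Ties are broken by order of occurrence.
#'
#' @param x numeric vector
#' @param m embedding dimension (default 3)
#' @param delay delay in samples (default 1)
#' @return entropy in nats, or `NA` for too-short input
#' @export
permutation_entropy <- function(x, m = 3L, delay = 1L) {
  if (length(x) < (m - 1L) * delay + 2L) return(NA_real_)
  .pe_cpp(as.numeric(x), as.integer(m), as.integer(delay))
}

#' Approximate entropy
#'
#' `ApEn(m, r)` with `r = r_frac * sd(x)`, Chebyshev distance, self-matches
#' included. Constant input returns 0 by convention.
#'
#' @param x numeric vector
#' @param m template length (default 2)
#' @param r_frac tolerance as a fraction of SD (default 0.2)
#' @param r absolute tolerance; overrides `r_frac` when given (used by the
#'   multiscale wrapper to keep `r` fixed across scales)
#' @return entropy value, or `NA` for too-short input
#' @export
approximate_entropy <- function(x, m = 2L, r_frac = 0.2, r = NULL) {
  if (length(x) < m + 2L) return(NA_real_)
  s <- sd(x)
  if (is.null(r)) {
    if (s == 0) return(0)
    r <- r_frac * s
  }
  if (r <= 0) return(0)
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Sample entropy
#'
#' `-log(A/B)` with self-matches excluded (`B` = template matches at length
#' `m`, `A` at length `m+1`). Zero matches at length `m+1` yield `NA`
#' (flagged missing). Constant input returns 0 (all templates match).
#'
#' @inheritParams approximate_entropy
#' @return entropy value, `NA` when undefined
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.2, r = NULL) {
  if (length(x) < m + 2L) return(NA_real_)
  s <- sd(x)
  if (is.null(r)) {
    if (s == 0) return(0)
    r <- r_frac * s
  }
  if (r <= 0) return(0)
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Lempel-Ziv complexity
#'
#' The signal is binarized at its mean (`1` where `x > mean(x)`), parsed by
#' the LZ76 phrase-counting scheme, and reported normalised:
#' `C = c(n) * log2(n) / n`. The raw phrase count is available via
#' `attr(, "raw")`.
#'
#' @param x numeric vector (length >= 2)
#' @return normalised LZ complexity with attribute `raw`
#' @export
lempel_ziv <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  s <- as.integer(x > mean(x))
  cc <- .lz76_cpp(s)
  structure(cc * log2(n) / n, raw = cc)
}

#' Hurst exponent (rescaled-range estimate)
#'
#' Classical R/S analysis: for dyadic block sizes from 8 up to `n/2`, the
#' rescaled range (range of the cumulative mean-adjusted sum over the block
#' SD) is averaged over non-overlapping blocks; the estimate is the slope of
#' `log(mean R/S)` against `log(block size)`.
#'
#' @param x numeric vector, length >= 64
#' @return Hurst estimate, `NA` for zero-variance input
#' @export
hurst_exponent <- function(x) {
  n <- length(x)
  if (n < 64L) return(NA_real_)
  if (sd(x) == 0) return(NA_real_)
  sizes <- 2^(3:floor(log2(n / 2)))
  rs <- vapply(sizes, function(sz) {
    nb <- n %/% sz
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1L) * sz + 1L):(b * sz)]
      s <- sd(seg)
      if (s == 0) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(NA_real_)
  unname(coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2L])
}

# lag selection for phase-space reconstruction: smallest lag where the
# sample autocorrelation first crosses <= 0; if none below n/3, smallest lag
# with acf <= 1/e; capped so that m-dimensional embedding is possible.
.psr_lag <- function(x, m) {
  n <- length(x)
  maxlag <- max(1L, floor(n / 3))
  ac <- stats::acf(x, lag.max = maxlag, plot = FALSE, demean = TRUE)$acf[-1L]
  tau <- which(ac <= 0)[1L]
  if (is.na(tau)) tau <- which(ac <= exp(-1))[1L]
  if (is.na(tau)) tau <- 1L
  min(as.integer(tau), max(1L, (n - 1L) %/% (m - 1L)))
}

#' Median distance from the centroid of the phase-space reconstruction
#'
#' Delay-embeds the signal in `m` dimensions (lag from the autocorrelation
#' function: first zero crossing, with a 1/e fallback), computes the
#' centroid of the embedded points, and returns the median Euclidean
#' distance of the points from the centroid. Absolutely homogeneous
#' (`f(a x) = |a| f(x)`) and translation invariant.
#'
#' @param x numeric vector
#' @param m embedding dimension (default 3)
#' @return median centroid distance, `NA` for too-short input
#' @export
m_dcpsr <- function(x, m = 3L) {
  n <- length(x)
  if (n < m + 1L) return(NA_real_)
  if (sd(x) == 0) return(0)
  tau <- .psr_lag(x, m)
  npts <- n - (m - 1L) * tau
  if (npts < 1L) return(NA_real_)
  pts <- vapply(seq_len(m) - 1L, function(k) x[(1L + k * tau):(npts + k * tau)],
                numeric(npts))
  centroid <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, centroid)^2))
  median(d)
}

#' Apply a feature over coarse-graining scales 1..10
#'
#' For approximate/sample entropy the tolerance `r` is fixed from the SD of
#' the original (scale-1) series so values are comparable across scales.
#' Per-scale failures yield `NA` without affecting other scales.
#'
#' @param feature one of `"pe"`, `"ae"`, `"se"`
#' @param x numeric vector
#' @param scales integer vector (default 1:10)
#' @param m,delay,r_frac parameters passed through
#' @return named numeric vector, one value per scale
#' @export
multiscale <- function(feature = c("pe", "ae", "se"), x, scales = 1:10,
                       m = NULL, delay = 1L, r_frac = 0.2) {
  feature <- match.arg(feature)
  if (is.null(m)) m <- if (feature == "pe") 3L else 2L
  r <- if (feature != "pe") r_frac * sd(x) else NULL
  out <- vapply(scales, function(s) {
    if (s > length(x)) return(NA_real_)
    xs <- coarse_grain(x, s)
    switch(feature,
           pe = permutation_entropy(xs, m = m, delay = delay),
           ae = approximate_entropy(xs, m = m, r = r),
           se = sample_entropy(xs, m = m, r = r))
  }, numeric(1))
  names(out) <- paste0("s", scales)
  out
}

#' All nonlinear features of one epoch
#'
#' Per channel: multiscale PE/AE/SE over scales 1-10 (3 x 10), LZ, Hurst,
#' M-DCPSR -> 33 features x 16 channels = 528 named features.
#'
#' @param epoch an `eeg_epoch`
#' @param scales coarse-graining scales (default 1:10)
#' @return named numeric vector of length `33 * n_channels`
#' @export
nonlinear_features <- function(epoch, scales = 1:10) {
  chn <- epoch$channel_names
  out <- numeric(0)
  for (ci in seq_along(chn)) {
    x <- epoch$data[ci, ]
    pe <- multiscale("pe", x, scales)
    ae <- multiscale("ae", x, scales)
    se <- multiscale("se", x, scales)
    v <- c(pe, ae, se, lz = as.numeric(lempel_ziv(x)),
           hurst = hurst_exponent(x), mdcpsr = m_dcpsr(x))
    names(v) <- c(paste0("pe_", names(pe)), paste0("ae_", names(ae)),
                  paste0("se_", names(se)), "lz", "hurst", "mdcpsr")
    names(v) <- paste0(names(v), "__", chn[ci])
    out <- c(out, v)
  }
  out
}
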