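# Independent brute-force oracles for the nonlinear statistics and the AUC.
# These deliberately use naive double loops / direct enumeration so they share
# no code path with the package implementations.

pe_brute <- function(x, m, delay = 1L) {
  n <- length(x)
  nvec <- n - (m - 1L) * delay
  pats <- character(nvec)
  for (t in seq_len(nvec)) {
    v <- x[t + (0:(m - 1L)) * delay]
    pats[t] <- paste(order(v), collapse = "-")   # stable: ties by occurrence
  }
  p <- table(pats) / nvec
  -sum(p * log(p))
}

apen_brute <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nv <- n - mm + 1L
    tot <- 0
    for (i in seq_len(nv)) {
      cnt <- 0L
      for (j in seq_len(nv)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      tot <- tot + log(cnt / nv)
    }
    tot / nv
  }
  phi(m) - phi(m + 1L)
}

sampen_brute <- function(x, m, r) {
  n <- length(x)
  nv <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      dB <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dB <= r) {
        B <- B + 1L
        dA <- max(dB, abs(x[i + m] - x[j + m]))
        if (dA <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

lz76_brute <- function(s) {
  # phrase-by-phrase parse: the phrase starting at i grows while
  # s[i..i+k-1] occurs as a substring of s[1..i+k-2] (copy sources may
  # overlap the phrase itself); the final partial phrase counts
  n <- length(s)
  c <- 0L
  i <- 1L
  while (i <= n) {
    k <- 1L
    repeat {
      if (i + k - 1L > n) break
      sub <- s[i:(i + k - 1L)]
      lim <- i + k - 2L
      found <- FALSE
      if (lim >= k) {
        for (st in 1:(lim - k + 1L)) {
          if (all(s[st:(st + k - 1L)] == sub)) { found <- TRUE; break }
        }
      }
      if (!found) break
      k <- k + 1L
    }
    c <- c + 1L
    i <- i + k
  }
  c
}

mdcpsr_brute <- function(x, m = 3L) {
  # independent step-by-step reimplementation: lag from autocorrelation
  # (first nonpositive crossing, 1/e fallback), embedding, centroid, median
  n <- length(x)
  maxlag <- max(1L, floor(n / 3))
  xc <- x - mean(x)
  denom <- sum(xc^2)
  ac <- vapply(seq_len(maxlag), function(l)
    sum(xc[1:(n - l)] * xc[(1 + l):n]) / denom, numeric(1))
  tau <- which(ac <= 0)[1L]
  if (is.na(tau)) tau <- which(ac <= exp(-1))[1L]
  if (is.na(tau)) tau <- 1L
  tau <- min(tau, max(1L, (n - 1L) %/% (m - 1L)))
  npts <- n - (m - 1L) * tau
  d <- numeric(npts)
  ctr <- numeric(m)
  for (k in 0:(m - 1L)) ctr[k + 1L] <- mean(x[(1L + k * tau):(npts + k * tau)])
  for (t in seq_len(npts)) {
    pt <- x[t + (0:(m - 1L)) * tau]
    d[t] <- sqrt(sum((pt - ctr)^2))
  }
  if (npts %% 2L == 1L) sort(d)[(npts + 1L) / 2L]
  else mean(sort(d)[npts / 2L + c(0L, 1L)])
}

auc_brute <- function(scores, truth) {
  pos <- scores[truth == "PMCI"]
  neg <- scores[truth == "SMCI"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# build an eeg_epoch from a channels x samples matrix
make_epoch <- function(data, fs = 250, channel_names = NULL, subject = "S1",
                       group = "SMCI") {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) <= 16L) eeg_channels_1020[seq_len(nrow(data))]
                     else sprintf("Ch%02d", seq_len(nrow(data)))
  }
  structure(list(subject_id = subject, group = group, epoch_index = 1L,
                 channel_names = channel_names, fs = fs, data = data),
            class = "eeg_epoch")
}

# random multichannel epoch for property tests
random_epoch <- function(nch = 4L, n = 500L, fs = 250, seed = 1L) {
  set.seed(seed)
  make_epoch(matrix(rnorm(nch * n), nch, n), fs = fs)
}
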