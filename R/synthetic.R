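#' Standard 16-channel 10-20 montage used throughout the package
#' @export
eeg_channels_1020 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                       "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")

#' Homologous left-right channel pairs for interhemispheric asymmetry
#' @export
eeg_pairs_1020 <- list(c("Fp1", "Fp2"), c("F3", "F4"), c("C3", "C4"),
                       c("P3", "P4"), c("O1", "O2"), c("F7", "F8"),
                       c("T3", "T4"), c("T5", "T6"))

# fixed per-channel amplitude profile (uV RMS-ish scale): slightly larger
# posterior amplitudes, as in eyes-closed resting EEG. Deterministic, so
# subjects differ only through their noise realisations and group profile.
.channel_gain_1020 <- c(Fp1 = 0.9, Fp2 = 0.9, F3 = 1.0, F4 = 1.0,
                        C3 = 1.0, C4 = 1.0, P3 = 1.15, P4 = 1.15,
                        O1 = 1.25, O2 = 1.25, F7 = 0.95, F8 = 0.95,
                        T3 = 1.0, T4 = 1.0, T5 = 1.1, T6 = 1.1)

#' EEG recording container
#'
#' @param subject_id character scalar
#' @param group `"SMCI"`, `"PMCI"` or `"unknown"`
#' @param channel_names character vector, one per data row
#' @param fs sampling rate in Hz
#' @param data channels x samples numeric matrix (microvolts)
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(subject_id, group, channel_names, fs, data) {
  group <- match.arg(group, c("SMCI", "PMCI", "unknown"))
  data <- as.matrix(data)
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal the number of data rows")
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive finite number")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  structure(list(subject_id = as.character(subject_id), group = group,
                 channel_names = as.character(channel_names),
                 fs = fs, data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Configuration of a synthetic two-group aMCI EEG cohort
#'
#' The defaults emulate the group contrasts reported for aMCI progressors
#' (PMCI) against stable patients (SMCI): a "high to low" spectral shift
#' (more relative delta/theta, less alpha/beta), reduced signal complexity
#' (less broadband noise admixture), and weaker inter-channel phase coupling.
#' `effect_scale` interpolates the PMCI profile between the SMCI profile
#' (0, a null cohort) and the full default contrast (1).
#'
#' @param n_smci,n_pmci subjects per group (defaults 65 and 42)
#' @param n_channels number of channels (16, 10-20 names)
#' @param fs sampling rate Hz (500)
#' @param duration seconds per subject (20)
#' @param band_power_profile named list with `SMCI` and `PMCI` numeric vectors
#'   of relative powers over delta/theta/alpha/beta/gamma, each summing to 1
#' @param connectivity_strength named numeric: shared-source coupling in
#'   `[0, 1]` per group
#' @param complexity_noise named numeric: broadband-noise mixing weight in
#'   `[0, 1]` per group
#' @param effect_scale scales the PMCI-vs-SMCI contrast of all three knobs
#' @param seed integer master seed
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_smci = 65L, n_pmci = 42L, n_channels = 16L,
                          fs = 500, duration = 20,
                          band_power_profile = NULL,
                          connectivity_strength = c(SMCI = 0.6, PMCI = 0.25),
                          complexity_noise = c(SMCI = 0.8, PMCI = 0.25),
                          effect_scale = 1, seed = 1L) {
  if (is.null(band_power_profile)) {
    band_power_profile <- list(
      SMCI = c(delta = 0.20, theta = 0.18, alpha = 0.36, beta = 0.18, gamma = 0.08),
      PMCI = c(delta = 0.33, theta = 0.26, alpha = 0.21, beta = 0.13, gamma = 0.07))
  }
  if (effect_scale != 1) {
    blend <- function(s, p) s + effect_scale * (p - s)
    band_power_profile$PMCI <- blend(band_power_profile$SMCI, band_power_profile$PMCI)
    connectivity_strength["PMCI"] <- blend(connectivity_strength[["SMCI"]],
                                           connectivity_strength[["PMCI"]])
    complexity_noise["PMCI"] <- blend(complexity_noise[["SMCI"]],
                                      complexity_noise[["PMCI"]])
  }
  cfg <- list(n_smci = as.integer(n_smci), n_pmci = as.integer(n_pmci),
              n_channels = as.integer(n_channels), fs = fs, duration = duration,
              band_power_profile = band_power_profile,
              connectivity_strength = connectivity_strength,
              complexity_noise = complexity_noise,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_smci < 1L || cfg$n_pmci < 1L) stop("need at least one subject per group")
  if (!all(is.finite(unlist(cfg[c("fs", "duration")]))) || cfg$fs <= 0 || cfg$duration <= 0)
    stop("fs and duration must be positive and finite")
  nsamp <- cfg$duration * cfg$fs
  if (abs(nsamp - round(nsamp)) > 1e-9)
    stop("duration x fs must be an integer number of samples")
  for (g in c("SMCI", "PMCI")) {
    bp <- cfg$band_power_profile[[g]]
    if (any(!is.finite(bp)) || any(bp < 0)) stop("band powers must be finite and nonnegative")
    if (abs(sum(bp) - 1) > 1e-6) stop("relative band powers must sum to 1 (group ", g, ")")
    cs <- cfg$connectivity_strength[[g]]
    cn <- cfg$complexity_noise[[g]]
    if (!is.finite(cs) || cs < 0 || cs > 1) stop("connectivity_strength must be in [0,1]")
    if (!is.finite(cn) || cn < 0 || cn > 1) stop("complexity_noise must be in [0,1]")
  }
  invisible(cfg)
}

# Band-limited unit-SD Gaussian noise by circular spectral shaping: white
# noise is exactly stationary, so multiplying its FFT by the band response
# (raised-cosine edges, as in fir_zerophase) needs no padding and yields a
# Gaussian process with exactly the target spectrum. With analytic = TRUE
# the analytic signal is returned from the same transform.
.shaped_noise <- function(nc, n, fs, low, high, analytic = FALSE) {
  freqs <- (seq_len(n) - 1L) / n * fs
  folded <- pmin(freqs, fs - freqs)
  H <- rep(1, n)
  nyq <- fs / 2
  if (low > 0) {
    tw <- min(max(0.25 * low, 0.05), low)
    H <- H * .raised_cosine_edge(folded, low - tw, low, rising = TRUE)
  }
  if (is.finite(high) && high < nyq) {
    tw <- min(0.25 * high, nyq - high)
    H <- H * .raised_cosine_edge(folded, high, high + tw, rising = FALSE)
  }
  if (analytic) {
    h <- numeric(n)
    if (n %% 2L == 0L) { h[c(1L, n / 2L + 1L)] <- 1; h[2L:(n / 2L)] <- 2 }
    else { h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2 }
    H <- H * h
  }
  out <- matrix(if (analytic) 0 + 0i else 0, nc, n)
  for (ch in seq_len(nc)) {
    y <- fft(fft(rnorm(n)) * H, inverse = TRUE) / n
    if (!analytic) y <- Re(y)
    s <- if (analytic) sd(Re(y)) else sd(y)
    out[ch, ] <- y / max(s, 1e-12)
  }
  out
}

# analysis bands used by the generator's band-limited components.
# Oscillatory components occupy the central ~60% of each band, so each
# band's spectrum is peaked rather than flat; broadband white noise then
# controls spectral (and temporal) disorder via complexity_noise.
.gen_band_cores <- list(delta = c(1.0, 3.2), theta = c(4.8, 7.2),
                        alpha = c(9.0, 12.0), beta = c(16.0, 27.0),
                        gamma = c(33.0, 42.0))

#' Generate one synthetic EEG subject
#'
#' The signal of every channel is a sum of (i) band-limited stochastic
#' oscillations with group-specific relative band powers, (ii) a shared
#' narrowband alpha source injecting inter-channel phase coupling, scaled by
#' the group's `connectivity_strength` and received by each channel at a
#' random but constant phase offset, and (iii) broadband white noise scaled
#' by `complexity_noise`. Deterministic given `(config$seed, subject_seed)`.
#'
#' @param config a `cohort_config`
#' @param group `"SMCI"` or `"PMCI"`
#' @param subject_seed integer distinguishing subjects
#' @param subject_id optional ID string
#' @return an `eeg_recording`
#' @export
generate_subject <- function(config, group, subject_seed,
                             subject_id = sprintf("%s_%03d", group, subject_seed)) {
  validate_cohort_config(config)
  if (!group %in% c("SMCI", "PMCI")) stop("group must be 'SMCI' or 'PMCI'")
  n <- as.integer(round(config$duration * config$fs))
  nc <- config$n_channels
  chn <- if (nc == 16L) eeg_channels_1020 else sprintf("Ch%02d", seq_len(nc))
  gains <- if (nc == 16L) unname(.channel_gain_1020) else rep(1, nc)
  # per-subject seed derived from both the master seed and the subject seed
  seed <- (config$seed * 48271 + subject_seed * 16807) %% 2147483647L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  bp <- config$band_power_profile[[group]]
  cs <- config$connectivity_strength[[group]]
  cn <- config$complexity_noise[[group]]
  base_amp <- 20                        # overall uV scale (arbitrary for ratios)

  osc <- matrix(0, nc, n)
  # lower complexity -> narrower band cores (more ordered oscillations)
  hw_factor <- 0.45 + 0.55 * cn
  for (b in names(.gen_band_cores)) {
    edges <- .gen_band_cores[[b]]
    ctr <- mean(edges); hw <- diff(edges) / 2 * hw_factor
    comp <- .shaped_noise(nc, n, config$fs, ctr - hw, ctr + hw)
    osc <- osc + sqrt(bp[[b]]) * comp
  }
  # shared narrowband alpha source: constant per-channel phase offsets
  a_src <- .shaped_noise(1L, n, config$fs, 8.5, 12.5, analytic = TRUE)[1L, ]
  # per-channel reception phases are montage geometry: fixed across subjects
  # (golden-angle spacing keeps pairwise differences away from 0 and pi)
  phases <- (seq_len(nc) * 2.3999632) %% (2 * pi)
  shared <- t(vapply(phases, function(ph) Re(a_src * exp(1i * ph)), numeric(n)))
  # broadband noise restricted to the analysis range so its full variance
  # survives the 0.1-70 Hz preprocessing band-pass
  noise <- .shaped_noise(nc, n, config$fs, 0.5, 45)
  # additive mixture: the noise term raises both total power and disorder,
  # so a group with lower complexity_noise has lower entropies AND a smaller
  # phase-space orbit (lower M-DCPSR), matching the reported PMCI contrasts
  sig <- (1 - cs) * osc + cs * shared + cn * noise
  sig <- sig * gains * base_amp
  eeg_recording(subject_id = subject_id, group = group, channel_names = chn,
                fs = config$fs, data = sig)
}

#' Generate a full two-group synthetic cohort
#'
#' @param config a `cohort_config`
#' @return list of `eeg_recording`s (`n_smci` SMCI then `n_pmci` PMCI),
#'   with unique subject IDs and per-subject seeds derived from `config$seed`
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  groups <- c(rep("SMCI", config$n_smci), rep("PMCI", config$n_pmci))
  ids <- c(sprintf("SMCI_%03d", seq_len(config$n_smci)),
           sprintf("PMCI_%03d", seq_len(config$n_pmci)))
  lapply(seq_along(groups), function(i)
    generate_subject(config, groups[i], subject_seed = i, subject_id = ids[i]))
}
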