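test_that("band filters pass in-band tones and suppress out-of-band tones", {
  fs <- 250
  t <- seq_len(1000) / fs
  tone <- make_epoch(rbind(sin(2 * pi * 10 * t), rnorm(1000)), fs = fs)
  rms <- function(x) sqrt(mean(x^2))
  alpha <- band_filter(tone, "alpha")
  expect_gte(rms(alpha$data[1, ]) / rms(tone$data[1, ]), 0.9)
  gamma <- band_filter(tone, "gamma")
  expect_lte(rms(gamma$data[1, ]) / rms(tone$data[1, ]), 0.05)
  twice <- band_filter(alpha, "alpha")
  expect_lt(abs(rms(twice$data[1, ]) / rms(alpha$data[1, ]) - 1), 0.05)
  expect_error(band_filter(tone, c(100, 200)), "fs/2")
})

test_that("Pearson connectivity reproduces exact correlations", {
  set.seed(16)
  x <- rnorm(500)
  t <- seq_len(500) / 250
  ep <- make_epoch(rbind(x, 2 * x, -x, rnorm(500)), fs = 250)
  r <- pearson_connectivity(ep)$values
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  quad <- make_epoch(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)), fs = 250)
  expect_lt(abs(pearson_connectivity(quad)$values[1, 2]), 0.01)
  const <- make_epoch(rbind(x, rep(1, 500)), fs = 250)
  expect_true(is.na(pearson_connectivity(const)$values[1, 2]))
})

test_that("PLI is 0 for zero-lag coupling and 1 for quadrature coupling", {
  fs <- 250
  t <- seq_len(500) / fs
  s <- sin(2 * pi * 10 * t)
  same <- make_epoch(rbind(s, s), fs = fs)
  expect_equal(pli(same, band = NULL)$values[1, 2], 0)
  quarter <- make_epoch(rbind(s, sin(2 * pi * 10 * t + pi / 2)), fs = fs)
  expect_equal(pli(quarter, band = NULL)$values[1, 2], 1)
  # independent alpha-filtered noise: low PLI on average
  set.seed(17)
  nulls <- vapply(1:20, function(i) {
    ep <- make_epoch(matrix(rnorm(1000), 2), fs = fs)
    pli(ep, band = "alpha")$values[1, 2]
  }, numeric(1))
  expect_lt(mean(nulls), 0.3)
})

test_that("PLI ignores zero-lag mixing while Pearson correlation does not", {
  set.seed(18)
  fs <- 250
  vals <- vapply(1:10, function(i) {
    x <- fir_zerophase(rnorm(2000), fs, low = 8, high = 13)
    y <- fir_zerophase(rnorm(2000), fs, low = 8, high = 13)
    ep <- make_epoch(rbind(x, x + 0.1 * y), fs = fs)
    c(r = pearson_connectivity(ep)$values[1, 2],
      p = pli(ep, band = NULL)$values[1, 2])
  }, numeric(2))
  expect_gt(mean(vals["r", ]), 0.95)
  expect_lt(mean(vals["p", ]), 0.15)
})

test_that("MSC is 1 for self-coherence, high across LTI filters, low for independent noise", {
  set.seed(19)
  fs <- 250
  x <- rnorm(2000)
  self <- make_epoch(rbind(x, x), fs = fs)
  m <- msc(self, "full")$values
  expect_equal(m[1, 2], 1, tolerance = 1e-9)
  # LTI-filtered copy keeps in-band coherence near 1
  y <- fir_zerophase(x, fs, low = 2, high = 100)
  lti <- make_epoch(rbind(x, y), fs = fs)
  expect_gt(msc(lti, c(4, 40))$values[1, 2], 0.9)
  # independent noise with 8 averaged segments: biased null near 1/8
  nulls <- vapply(1:15, function(i) {
    a <- rnorm(9 * 125); b <- rnorm(9 * 125)      # 8 segments at 50% overlap
    ep <- make_epoch(rbind(a, b), fs = fs)
    msc(ep, "full", window_sec = 1)$values[1, 2]
  }, numeric(1))
  expect_lt(mean(nulls), 0.35)
  one_seg <- make_epoch(matrix(rnorm(500), 2), fs = fs)
  expect_error(msc(one_seg, "full", window_sec = 1, overlap = 0), "2 Welch segments")
})

test_that("connectivity matrices respect bounds and symmetry on random epochs", {
  for (seed in 1:5) {
    ep <- random_epoch(nch = 5, n = 600, seed = seed)
    r <- pearson_connectivity(ep)$values
    p <- pli(ep, "alpha")$values
    m <- msc(ep, "theta")$values
    expect_true(all(abs(r) <= 1 + 1e-12))
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
    expect_true(isSymmetric(r) && isSymmetric(p) && isSymmetric(m))
    expect_true(all(diag(p) == 0))
  }
})

test_that("vectorization emits 120 stably-ordered pair features that round-trip", {
  ep <- random_epoch(nch = 16, n = 500, seed = 20)
  cm <- pearson_connectivity(ep, band_name = "alpha")
  v <- vectorize_connectivity(cm)
  expect_length(v, 120L)
  expect_identical(names(v)[1], "pearson_alpha__Fp1-Fp2")
  expect_identical(names(v), names(vectorize_connectivity(cm)))
  # round-trip the strict upper triangle
  rebuilt <- matrix(0, 16, 16)
  rebuilt[upper.tri(rebuilt)] <- 0
  k <- 1L
  for (i in 1:15) for (j in (i + 1):16) { rebuilt[i, j] <- v[k]; k <- k + 1L }
  expect_equal(rebuilt[upper.tri(rebuilt)], cm$values[upper.tri(cm$values)])
})

test_that("the connectivity feature census is 2160 per 16-channel epoch", {
  ep <- random_epoch(nch = 16, n = 500, seed = 21)
  cf <- connectivity_features(ep)
  expect_length(cf, 2160L)
  expect_identical(sum(startsWith(names(cf), "pli_full__")), 120L)
  expect_identical(length(unique(names(cf))), 2160L)
})
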