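test_that("coarse-graining takes non-overlapping block means", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_identical(coarse_grain(1:7, 1), 1:7)
  expect_equal(coarse_grain(rep(5, 30), 7), rep(5, 4))
  expect_error(coarse_grain(1:3, 4), "exceeds")
})

test_that("permutation entropy matches direct pattern counting and its bounds", {
  expect_equal(permutation_entropy(1:50, m = 3), 0)
  set.seed(4)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    m <- sample(2:4, 1)
    d <- sample(1:3, 1)
    expect_equal(permutation_entropy(x, m, d), pe_brute(x, m, d), tolerance = 1e-10)
  }
  x <- rep(c(1, 3, 2, 4), 10)
  expect_equal(permutation_entropy(x, m = 2), pe_brute(x, 2), tolerance = 1e-12)
  set.seed(5)
  big <- rnorm(5000)
  expect_equal(permutation_entropy(big, m = 3), log(6), tolerance = 0.05 * log(6))
  expect_true(permutation_entropy(rnorm(100), m = 3) <= log(6))
})

test_that("approximate entropy matches the brute-force double loop", {
  expect_equal(approximate_entropy(rep(2, 50)), 0)
  per <- rep(c(1, 2), 25)
  r <- 0.2 * sd(per)
  expect_equal(approximate_entropy(per, m = 2, r = r), apen_brute(per, 2, r),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:25) {
    x <- rnorm(sample(30:120, 1))
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, r = r), apen_brute(x, 2, r),
                 tolerance = 1e-10)
  }
})

test_that("sample entropy matches the brute-force oracle and flags zero matches", {
  per <- rep(c(1, 2), 50)
  r <- 0.2 * sd(per)
  expect_equal(sample_entropy(per, m = 2, r = r), sampen_brute(per, 2, r),
               tolerance = 1e-12)
  expect_equal(sample_entropy(rep(1, 50)), 0)
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(30:120, 1))
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, m = 2, r = r), sampen_brute(x, 2, r),
                 tolerance = 1e-10)
  }
  # strongly low-passed noise is more regular than raw noise
  set.seed(8)
  wins <- vapply(1:20, function(i) {
    x <- rnorm(500)
    lp <- fir_zerophase(x, 250, low = 0, high = 5)
    sample_entropy(x) > sample_entropy(lp)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("LZ76 complexity matches hand-traceable parses and the brute-force parser", {
  expect_identical(attr(lempel_ziv(rep(3.5, 64)), "raw"),
                   lz76_brute(rep(0L, 64)))
  expect_identical(attr(lempel_ziv(rep(c(0, 1), 5)), "raw"), 3L)
  expect_identical(lz76_brute(rep(c(0L, 1L), 5)), 3L)
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(sample(10:200, 1))
    s <- as.integer(x > mean(x))
    expect_identical(attr(lempel_ziv(x), "raw"), lz76_brute(s))
  }
  set.seed(10)
  big <- rnorm(10000)
  expect_gt(as.numeric(lempel_ziv(big)), 0.8)
  expect_lt(as.numeric(lempel_ziv(big)), 1.2)
})

test_that("the Hurst exponent separates noise from integrated noise and ignores affine maps", {
  set.seed(11)
  h_noise <- vapply(1:20, function(i) hurst_exponent(rnorm(4096)), numeric(1))
  expect_gt(mean(h_noise), 0.4)
  expect_lt(mean(h_noise), 0.6)
  h_walk <- vapply(1:20, function(i) hurst_exponent(cumsum(rnorm(4096))), numeric(1))
  expect_gt(mean(h_walk), 0.85)
  expect_lt(mean(h_walk), 1.05)
  x <- rnorm(512)
  expect_equal(hurst_exponent(3 * x + 11), hurst_exponent(x), tolerance = 1e-9)
  expect_true(is.na(hurst_exponent(rep(1, 512))))
})

test_that("M-DCPSR matches an independent reimplementation and its invariances", {
  expect_equal(m_dcpsr(rep(4, 100)), 0)
  t <- seq_len(500) / 250
  sine <- sin(2 * pi * 10 * t)
  expect_equal(m_dcpsr(sine), mdcpsr_brute(sine), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(sample(30:200, 1))
    expect_equal(m_dcpsr(x), mdcpsr_brute(x), tolerance = 1e-10)
  }
  x <- rnorm(300)
  expect_equal(m_dcpsr(2.5 * x), 2.5 * m_dcpsr(x), tolerance = 1e-10)
  expect_equal(m_dcpsr(x + 40), m_dcpsr(x), tolerance = 1e-8)
})

test_that("multiscale wrappers fix the tolerance at scale 1 and degrade gracefully", {
  set.seed(13)
  x <- rnorm(500)
  ms <- multiscale("se", x)
  expect_length(ms, 10L)
  expect_equal(unname(ms["s1"]), sample_entropy(x), tolerance = 1e-12)
  # scale 10 of a 500-sample epoch works on 50 samples
  expect_equal(unname(multiscale("pe", x)["s10"]),
               permutation_entropy(coarse_grain(x, 10)), tolerance = 1e-12)
  # white noise: averaging reduces irregularity relative to the original tolerance
  drops <- vapply(1:10, function(i) {
    y <- rnorm(500)
    m <- multiscale("se", y)
    m["s1"] > m["s10"] || is.na(m["s10"])
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("entropies rank noise above a sine of matched length", {
  set.seed(14)
  t <- seq_len(500) / 250
  sine <- sin(2 * pi * 10 * t)
  wins <- vapply(1:20, function(i) {
    x <- rnorm(500)
    c(pe = permutation_entropy(x) > permutation_entropy(sine),
      ae = approximate_entropy(x) > approximate_entropy(sine),
      se = sample_entropy(x) > sample_entropy(sine),
      lz = as.numeric(lempel_ziv(x)) > as.numeric(lempel_ziv(sine)))
  }, logical(4))
  expect_gte(mean(rowMeans(wins)), 0.9)
  expect_true(all(rowMeans(wins) >= 0.9))
})

test_that("the nonlinear feature census is 528 per 16-channel epoch", {
  ep <- random_epoch(nch = 16, n = 500, seed = 15)
  nf <- nonlinear_features(ep)
  expect_length(nf, 528L)
  expect_true(all(c("pe_s1__Fp1", "se_s10__T6", "lz__O1", "hurst__C3",
                    "mdcpsr__F7") %in% names(nf)))
})
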