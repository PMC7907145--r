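# Fuzzy entropy, DFT, band features, and feature-frame assembly.

test_that("fuzzy entropy matches the brute-force definition", {
  u <- c(1, 2, 3, 4, 3, 2, 1, 2, 3, 4)
  expect_equal(fuzzy_entropy(u, fuzzyen_params(m = 2, n = 2, r_abs = 0.2)),
               fuzzyen_oracle(u, 2, 2, 0.2), tolerance = 1e-10)
  set.seed(10)
  for (i in 1:8) {
    u <- rnorm(sample(20:200, 1))
    expect_equal(fuzzy_entropy(u, fuzzyen_params(r_abs = 0.2)),
                 fuzzyen_oracle(u, 2, 2, 0.2), tolerance = 1e-10)
  }
  # non-default m and n go through the generic path
  u <- rnorm(60)
  expect_equal(fuzzy_entropy(u, fuzzyen_params(m = 3, n = 1, r_abs = 0.3)),
               fuzzyen_oracle(u, 3, 1, 0.3), tolerance = 1e-10)
})

test_that("fuzzy entropy degenerate and ordering behaviour", {
  expect_identical(fuzzy_entropy(rep(5, 100), fuzzyen_params(r_abs = 0.2)), 0)
  expect_identical(fuzzy_entropy(rep(1.5, 50)), 0)  # sd == 0, relative r
  expect_error(fuzzy_entropy(c(1, 2, 3), fuzzyen_params(m = 2)), "length")
  set.seed(1)
  noise <- rnorm(200)
  sine <- sin(2 * pi * 10 * (0:199) / 500)
  expect_gt(fuzzy_entropy(noise), fuzzy_entropy(sine))
})

test_that("fuzzy entropy invariances: shift always; scale for n = 1; monotone in r", {
  set.seed(4)
  for (i in 1:5) {
    u <- rnorm(120)
    expect_equal(fuzzy_entropy(u), fuzzy_entropy(u + 57.3), tolerance = 1e-9)
    # with the exponential membership exp(-d^n / r) and relative r the
    # value is exactly scale-free only for n = 1 (d/r is then unitless)
    p1 <- fuzzyen_params(n = 1)
    expect_equal(fuzzy_entropy(u, p1), fuzzy_entropy(3.7 * u, p1),
                 tolerance = 1e-9)
    expect_gte(fuzzy_entropy(u, fuzzyen_params(r_abs = 0.1)),
               fuzzy_entropy(u, fuzzyen_params(r_abs = 0.3)))
  }
})

test_that("fft_spectrum: trivial cases, butterfly vs direct oracle, Parseval", {
  expect_equal(fft_spectrum(c(1, 1, 1, 1))$coefficients, c(4, 0, 0, 0) + 0i,
               tolerance = 1e-12)
  expect_equal(fft_spectrum(c(1, 0, 0, 0))$coefficients, c(1, 1, 1, 1) + 0i,
               tolerance = 1e-12)
  expect_error(fft_spectrum(numeric(0)), "empty")
  set.seed(2)
  x <- rnorm(256)                       # power of two: butterfly path
  expect_lt(max(Mod(fft_spectrum(x)$coefficients - dft_oracle(x))), 1e-9)
  y <- rnorm(200)                       # direct path
  expect_lt(max(Mod(fft_spectrum(y)$coefficients - dft_oracle(y))), 1e-9)
  for (x in list(rnorm(64), rnorm(128))) {
    s <- fft_spectrum(x)$coefficients
    expect_equal(sum(x^2), sum(Mod(s)^2) / length(x), tolerance = 1e-9)
  }
})

test_that("band_feature: integer-cycle sine, zero signal, leakage bounds", {
  bands <- default_bands()
  sine <- sin(2 * pi * 10 * (0:199) / 500)
  s <- fft_spectrum(sine, fs = 500)
  expect_equal(band_feature(s, bands[[2]]), 50, tolerance = 1e-9)
  expect_lt(band_feature(s, bands[[1]]), 1e-9)
  s0 <- fft_spectrum(rep(0, 200), fs = 500)
  for (b in bands) expect_equal(band_feature(s0, b), 0)
  # disjoint integer-cycle tones stay in their own bands (< 1% leakage)
  t <- (0:199) / 500
  mix <- sin(2 * pi * 5 * t) + sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t)
  sm <- fft_spectrum(mix, fs = 500)
  expect_equal(band_feature(sm, bands[[1]]), 100, tolerance = 1)  # theta: 1 bin
  expect_lt(abs(band_feature(fft_spectrum(sin(2 * pi * 5 * t), fs = 500),
                             bands[[2]])) / 50, 0.01)
  expect_error(band_feature(fft_spectrum(rnorm(10), fs = 500),
                            band_definition("narrow", 4.1, 4.2)), "no DFT bin")
})

test_that("feature frames have the contracted shape and the fast path matches", {
  tr <- toy_trial(n_channels = 2)
  win <- sliding_windows(tr)
  ff <- feature_frames(win, feature_name = "fft")
  expect_length(ff, 6)
  expect_equal(dim(ff[[1]]$values), c(2, 3))
  expect_true(all(is.finite(unlist(lapply(ff, `[[`, "values")))))
  fast <- trial_features(tr, feature_name = "fft")
  for (k in 1:6) expect_equal(fast[[k]]$values, ff[[k]]$values, tolerance = 1e-9)
  # single-channel single-window input
  one <- feature_frames(win[1], feature_name = "fft")
  expect_equal(dim(one[[1]]$values), c(2, 3))
})

test_that("fuzzyen trial features equal elementwise recomputation on the filtered trial", {
  tr <- toy_trial(n_channels = 2, seed = 9)
  fast <- trial_features(tr, feature_name = "fuzzyen")
  bands <- default_bands()
  for (b in 1:3) {
    filt <- bandpass(tr$data, bands[[b]], tr$sampling_rate)
    for (k in c(1, 4)) {
      idx <- ((k - 1) * 100 + 1):((k - 1) * 100 + 200)
      for (ch in 1:2) {
        expect_equal(unname(fast[[k]]$values[ch, b]),
                     fuzzy_entropy(filt[ch, idx]), tolerance = 1e-9,
                     label = sprintf("band %d win %d ch %d", b, k, ch))
      }
    }
  }
})
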