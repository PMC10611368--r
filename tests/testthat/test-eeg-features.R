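test_that("band_power concentrates a pure tone and splits white noise by width", {
  fs <- 128
  x <- sin(2 * pi * 10 * seq_len(8 * fs) / fs)
  bp <- vapply(eeg_bands(), function(b) band_power(x, fs, b), numeric(1))
  expect_gte(bp["alpha"] / max(bp[c("delta", "theta", "beta")]), 50)
  expect_equal(unname(vapply(eeg_bands(), function(b) band_power(numeric(fs * 2), fs, b),
                             numeric(1))), rep(0, 4))
  expect_error(band_power(x, fs, c(10, 100)), "fs/2")

  perhz <- rowMeans(vapply(1:20, function(s) {
    set.seed(s)
    w <- rnorm(1024)
    vapply(eeg_bands(), function(b) band_power(w, fs, b), numeric(1)) /
      c(4, 4, 4, 18)
  }, numeric(4)))
  expect_true(all(abs(perhz / mean(perhz) - 1) < 0.25))
})

test_that("entropies equal brute-force oracles and behave on canonical signals", {
  cfg <- entropy_config()
  set.seed(11)
  for (k in 1:10) {
    n <- sample(40:150, 1)
    x <- rnorm(n)
    # both sides return NA when no template pair matches at tolerance r
    expect_equal(suppressWarnings(sample_entropy(x, cfg)), oracle_sample_entropy(x),
                 tolerance = 1e-12)
    expect_equal(approximate_entropy(x, cfg), oracle_approximate_entropy(x),
                 tolerance = 1e-12)
    expect_equal(fuzzy_entropy(x, cfg), oracle_fuzzy_entropy(x), tolerance = 1e-12)
  }

  per <- rep(c(0, 1), 40)
  expect_equal(sample_entropy(per, cfg), 0)
  expect_lt(fuzzy_entropy(per, cfg), 0.05)
  expect_equal(approximate_entropy(rep(1, 60) + numeric(60), cfg), 0)

  # noise is less regular than a sinusoid of the same length
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    no <- rnorm(1000)
    si <- sin(2 * pi * 5 * seq_len(1000) / 128)
    c(sample_entropy(no, cfg) > sample_entropy(si, cfg),
      approximate_entropy(no, cfg) > approximate_entropy(si, cfg))
  }, logical(2))
  expect_true(all(wins))

  # fuzzy entropy grows with the noise floor on a noisy sinusoid
  ord_ok <- vapply(1:10, function(s) {
    set.seed(s)
    t <- seq_len(500) / 128
    v <- vapply(c(0, 0.25, 0.5, 1), function(a)
      fuzzy_entropy(sin(2 * pi * 6 * t) + a * rnorm(500), entropy_config()), numeric(1))
    all(diff(v) > 0)
  }, logical(1))
  expect_gt(mean(ord_ok), 0.5)
})

test_that("entropies are amplitude-scale invariant and flag degenerate input", {
  set.seed(3)
  x <- rnorm(300)
  cfg <- entropy_config()
  expect_lt(abs(sample_entropy(10 * x, cfg) - sample_entropy(x, cfg)), 1e-9)
  expect_lt(abs(fuzzy_entropy(10 * x, cfg) - fuzzy_entropy(x, cfg)), 1e-9)
  expect_lt(abs(approximate_entropy(10 * x, cfg) - approximate_entropy(x, cfg)), 1e-9)
  expect_warning(v <- sample_entropy(rep(1, 50) + numeric(50), cfg), "constant")
  expect_true(is.na(v))
  expect_warning(sz <- spectral_entropy(numeric(256), 128), "zero signal")
  expect_true(is.na(sz))
})

test_that("spectral entropy orders tone < two tones < noise", {
  fs <- 128
  t <- seq_len(512) / fs
  one <- spectral_entropy(sin(2 * pi * 10 * t), fs)
  two <- spectral_entropy(sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t), fs)
  set.seed(1)
  noi <- mean(vapply(1:10, function(s) {
    set.seed(s); spectral_entropy(rnorm(4096), fs)
  }, numeric(1)))
  expect_lte(one, 0.2)
  expect_gt(two, one)
  expect_lt(two, noi)
  expect_gte(noi, 0.9)
})

test_that("extract_eeg_features yields 8 features per channel and separates presets", {
  rec <- gen_eeg(eeg_preset("alert", 20, 128, seed = 6))
  ft <- extract_eeg_features(epoch_signal(preprocess_eeg(rec), 5, 0))
  expect_equal(dim(as.data.frame(ft)), c(4L, 16L))
  expect_true(all(c("P3_delta", "P4_approx_en", "P3_fuzzy_en") %in% feature_names(ft)))
  expect_true(all(is.finite(as.matrix(as.data.frame(ft)[feature_names(ft)]))))

  # band powers barely move when a 50 Hz tone is added before preprocessing
  t50 <- sin(2 * pi * 50 * seq_len(20 * 128) / 128)
  rec2 <- rec; rec2$samples <- rec$samples + t50
  bp1 <- vapply(eeg_bands(), function(b)
    band_power(preprocess_eeg(rec)$samples[, 1], 128, b), numeric(1))
  bp2 <- vapply(eeg_bands(), function(b)
    band_power(preprocess_eeg(rec2)$samples[, 1], 128, b), numeric(1))
  expect_true(all(abs(bp2 / bp1 - 1) < 0.05))

  # theta power separates the presets
  fa <- extract_eeg_features(epoch_signal(preprocess_eeg(
    gen_eeg(eeg_preset("alert", 150, 128, seed = 21))), labels = "alert"))
  ff <- extract_eeg_features(epoch_signal(preprocess_eeg(
    gen_eeg(eeg_preset("fatigued", 150, 128, seed = 22))), labels = "fatigued"))
  expect_lt(t.test(fa$P3_theta, ff$P3_theta)$p.value, 0.05)

  p <- file.path(tempdir(), "eegft.csv")
  write_feature_table(fa, p)
  expect_equal(read_feature_table(p)$P3_theta, fa$P3_theta, tolerance = 1e-12)
})
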