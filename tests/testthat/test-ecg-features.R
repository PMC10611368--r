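test_that("qrs_kernel matches the stated sine phases", {
  k <- qrs_kernel()
  expect_length(k, 15L)
  expect_equal(k[1], -1)
  expect_equal(k[8], 1)
  expect_equal(k[15], -1)
  expect_equal(k, rev(k), tolerance = 1e-12)   # symmetric about the centre tap
  expect_lt(sum(k), 0)                         # negative lobes dominate
})

test_that("R-peak detection recovers ground truth", {
  ge <- gen_ecg(ecg_synth_spec(10, 256, 800, rr_jitter_sd_ms = 0, seed = 1))
  pk <- detect_r_peaks(preprocess_ecg(ge$record))
  expect_length(pk$indices, length(ge$true_r_times))
  det_t <- (pk$indices - 1) / 256
  expect_lt(max(vapply(det_t, function(d) min(abs(d - ge$true_r_times)), numeric(1))),
            0.020)

  flat <- signal_record(numeric(1024), 256, "z", "ECG")
  expect_warning(pk0 <- detect_r_peaks(flat), "no R-peaks")
  expect_length(pk0$indices, 0L)

  ge2 <- gen_ecg(ecg_synth_spec(60, 256, 800, rr_jitter_sd_ms = 20, seed = 3))
  pk2 <- detect_r_peaks(preprocess_ecg(ge2$record))
  m <- match_events((pk2$indices - 1) / 256, ge2$true_r_times, tol = 0.05)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("detection is invariant to amplitude scaling and time shifts", {
  ge <- gen_ecg(ecg_synth_spec(20, 256, 750, rr_jitter_sd_ms = 15, seed = 5))
  pre <- preprocess_ecg(ge$record)
  pk <- detect_r_peaks(pre)

  big <- pre; big$samples <- pre$samples * 10
  expect_identical(detect_r_peaks(big)$indices, pk$indices)

  k <- 37L
  x <- pre$samples[, 1]
  shifted <- signal_record(c(x[(length(x) - k + 1L):length(x)], x[1:(length(x) - k)]),
                           256, "s", "ECG")
  pks <- detect_r_peaks(shifted)$indices
  # compare away from the wrap-around boundary
  interior <- pk$indices[pk$indices > 256 & pk$indices < length(x) - 2 * 256]
  expect_true(all((interior + k) %in% pks))
})

test_that("rr_intervals converts indices and enforces monotonicity", {
  pk <- structure(list(indices = c(0L, 256L, 512L) + 1L, fs = 256),
                  class = "rpeak_series")
  rr <- rr_intervals(pk)
  expect_equal(rr$intervals_ms, c(1000, 1000))
  expect_equal(rr$n, 2L)
  pk11 <- structure(list(indices = cumsum(rep(200L, 11)), fs = 256),
                    class = "rpeak_series")
  expect_equal(rr_intervals(pk11)$n, 10L)
  bad <- structure(list(indices = c(10L, 5L), fs = 256), class = "rpeak_series")
  expect_error(rr_intervals(bad), "increasing")
  one <- structure(list(indices = 5L, fs = 256), class = "rpeak_series")
  expect_error(rr_intervals(one), "2 peaks")
})

test_that("hrv_features reproduces hand-computed values and stated symmetries", {
  h <- hrv_features(c(800, 810, 800, 810))
  expect_equal(h$rmssd, 10)
  expect_equal(h$avrr, 805)
  expect_equal(h$skew, 0)

  expect_warning(hc <- hrv_features(rep(800, 5)), "undefined")
  expect_equal(hc$rmssd, 0)
  expect_equal(hc$sdrr, 0)
  expect_true(is.na(hc$skew) && is.na(hc$kurt))

  set.seed(8)
  for (k in 1:100) {
    rr <- runif(sample(4:30, 1), 500, 1200)
    a <- hrv_features(rr); b <- oracle_hrv(rr)
    for (f in names(b)) expect_equal(a[[f]], b[[f]], tolerance = 1e-9)
  }

  rr <- runif(20, 600, 1000)
  fwd <- hrv_features(rr); rev_ <- hrv_features(rev(rr))
  expect_equal(fwd$rmssd, rev_$rmssd)
  expect_equal(fwd$sdrr, rev_$sdrr)
  refl <- hrv_features(2 * fwd$avrr - rr)
  expect_equal(refl$skew, -fwd$skew, tolerance = 1e-9)
  expect_equal(refl$kurt, fwd$kurt, tolerance = 1e-9)

  # Gaussian RR: skew ~ 0, excess kurtosis ~ 0
  mom <- rowMeans(vapply(1:20, function(s) {
    set.seed(s)
    h <- hrv_features(rnorm(10000, 800, 50))
    c(h$skew, h$kurt)
  }, numeric(2)))
  expect_lt(abs(mom[1]), 0.1)
  expect_lt(abs(mom[2]), 0.15)
})

test_that("extract_ecg_features produces one HRV row per epoch", {
  ge <- gen_ecg(ecg_synth_spec(60, 256, 800, rr_jitter_sd_ms = 10, seed = 2))
  ep <- epoch_signal(preprocess_ecg(ge$record), 5, 0)
  ft <- extract_ecg_features(ep)
  expect_equal(dim(as.data.frame(ft)), c(12L, 5L))
  expect_equal(feature_names(ft), c("rmssd", "avrr", "sdrr", "skew", "kurt"))
  expect_true(all(abs(ft$avrr - 800) < 50))

  # RR jitter separates low- from high-variability recordings
  lo <- extract_ecg_features(epoch_signal(preprocess_ecg(
    gen_ecg(ecg_synth_spec(120, 256, 800, 4, seed = 31))$record), labels = "alert"))
  hi <- extract_ecg_features(epoch_signal(preprocess_ecg(
    gen_ecg(ecg_synth_spec(120, 256, 800, 30, seed = 32))$record), labels = "fatigued"))
  expect_lt(t.test(lo$rmssd, hi$rmssd)$p.value, 0.05)

  p <- file.path(tempdir(), "ecgft.csv")
  write_feature_table(lo, p)
  expect_equal(read_feature_table(p)$rmssd, lo$rmssd, tolerance = 1e-12)
})
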