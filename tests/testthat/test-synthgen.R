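test_that("gen_eeg honours band weights, determinism and the zero case", {
  spec <- eeg_synth_spec("alert", 10, 128, c(delta = 1, theta = 1, alpha = 1, beta = 3),
                         seed = 7)
  rec <- gen_eeg(spec)
  expect_s3_class(rec, "signal_record")
  expect_equal(dim(rec$samples), c(1280L, 2L))
  expect_equal(rec$channel_names, c("P3", "P4"))
  bp <- vapply(eeg_bands(), function(b) band_power(rec$samples[, 1], 128, b), numeric(1))
  expect_equal(names(which.max(bp)), "beta")

  expect_identical(gen_eeg(spec)$samples, gen_eeg(spec)$samples)

  z <- gen_eeg(eeg_synth_spec("alert", 2, 128,
                              c(delta = 0, theta = 0, alpha = 0, beta = 0),
                              noise_sd = 0, seed = 1))
  expect_true(all(z$samples == 0))

  expect_error(eeg_synth_spec("alert", -1, 128, c(delta = 1, theta = 1, alpha = 1, beta = 1)),
               "duration")
  expect_error(eeg_synth_spec("alert", 10, 50, c(delta = 1, theta = 1, alpha = 1, beta = 1)),
               "fs")
})

test_that("EEG band-power ordering holds in expectation over seeds", {
  bands <- eeg_bands()
  for (top in c("theta", "beta")) {
    w <- c(delta = 1, theta = 1, alpha = 1, beta = 1)
    w[top] <- 4
    wins <- vapply(1:20, function(s) {
      rec <- gen_eeg(eeg_synth_spec("alert", 6, 128, w, noise_sd = 0.1, seed = s),
                     n_channels = 1L)
      bp <- vapply(bands, function(b) band_power(rec$samples[, 1], 128, b), numeric(1))
      names(which.max(bp)) == top
    }, logical(1))
    expect_gt(mean(wins), 0.9)
  }
})

test_that("gen_ecg places beats as specified", {
  ge <- gen_ecg(ecg_synth_spec(10, 256, 800, rr_jitter_sd_ms = 0, seed = 1))
  expect_equal(diff(ge$true_r_times), rep(0.8, length(ge$true_r_times) - 1))
  expect_lte(abs(length(ge$true_r_times) - floor(10 * 1000 / 800)), 1)
  expect_equal(nrow(ge$record$samples), 2560L)

  # RR-diff SD tracks the jitter parameter (Monte-Carlo over 20 seeds)
  sds <- vapply(1:20, function(s) {
    sd(diff(gen_ecg(ecg_synth_spec(60, 256, 800, 20, seed = s))$true_r_times)) * 1000
  }, numeric(1))
  expect_lt(abs(mean(sds) - 20), 3 * 20 / sqrt(70) )  # 3 sigma of an SD estimate

  expect_error(ecg_synth_spec(10, 256, mean_rr_ms = 100), "mean_rr_ms")
  expect_error(ecg_synth_spec(10, 50, mean_rr_ms = 800), "fs")
})

test_that("gen_label_stream concatenates scripted segments", {
  m <- gen_label_stream(scenario_script(list(list(duration_s = 5, labels = c(1, 3, 4, 7)))))
  expect_equal(dim(m), c(4L, 5L))
  expect_true(all(m == c(1L, 3L, 4L, 7L)))

  # two segments reproducing the printed example window column by column
  segs <- list(list(1, c(0, 2, 4, 7)), list(1, c(1, 3, 4, 7)), list(1, c(1, 3, 4, 7)),
               list(1, c(1, 2, 4, 7)), list(1, c(1, 3, 4, 7)))
  m2 <- gen_label_stream(scenario_script(segs))
  expect_equal(unclass(m2), unclass(example_window()), ignore_attr = TRUE)

  expect_equal(dim(gen_label_stream(scenario_script(list()))), c(4L, 0L))
  expect_error(scenario_script(list(list(duration_s = 2, labels = c(9, 3, 4, 7)))),
               "alphabet")
})

test_that("gen_images is deterministic, counted and size-checked", {
  g <- gen_images(10, c(0L, 1L), 64, seed = 1)
  expect_length(g$images, 20L)
  expect_equal(as.vector(table(g$labels)), c(10L, 10L))
  expect_identical(g, gen_images(10, c(0L, 1L), 64, seed = 1))
  expect_error(gen_images(10, c(0L, 1L), 4, seed = 1), "size")
  expect_error(gen_images(0, c(0L, 1L), 64, seed = 1), "n_per_class")

  # PPM round-trip is exact at 8-bit quantisation
  p <- file.path(tempdir(), "im.ppm")
  write_ppm(g$images[[1]], p)
  back <- read_ppm(p)
  expect_equal(back, round(g$images[[1]] * 255) / 255, tolerance = 1e-12)
})
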