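test_that("label matrices grow by one validated column per second", {
  m <- label_matrix()
  expect_equal(dim(m), c(4L, 0L))
  m <- append_second(m, c(1, 3, 4, 7))
  expect_equal(dim(m), c(4L, 1L))
  expect_error(append_second(m, c(9, 3, 4, 7)), "alphabet")
  for (i in 1:59) m <- append_second(m, c(1, 3, 4, 7))
  expect_equal(ncol(m), 60L)
})

test_that("window modes reproduce the printed example and count frequencies", {
  w <- example_window()
  expect_equal(window_modes(w), c(1L, 3L, 4L, 7L))
  cst <- label_matrix(matrix(rep(c(0L, 2L, 4L, 6L), 5), nrow = 4))
  expect_equal(window_modes(cst), c(0L, 2L, 4L, 6L))
  r <- label_matrix(rbind(c(0L, 0L, 1L, 1L, 0L), rep(2L, 5), rep(4L, 5), rep(6L, 5)))
  expect_equal(window_modes(r)[1], 0L)
  expect_null(window_modes(label_matrix(matrix(c(0L, 2L, 4L, 6L), 4, 3))))
  # even-window tie breaks toward the abnormal label
  tie <- label_matrix(rbind(c(0L, 0L, 1L, 1L), rep(2L, 4), rep(4L, 4), rep(6L, 4)))
  expect_equal(window_modes(tie, window = 4L)[1], 1L)
})

test_that("the default dictionary maps the stated patterns", {
  d <- default_pattern_dictionary()
  expect_equal(map_pattern(c(1, 3, 4, 7), d), "severe")
  for (p in list(c(1, 3, 5, 7), c(1, 3, 5, 6), c(1, 3, 4, 6))) {
    expect_equal(map_pattern(p, d), "mild")
  }
  expect_equal(map_pattern(c(0, 2, 4, 6), d), "normal")

  # exactly 1 severe and 3 mild among all 16 tuples
  lv <- character(0)
  for (a in 0:1) for (b in 2:3) for (c in 4:5) for (dd in 6:7) {
    lv <- c(lv, map_pattern(c(a, b, c, dd), d))
  }
  expect_equal(sum(lv == "severe"), 1L)
  expect_equal(sum(lv == "mild"), 3L)
  expect_equal(sum(lv == "normal"), 12L)

  # JSON round trip preserves the mapping
  p <- file.path(tempdir(), "dict.json")
  write_pattern_dictionary(d, p)
  d2 <- read_pattern_dictionary(p)
  expect_equal(map_pattern(c(1, 3, 4, 7), d2), "severe")
  expect_equal(map_pattern(c(0, 2, 4, 6), d2), "normal")
})

test_that("the prose-rule dictionary excuses phone-explained departures", {
  d <- prose_rule_dictionary()
  expect_equal(map_pattern(c(1, 3, 5, 7), d), "normal")  # phone explains departure
  expect_equal(map_pattern(c(1, 2, 4, 7), d), "severe")  # departure + abnormal EEG
  expect_equal(map_pattern(c(1, 2, 4, 6), d), "mild")    # biosignal only
  expect_equal(map_pattern(c(0, 2, 4, 6), d), "normal")
})

test_that("persistence gating follows the stated update rule", {
  m <- gen_label_stream(scenario_script(list(list(duration_s = 10, labels = c(1, 3, 4, 7)))))
  fb <- feedback_stream(m, t_persist = 3)
  expect_equal(nrow(fb), 10L - 4L)
  expect_equal(fb$delta_t, 0:5)
  expect_equal(fb$level, c(rep("normal", 4), rep("severe_fatigue", 2)))
  # level flips to severe exactly when delta_t first exceeds 3 s
  expect_equal(min(fb$window_end_time[fb$level == "severe_fatigue"]), 9)

  fbinf <- feedback_stream(m, t_persist = Inf)
  expect_true(all(fbinf$level == "normal"))

  alt <- gen_label_stream(scenario_script(lapply(1:12, function(i)
    list(duration_s = 1, labels = if (i %% 2) c(1, 3, 4, 7) else c(0, 2, 4, 6)))))
  fba <- feedback_stream(alt, t_persist = 0)
  expect_true(all(fba$level == "normal"))

  # every non-normal emission satisfies the invariant
  mixed <- gen_label_stream(scenario_script(list(
    list(duration_s = 8, labels = c(1, 3, 4, 7)),
    list(duration_s = 6, labels = c(1, 3, 5, 6)),
    list(duration_s = 6, labels = c(0, 2, 4, 6)))))
  fbm <- feedback_stream(mixed, t_persist = 2)
  bad <- fbm$level != "normal"
  expect_true(all(fbm$delta_t[bad] > 2))
  expect_true(all(ifelse(fbm$level == "severe_fatigue", fbm$key == "severe",
                         ifelse(fbm$level == "mild_fatigue", fbm$key == "mild", TRUE))))

  # label-stream CSV round trip
  p <- file.path(tempdir(), "stream.csv")
  write_label_stream(mixed, p)
  expect_equal(unclass(read_label_stream(p)), unclass(mixed), ignore_attr = TRUE)
})
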