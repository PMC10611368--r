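# Synthetic EEG / ECG / label-stream / image generators. These state the
# world the test suite runs in: EEG is band-limited filtered noise whose
# expected band powers are proportional to the requested weights; ECG is a
# PQRST-like Gaussian-bump train with controllable RR mean, jitter and slow
# drift; label streams are scripted 4-row second-by-second matrices; images
# are simple geometric motifs, one per class. Every generator is a pure
# function of its spec (including the seed).

#' EEG synthesis specification
#'
#' @param state `"alert"` or `"fatigued"` (a tag carried into epoch labels)
#' @param duration_s duration in seconds (> 0)
#' @param fs sampling rate in Hz; at least twice the highest band edge
#' @param band_weights named relative-power weights for `delta`, `theta`,
#'   `alpha`, `beta`; all >= 0, at least one > 0 (unless synthesising the
#'   all-zero signal)
#' @param noise_sd SD of added broadband white noise (amplitude units)
#' @param seed integer RNG seed
#' @return an `eeg_synth_spec`
#' @export
eeg_synth_spec <- function(state = c("alert", "fatigued"), duration_s, fs,
                           band_weights, noise_sd = 0.2, seed = 1L) {
  state <- match.arg(state)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  bands <- eeg_bands()
  if (fs < 2 * max(vapply(bands, max, numeric(1)))) {
    stop("fs must be at least twice the highest band edge (>= 60 Hz)", call. = FALSE)
  }
  if (!all(names(bands) %in% names(band_weights))) {
    stop("band_weights needs entries delta, theta, alpha, beta", call. = FALSE)
  }
  w <- unlist(band_weights)[names(bands)]
  if (any(w < 0)) stop("band_weights must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(state = state, duration_s = duration_s, fs = fs,
                 band_weights = w, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "eeg_synth_spec")
}

#' Preset EEG synthesis specs for the two driver states
#'
#' Conventions, not empirical claims: the fatigued preset raises theta and
#' alpha weights and lowers beta relative to the alert preset, the pattern
#' the drowsiness literature most often reports; it also carries less
#' broadband noise, making the signal more regular (lower entropy). Both are
#' fully overridable via [eeg_synth_spec()].
#'
#' @param state `"alert"` or `"fatigued"`
#' @param duration_s,fs,seed passed through
#' @return an `eeg_synth_spec`
#' @export
eeg_preset <- function(state = c("alert", "fatigued"), duration_s = 60,
                       fs = 128, seed = 1L) {
  state <- match.arg(state)
  if (state == "alert") {
    eeg_synth_spec("alert", duration_s, fs,
                   c(delta = 1.0, theta = 0.7, alpha = 1.0, beta = 2.2),
                   noise_sd = 0.6, seed = seed)
  } else {
    eeg_synth_spec("fatigued", duration_s, fs,
                   c(delta = 1.2, theta = 2.4, alpha = 2.0, beta = 0.7),
                   noise_sd = 0.25, seed = seed)
  }
}

# white noise band-limited by a 4th-order Butterworth per band, rescaled to
# unit empirical SD so band power tracks the requested weight
band_limited_noise <- function(n, fs, band, order = 4) {
  x <- stats::rnorm(n)
  if (band[1] <= 0) {
    y <- sos_filtfilt(butter_design(order, band[2], fs, "low"), x)
  } else {
    hp <- butter_design(order, band[1], fs, "high")
    lp <- butter_design(order, min(band[2], fs / 2 * 0.999), fs, "low")
    y <- sos_filtfilt(lp, sos_filtfilt(hp, x))
  }
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate synthetic multichannel EEG
#'
#' Each channel is an independent sum of band-limited noise components, one
#' per canonical band, scaled so the expected power in band b is
#' proportional to `band_weights[b]`, plus white noise of SD `noise_sd`.
#'
#' @param spec an [eeg_synth_spec()] (or [eeg_preset()])
#' @param n_channels number of channels; the first two are named P3 and P4
#' @return a `signal_record` of EEG modality
#' @export
gen_eeg <- function(spec, n_channels = 2L) {
  stopifnot(inherits(spec, "eeg_synth_spec"))
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration_s * spec$fs))
  bands <- eeg_bands()
  out <- matrix(0, n, n_channels)
  for (ch in seq_len(n_channels)) {
    x <- numeric(n)
    for (b in names(bands)) {
      w <- spec$band_weights[[b]]
      if (w > 0) x <- x + sqrt(w) * band_limited_noise(n, spec$fs, bands[[b]])
    }
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
    out[, ch] <- x
  }
  nm <- c("P3", "P4", paste0("ch", seq_len(max(0L, n_channels - 2L)) + 2L))[seq_len(n_channels)]
  rec <- signal_record(out, spec$fs, channel_names = nm, modality = "EEG")
  rec$state <- spec$state
  rec
}

#' ECG synthesis specification
#'
#' @param duration_s duration in seconds
#' @param fs sampling rate in Hz (>= 100)
#' @param mean_rr_ms mean RR interval in ms, within \[300, 2000\]
#' @param rr_jitter_sd_ms SD of i.i.d. Gaussian RR perturbation (ms, >= 0)
#' @param rr_drift amplitude of a slow sinusoidal RR modulation (fraction of
#'   `mean_rr_ms`; period 30 s), emulating respiratory-like drift
#' @param seed integer RNG seed
#' @return an `ecg_synth_spec`
#' @export
ecg_synth_spec <- function(duration_s, fs, mean_rr_ms = 800,
                           rr_jitter_sd_ms = 0, rr_drift = 0, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (mean_rr_ms < 300 || mean_rr_ms > 2000) {
    stop("mean_rr_ms must lie in [300, 2000]", call. = FALSE)
  }
  if (rr_jitter_sd_ms < 0) stop("rr_jitter_sd_ms must be >= 0", call. = FALSE)
  structure(list(duration_s = duration_s, fs = fs, mean_rr_ms = mean_rr_ms,
                 rr_jitter_sd_ms = rr_jitter_sd_ms, rr_drift = rr_drift,
                 seed = as.integer(seed)),
            class = "ecg_synth_spec")
}

# PQRST template: Gaussian bumps, offsets/widths in seconds relative to R
pqrst_waves <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             offset = c(-0.160, -0.025, 0.000, 0.030, 0.250),
             amp    = c(0.15, -0.12, 1.00, -0.25, 0.35),
             width  = c(0.025, 0.010, 0.012, 0.010, 0.060))
}

#' Generate a synthetic ECG beat train with ground-truth R times
#'
#' Beats are placed at times whose successive differences are `mean_rr_ms`
#' perturbed by `N(0, rr_jitter_sd_ms^2)` plus a slow sinusoidal drift; each
#' beat contributes five Gaussian bumps (P, Q, R, S, T) with the R wave
#' dominant.
#'
#' @param spec an [ecg_synth_spec()]
#' @return list with `record` (single-channel ECG `signal_record`) and
#'   `true_r_times` (seconds)
#' @export
gen_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_synth_spec"))
  set.seed(spec$seed)
  mean_rr_s <- spec$mean_rr_ms / 1000
  t_beat <- mean_rr_s / 2
  beats <- numeric(0)
  while (t_beat <= spec$duration_s - 0.3) {   # margin so the T wave fits
    beats <- c(beats, t_beat)
    rr <- mean_rr_s +
      stats::rnorm(1, sd = spec$rr_jitter_sd_ms / 1000) +
      spec$rr_drift * mean_rr_s * sin(2 * pi * t_beat / 30)
    t_beat <- t_beat + max(0.3, rr)
  }
  n <- as.integer(round(spec$duration_s * spec$fs))
  tt <- (seq_len(n) - 1L) / spec$fs
  x <- numeric(n)
  wv <- pqrst_waves()
  for (tb in beats) {
    lo <- max(1L, floor((tb - 0.35) * spec$fs))
    hi <- min(n, ceiling((tb + 0.45) * spec$fs))
    idx <- lo:hi
    for (w in seq_len(nrow(wv))) {
      x[idx] <- x[idx] + wv$amp[w] *
        exp(-((tt[idx] - tb - wv$offset[w])^2) / (2 * wv$width[w]^2))
    }
  }
  rec <- signal_record(x, spec$fs, channel_names = "ECG", modality = "ECG")
  list(record = rec, true_r_times = beats)
}

fusion_row_alphabets <- function() {
  list(eeg = c(0L, 1L), ecg = c(2L, 3L), phone = c(4L, 5L), lane = c(6L, 7L))
}

#' Scenario script for label-stream synthesis
#'
#' @param segments list of segments, each a list/vector with `duration_s`
#'   (whole seconds) and `labels` (length-4 integer vector, one label per
#'   fusion row, drawn from the row alphabets 0/1, 2/3, 4/5, 6/7)
#' @param seed integer (reserved for stochastic scripts; current segments
#'   are deterministic)
#' @return a `scenario_script`
#' @export
scenario_script <- function(segments, seed = 1L) {
  segments <- lapply(segments, function(s) {
    s <- as.list(s)
    names(s)[1:2] <- c("duration_s", "labels")
    s$labels <- as.integer(s$labels)
    validate_fusion_labels(s$labels)
    if (s$duration_s < 1 || s$duration_s != round(s$duration_s)) {
      stop("segment duration must be a whole number of seconds", call. = FALSE)
    }
    s
  })
  structure(list(segments = segments, seed = as.integer(seed)),
            class = "scenario_script")
}

validate_fusion_labels <- function(labels) {
  if (length(labels) != 4L) stop("need one label per fusion row (4)", call. = FALSE)
  alph <- fusion_row_alphabets()
  for (r in 1:4) {
    if (!labels[r] %in% alph[[r]]) {
      stop(sprintf("row %d label %d outside its alphabet {%s}",
                   r, labels[r], paste(alph[[r]], collapse = ",")), call. = FALSE)
    }
  }
  invisible(labels)
}

#' Generate a 4-row label stream from a scenario script
#'
#' One column per second, concatenating the script's segments in order.
#'
#' @param script a [scenario_script()] (or a bare list of segments)
#' @return a `label_matrix` (4 x total seconds integer matrix)
#' @export
gen_label_stream <- function(script) {
  if (!inherits(script, "scenario_script")) script <- scenario_script(script)
  cols <- lapply(script$segments, function(s) {
    matrix(rep(s$labels, s$duration_s), nrow = 4L)
  })
  m <- if (length(cols) > 0) do.call(cbind, cols) else matrix(integer(0), nrow = 4L)
  label_matrix(m)
}

#' Generate labelled fixture images
#'
#' Renders one geometric motif per class (filled disc, horizontal bar,
#' vertical bar, hollow square, cycling for more classes) on a dark noisy
#' background, with seed-controlled position jitter. Deterministic given the
#' seed.
#'
#' @param n_per_class images per class (>= 1)
#' @param classes integer class labels (used verbatim)
#' @param size image side in pixels (>= 8)
#' @param seed integer RNG seed
#' @return list with `images` (list of size x size x 3 arrays in \[0, 1\])
#'   and `labels` (integer vector)
#' @export
gen_images <- function(n_per_class, classes = c(0L, 1L), size = 64L, seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (size < 8L) stop("size must be >= 8 px", call. = FALSE)
  set.seed(as.integer(seed))
  size <- as.integer(size)
  imgs <- list(); labs <- integer(0)
  cx <- matrix(rep(seq_len(size), size), size, size)        # column index
  cy <- t(cx)                                               # row index
  for (ci in seq_along(classes)) {
    motif <- (ci - 1L) %% 4L
    for (k in seq_len(n_per_class)) {
      img <- array(stats::runif(size * size * 3, 0, 0.15), dim = c(size, size, 3))
      jx <- stats::runif(1, -0.15, 0.15) * size
      jy <- stats::runif(1, -0.15, 0.15) * size
      mx <- size / 2 + jx; my <- size / 2 + jy
      mask <- switch(as.character(motif),
        "0" = (cx - mx)^2 + (cy - my)^2 <= (size / 5)^2,                 # disc
        "1" = abs(cy - my) <= size / 10,                                 # horizontal bar
        "2" = abs(cx - mx) <= size / 10,                                 # vertical bar
        "3" = pmax(abs(cx - mx), abs(cy - my)) <= size / 4 &
              pmax(abs(cx - mx), abs(cy - my)) >= size / 6)              # square ring
      col <- c(0.9, 0.8, 0.2)
      for (p in 1:3) {
        plane <- img[, , p]
        plane[mask] <- col[p]
        img[, , p] <- plane
      }
      imgs[[length(imgs) + 1L]] <- img
      labs <- c(labs, as.integer(classes[ci]))
    }
  }
  list(images = imgs, labels = labs)
}

#' Write / read an image as plain-text PPM (P3)
#'
#' ASCII PPM keeps fixtures text-only and byte-stable; intensities are
#' quantised to 0-255.
#'
#' @param img a H x W x 3 numeric array in \[0, 1\]
#' @param path output path (`.ppm`)
#' @return `path` invisibly (`write`); a H x W x 3 array (`read`)
#' @export
write_ppm <- function(img, path) {
  d <- dim(img)
  v <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  # P3 stores row-major RGB triples
  arr <- array(v, dim = d)
  triples <- character(d[1])
  for (i in seq_len(d[1])) {
    row <- rbind(arr[i, , 1], arr[i, , 2], arr[i, , 3])
    triples[i] <- paste(as.vector(row), collapse = " ")
  }
  writeLines(c("P3", paste(d[2], d[1]), "255", triples), path)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  stopifnot(txt[1] == "P3")
  hd <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  w <- hd[1]; h <- hd[2]
  vals <- as.integer(unlist(strsplit(trimws(paste(txt[-(1:3)], collapse = " ")), "\\s+")))
  stopifnot(length(vals) == w * h * 3)
  img <- array(0, dim = c(h, w, 3))
  m <- matrix(vals, nrow = 3)            # columns are pixels, row-major
  px <- 0L
  for (i in seq_len(h)) {
    img[i, , 1] <- m[1, px + seq_len(w)]
    img[i, , 2] <- m[2, px + seq_len(w)]
    img[i, , 3] <- m[3, px + seq_len(w)]
    px <- px + w
  }
  img / 255
}
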