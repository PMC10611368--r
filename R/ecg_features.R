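# R-peak detection by matched filtering with a one-cycle sine kernel, and
# time-domain HRV statistics with the exact denominator conventions of the
# recognition engine (RMSSD and SDRR over N-1; skewness and excess kurtosis
# over N * SDRR^k).

#' QRS matched-filter configuration
#'
#' The kernel is a sine evaluated at `kernel_len` equally spaced phases from
#' `1.5 * pi` to `3.5 * pi` inclusive (one full cycle starting and ending at
#' -1, peaking at +1 mid-kernel) -- at 256 Hz its 15 taps span about 55 ms,
#' the width of a QRS complex.
#'
#' @param kernel_phase start/end phase in radians (default `c(1.5, 3.5) * pi`)
#' @param kernel_len number of taps (default 15)
#' @param sim_threshold similarity threshold T in (0, 1) on the normalised
#'   correlation (default 0.3)
#' @param refractory_ms minimum peak separation in ms (default 250, i.e. a
#'   physiological ceiling of 240 bpm)
#' @param resample_kernel if `TRUE`, stretch the kernel so it always spans
#'   about 60 ms regardless of `fs` (off by default: 15 literal taps)
#' @return a `qrs_config` list
#' @export
qrs_config <- function(kernel_phase = c(1.5 * pi, 3.5 * pi), kernel_len = 15L,
                       sim_threshold = 0.3, refractory_ms = 250,
                       resample_kernel = FALSE) {
  if (kernel_len < 3L) stop("kernel_len must be >= 3", call. = FALSE)
  if (sim_threshold <= 0 || sim_threshold >= 1) {
    stop("sim_threshold must be in (0, 1)", call. = FALSE)
  }
  if (refractory_ms <= 0) stop("refractory_ms must be > 0", call. = FALSE)
  structure(list(kernel_phase = kernel_phase, kernel_len = as.integer(kernel_len),
                 sim_threshold = sim_threshold, refractory_ms = refractory_ms,
                 resample_kernel = resample_kernel),
            class = "qrs_config")
}

#' QRS matched-filter taps
#'
#' @param cfg a [qrs_config()]
#' @param fs sampling rate, only used when `resample_kernel` is set
#' @return numeric vector of taps; with defaults, tap 1 = sin(1.5 pi) = -1,
#'   the middle tap = sin(2.5 pi) = +1 and the last tap = sin(3.5 pi) = -1
#' @export
qrs_kernel <- function(cfg = qrs_config(), fs = NULL) {
  len <- cfg$kernel_len
  if (isTRUE(cfg$resample_kernel) && !is.null(fs)) {
    len <- max(3L, as.integer(round(0.060 * fs)))
  }
  sin(seq(cfg$kernel_phase[1], cfg$kernel_phase[2], length.out = len))
}

# sliding cosine similarity between the signal and the unit-norm kernel;
# exactly invariant to amplitude scaling and time shifts of the signal
sliding_similarity <- function(x, kernel) {
  k <- kernel / sqrt(sum(kernel^2))
  kl <- length(k)
  half <- (kl - 1L) %/% 2L
  num <- as.numeric(stats::filter(x, rev(k), method = "convolution", sides = 2L))
  den2 <- as.numeric(stats::filter(x^2, rep(1, kl), method = "convolution", sides = 2L))
  # floor the local norm relative to the global RMS so that near-silent
  # stretches cannot produce spurious high cosines
  floor_norm <- 0.5 * sqrt(kl) * sqrt(mean(x^2))
  den <- sqrt(pmax(den2, 0))
  den <- pmax(den, floor_norm)
  sim <- num / den
  sim[!is.finite(sim)] <- 0
  sim[is.na(sim)] <- 0
  sim
}

#' Detect R-peaks by matched filtering
#'
#' Computes the sliding normalised correlation (cosine similarity) between
#' the preprocessed ECG and the unit-norm QRS kernel, picks local maxima
#' exceeding the similarity threshold, enforces the refractory period
#' (keeping the strongest candidate), and snaps each peak to the nearest
#' signal maximum within +/- 50 ms.
#'
#' @param rec a single-channel, preprocessed ECG `signal_record` of at least
#'   2 s
#' @param cfg a [qrs_config()]
#' @return an `rpeak_series`: list with integer `indices` (ascending sample
#'   positions) and `fs`; empty with a warning when nothing crosses the
#'   threshold
#' @export
detect_r_peaks <- function(rec, cfg = qrs_config()) {
  stopifnot(inherits(rec, "signal_record"))
  if (n_samples(rec) < 2 * rec$fs) stop("need at least 2 s of ECG", call. = FALSE)
  x <- rec$samples[, 1L]
  if (all(x == 0)) {
    warning("no R-peaks found (flat signal)")
    return(structure(list(indices = integer(0), fs = rec$fs), class = "rpeak_series"))
  }
  sim <- sliding_similarity(x, qrs_kernel(cfg, rec$fs))
  n <- length(sim)
  cand <- which(sim > cfg$sim_threshold)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[sim[cand] >= sim[cand - 1L] & sim[cand] >= sim[cand + 1L]]
  if (length(cand) == 0L) {
    warning("no R-peaks found above the similarity threshold")
    return(structure(list(indices = integer(0), fs = rec$fs), class = "rpeak_series"))
  }
  refr <- as.integer(round(cfg$refractory_ms / 1000 * rec$fs))
  keep <- integer(0)
  for (i in cand[order(-sim[cand])]) {     # strongest first
    if (length(keep) == 0L || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  snap <- as.integer(round(0.050 * rec$fs))
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - snap); hi <- min(length(x), i + snap)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # snapping can only tighten positions; re-enforce the refractory gap
  if (length(peaks) > 1L) {
    out <- peaks[1L]
    for (p in peaks[-1L]) if (p - out[length(out)] >= refr) out <- c(out, p)
    peaks <- out
  }
  structure(list(indices = peaks, fs = rec$fs), class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peak(s) @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Successive RR intervals in milliseconds
#'
#' @param peaks an `rpeak_series` with at least 2 strictly increasing peaks
#' @return an `rr_series`: list with `intervals_ms` and `n` (interval count,
#'   i.e. one fewer than the peak count)
#' @export
rr_intervals <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$indices) < 2L) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(peaks$indices) <= 0)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  iv <- diff(peaks$indices) / peaks$fs * 1000
  structure(list(intervals_ms = iv, n = length(iv)), class = "rr_series")
}

#' Time-domain HRV statistics
#'
#' With `N` the number of RR intervals and `AVRR` their mean:
#' \deqn{RMSSD = \sqrt{\sum_i (RR_{i+1} - RR_i)^2 / (N - 1)}}
#' \deqn{SDRR = \sqrt{\sum_i (RR_i - AVRR)^2 / (N - 1)}}
#' \deqn{SKEW = \sum_i (RR_i - AVRR)^3 / (N \cdot SDRR^3)}
#' \deqn{KURT = \sum_i (RR_i - AVRR)^4 / (N \cdot SDRR^4) - 3}
#' The denominators are kept exactly as stated (note the mixed N-1 / N
#' convention); `textbook = TRUE` switches skew/kurt to the usual
#' sample-moment estimators.
#'
#' @param rr an `rr_series` (or numeric vector of intervals in ms) with
#'   `N >= 4`
#' @param textbook use conventional moment estimators for skew/kurt
#' @return list with `rmssd`, `avrr`, `sdrr` (ms), `skew`, `kurt` (excess);
#'   skew/kurt are `NA` with a warning when `sdrr` is zero
#' @export
hrv_features <- function(rr, textbook = FALSE) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals_ms else as.numeric(rr)
  n <- length(iv)
  if (n < 4L) stop("need at least 4 RR intervals", call. = FALSE)
  if (any(iv <= 0)) stop("RR intervals must be positive", call. = FALSE)
  avrr <- sum(iv) / n
  rmssd <- sqrt(sum(diff(iv)^2) / (n - 1))
  sdrr <- sqrt(sum((iv - avrr)^2) / (n - 1))
  if (sdrr == 0) {
    warning("skew/kurt undefined: zero RR variability")
    skew <- NA_real_; kurt <- NA_real_
  } else if (textbook) {
    skew <- sum((iv - avrr)^3) / n / (sqrt(sum((iv - avrr)^2) / n))^3
    kurt <- sum((iv - avrr)^4) / n / (sum((iv - avrr)^2) / n)^2 - 3
  } else {
    skew <- sum((iv - avrr)^3) / (n * sdrr^3)
    kurt <- sum((iv - avrr)^4) / (n * sdrr^4) - 3
  }
  list(rmssd = rmssd, avrr = avrr, sdrr = sdrr, skew = skew, kurt = kurt)
}

#' Extract per-epoch HRV features from an ECG epoch set
#'
#' Runs R-peak detection and [hrv_features()] on each epoch; epochs whose
#' detection yields fewer than 5 peaks (4 intervals) or an undefined
#' statistic are dropped with a message.
#'
#' @param epochs an `epoch_set` of ECG modality (already preprocessed)
#' @param cfg a [qrs_config()]
#' @return a `feature_table` with columns rmssd, avrr, sdrr, skew, kurt
#' @export
extract_ecg_features <- function(epochs, cfg = qrs_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$modality != "ECG") stop("expected ECG epochs", call. = FALSE)
  rows <- matrix(NA_real_, length(epochs$epochs), 5L)
  for (i in seq_along(epochs$epochs)) {
    x <- epochs$epochs[[i]][1L, ]
    rec <- signal_record(x, epochs$fs, channel_names = "ECG", modality = "ECG")
    pk <- suppressWarnings(detect_r_peaks(rec, cfg))
    if (length(pk$indices) >= 5L) {
      hf <- suppressWarnings(hrv_features(rr_intervals(pk)))
      rows[i, ] <- c(hf$rmssd, hf$avrr, hf$sdrr, hf$skew, hf$kurt)
    }
  }
  keep <- apply(rows, 1L, function(r) all(is.finite(r)))
  if (!all(keep)) {
    message(sum(!keep), " epoch(s) dropped: too few beats or undefined HRV")
  }
  feature_table(rows[keep, , drop = FALSE],
                feature_names = c("rmssd", "avrr", "sdrr", "skew", "kurt"),
                labels = if (!is.null(epochs$labels)) epochs$labels[keep])
}
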