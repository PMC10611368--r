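# Zero-phase IIR preprocessing.
#
# Butterworth low/high-pass sections are designed by bilinear transform and
# applied forward-backward (filtfilt) with steady-state initial conditions,
# so filters add no group delay. Band-pass is realised as a high-pass +
# low-pass cascade: behaviourally identical for the pass/stop-band contracts
# here, and numerically far better conditioned than a direct order-2N
# band-pass when the lower edge (0.1-0.15 Hz) sits close to DC.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

polyval <- function(p, x) {
  acc <- 0
  for (c in p) acc <- acc * x + c
  acc
}

#' Design a digital Butterworth filter as second-order sections
#'
#' Returned as cascaded biquads (conjugate pole pairs, each normalised at
#' the band reference) rather than a single transfer function: for cutoffs
#' very close to DC -- the 0.1-0.15 Hz high-pass edges used here -- the
#' expanded polynomial form is numerically unusable while the cascade is
#' well conditioned.
#'
#' @param order filter order (>= 1)
#' @param cutoff_hz cutoff frequency in Hz
#' @param fs sampling rate in Hz
#' @param type `"low"` or `"high"`
#' @return an `iir_sos`: list of sections, each with `b` and `a`
#'   (length-3 biquad coefficients)
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  wc <- cutoff_hz / (fs / 2)             # fraction of Nyquist
  warped <- tan(pi * wc / 2)             # prewarped analog cutoff
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  if (type == "low") {
    p_analog <- warped * proto
    zero_d <- -1
    ref <- 1 + 0i                        # unit gain at DC
  } else {
    p_analog <- warped / proto
    zero_d <- 1
    ref <- -1 + 0i                       # unit gain at Nyquist
  }
  p_digital <- (1 + p_analog) / (1 - p_analog)
  sections <- list()
  pos <- p_digital[Im(p_digital) > 1e-12]
  for (p in pos) {
    a <- Re(poly_from_roots(c(p, Conj(p))))
    b <- Re(poly_from_roots(c(zero_d, zero_d)))
    g <- Re(polyval(a + 0i, ref) / polyval(b + 0i, ref))
    sections[[length(sections) + 1L]] <- list(b = b * g, a = a)
  }
  real_p <- Re(p_digital[abs(Im(p_digital)) <= 1e-12])
  for (p in real_p) {
    a <- c(1, -p)
    b <- c(1, -zero_d)
    g <- Re(polyval(a + 0i, ref) / polyval(b + 0i, ref))
    sections[[length(sections) + 1L]] <- list(b = b * g, a = a)
  }
  structure(list(sections = sections), class = "iir_sos")
}

#' Apply an `iir_sos` cascade zero-phase
#'
#' @param sos an `iir_sos` from [butter_design()]
#' @param x numeric vector
#' @return filtered vector
#' @export
sos_filtfilt <- function(sos, x) {
  for (sec in sos$sections) x <- filtfilt(sec$b, sec$a, x)
  x
}

# steady-state DF2T state for a unit step (scipy lfilter_zi construction)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a))) / a[1]
  b <- c(b, rep(0, nf - length(b))) / 1
  if (nf == 1L) return(numeric(0))
  A <- matrix(0, nf - 1L, nf - 1L)
  A[1L, ] <- -a[-1L]
  if (nf > 2L) A[cbind(2:(nf - 1L), 1:(nf - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(nf - 1L) - t(A), B)
}

# zero-state linear filter via stats::filter (convolution + C recursion)
lfilter_zero_state <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[nb:(nb + length(x) - 1L)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L] / a[1L], method = "recursive")) / a[1L]
  }
  v
}

# response to an initial DF2T state with zero input (decays geometrically)
zi_response <- function(b, a, zi, n) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- zi
  out <- numeric(n)
  for (i in seq_len(n)) {
    y <- z[1L]
    out[i] <- y
    if (nf > 2L) {
      z[1:(nf - 2L)] <- z[2:(nf - 1L)] - a[2:(nf - 1L)] * y
    }
    z[nf - 1L] <- -a[nf] * y
    if (max(abs(z)) < 1e-300) break
  }
  out
}

lfilter <- function(b, a, x, zi = NULL) {
  y <- lfilter_zero_state(b, a, x)
  if (!is.null(zi) && length(zi) > 0L && any(zi != 0)) {
    y <- y + zi_response(b, a, zi, length(x))
  }
  y
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter forward then backward over an odd-padded extension of
#' the signal with steady-state initial conditions, as in the standard
#' filtfilt procedure; the result has zero group delay and the squared
#' magnitude response of the one-pass filter.
#'
#' @param b,a filter coefficients
#' @param x numeric vector
#' @return filtered vector, same length as `x`
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  # pad by ~6 time constants of the slowest pole so that edge transients of
  # near-DC high-pass sections decay inside the padding, not the signal
  r <- max(Mod(polyroot(rev(a / a[1]))), 0)
  tau <- if (r > 0 && r < 1) -1 / log(r) else 1
  pad <- min(n - 1L, max(3L * (nf - 1L), as.integer(ceiling(6 * tau))))
  # even (mirror) extension: unlike the odd extension, it introduces no DC
  # step at the pad/data junction, which matters for high-pass sections with
  # poles very close to z = 1
  if (pad > 0L) {
    ext <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  } else {
    ext <- x
  }
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1L])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

apply_per_channel <- function(rec, fun) {
  out <- rec$samples
  for (j in seq_len(ncol(out))) out[, j] <- fun(rec$samples[, j])
  signal_record(out, rec$fs, rec$channel_names, rec$modality)
}

#' Band-pass filter a signal record
#'
#' Zero-phase Butterworth high-pass at `low_hz` cascaded with a zero-phase
#' Butterworth low-pass at `high_hz`, per channel.
#'
#' @param rec a `signal_record`
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < fs/2`
#' @param order Butterworth order of each section (default 4)
#' @return filtered `signal_record`, same shape and fs
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 4) {
  stopifnot(inherits(rec, "signal_record"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  hp <- butter_design(order, low_hz, rec$fs, "high")
  lp <- butter_design(order, high_hz, rec$fs, "low")
  apply_per_channel(rec, function(x) sos_filtfilt(lp, sos_filtfilt(hp, x)))
}

#' Notch (band-stop) filter a signal record
#'
#' Second-order IIR notch (biquad) applied zero-phase, used to suppress
#' 50 Hz powerline interference.
#'
#' @param rec a `signal_record`
#' @param center_hz notch center frequency in Hz
#' @param q quality factor (center / -3 dB bandwidth); default 30
#' @return filtered `signal_record`
#' @export
notch <- function(rec, center_hz, q = 30) {
  stopifnot(inherits(rec, "signal_record"))
  if (center_hz <= 0 || center_hz >= rec$fs / 2) {
    stop("notch center must lie inside (0, fs/2)", call. = FALSE)
  }
  w0 <- 2 * pi * center_hz / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]
  apply_per_channel(rec, function(x) filtfilt(b, a, x))
}

#' Remove the best-fit linear trend from each channel
#'
#' @param rec a `signal_record` with at least 2 samples
#' @return detrended `signal_record` (per-channel mean approximately 0)
#' @export
detrend <- function(rec) {
  stopifnot(inherits(rec, "signal_record"))
  n <- n_samples(rec)
  if (n < 2L) stop("detrend needs at least 2 samples", call. = FALSE)
  t <- seq_len(n)
  t_c <- t - mean(t)
  ss <- sum(t_c^2)
  apply_per_channel(rec, function(x) {
    slope <- sum(t_c * x) / ss
    x - mean(x) - slope * t_c
  })
}

#' Standard EEG preprocessing chain
#'
#' Band-pass 0.15-40 Hz followed by a 50 Hz powerline notch (defaults
#' config-overridable).
#'
#' @param rec an EEG `signal_record`
#' @param low_hz,high_hz band edges (default 0.15 and 40 Hz)
#' @param notch_hz powerline frequency (default 50 Hz); `NA` disables
#' @param q notch quality factor
#' @param order Butterworth section order
#' @return preprocessed `signal_record`
#' @export
preprocess_eeg <- function(rec, low_hz = 0.15, high_hz = 40, notch_hz = 50,
                           q = 30, order = 4) {
  out <- bandpass(rec, low_hz, high_hz, order)
  if (!is.na(notch_hz)) out <- notch(out, notch_hz, q)
  out
}

#' Standard ECG preprocessing chain
#'
#' Band-pass 0.1-30 Hz followed by linear detrending to remove baseline
#' offset.
#'
#' @param rec an ECG `signal_record`
#' @param low_hz,high_hz band edges (default 0.1 and 30 Hz)
#' @param order Butterworth section order
#' @return preprocessed `signal_record`
#' @export
preprocess_ecg <- function(rec, low_hz = 0.1, high_hz = 30, order = 4) {
  detrend(bandpass(rec, low_hz, high_hz, order))
}
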