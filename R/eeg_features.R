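# EEG feature extraction: band powers over the canonical delta/theta/alpha/
# beta bands and four regularity measures (sample, approximate, fuzzy and
# spectral entropy). Entropies follow the standard literature definitions
# (Richman-Moorman, Pincus, Chen), with the tolerance r expressed as a
# fraction of the series SD so that features are amplitude-scale invariant.

#' Canonical EEG frequency bands (Hz)
#'
#' delta 0-4, theta 4-8, alpha 8-12, beta 12-30.
#' @return named list of `c(low, high)` pairs
#' @export
eeg_bands <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram: segments of `seg_len` samples with
#' fractional `overlap`, one-sided density normalised so that integrating
#' over frequency recovers signal power.
#'
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param seg_len segment length in samples (default 1 s of samples, capped
#'   at `length(x)`)
#' @param overlap fractional overlap between segments (default 0.5)
#' @return list with `freq` (Hz) and `psd` (units^2 / Hz)
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(fs))
  seg_len <- as.integer(seg_len)
  if (seg_len < 8L) stop("segment too short for a PSD estimate", call. = FALSE)
  step <- max(1L, as.integer(floor(seg_len * (1 - overlap))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1L)) / (seg_len - 1L))
  u <- sum(w^2)
  nhalf <- seg_len %/% 2L + 1L
  acc <- numeric(nhalf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    p <- p[1:nhalf]
    # one-sided: double the interior bins
    ip <- 2:(nhalf - 1L + seg_len %% 2L)
    p[ip] <- 2 * p[ip]
    acc <- acc + p
  }
  list(freq = (0:(nhalf - 1L)) * fs / seg_len, psd = acc / length(starts))
}

#' Band power: area under the PSD between band edges
#'
#' Trapezoidal integration of the Welch PSD over `[band[1], band[2]]`.
#'
#' @param x numeric vector (one epoch, one channel)
#' @param fs sampling rate in Hz
#' @param band `c(low, high)` in Hz, inside the Nyquist range
#' @return nonnegative power (signal-units^2)
#' @export
band_power <- function(x, fs, band) {
  if (band[1] < 0 || band[2] <= band[1] || band[2] > fs / 2) {
    stop("band must satisfy 0 <= low < high <= fs/2", call. = FALSE)
  }
  if (length(x) < fs) stop("epoch must be at least 1 s long", call. = FALSE)
  sp <- welch_psd(x, fs)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  f <- sp$freq[sel]; p <- sp$psd[sel]
  if (length(f) < 2L) return(0)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Entropy configuration
#'
#' @param m template (embedding) length, integer >= 1; default 2
#' @param r matching tolerance as a fraction of the series SD; default 0.2
#' @param n_fuzzy fuzzy membership exponent (default 2)
#' @return an `entropy_config` list
#' @export
entropy_config <- function(m = 2L, r = 0.2, n_fuzzy = 2L) {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  if (n_fuzzy < 1L) stop("n_fuzzy must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), r = r, n_fuzzy = as.integer(n_fuzzy)),
            class = "entropy_config")
}

# Chebyshev distance matrix between all length-m templates starting at
# 1..n_templates (vectorised over template pairs).
template_chebyshev <- function(x, m, n_templates) {
  d <- matrix(0, n_templates, n_templates)
  for (k in 0:(m - 1L)) {
    xk <- x[(1L + k):(n_templates + k)]
    d <- pmax(d, abs(outer(xk, xk, "-")))
  }
  d
}

#' Sample entropy (Richman-Moorman)
#'
#' `-ln(A/B)` where `B` counts template pairs of length `m` and `A` pairs of
#' length `m + 1` within Chebyshev distance `r * SD(x)`; self-matches are
#' excluded and both template sets run over the same `n - m` start points.
#' Returns `NA` with a warning if either count is zero (undefined).
#'
#' @param x numeric vector, length >= m + 2, not constant
#' @param cfg an [entropy_config()]
#' @return nonnegative entropy value, or `NA` when undefined
#' @export
sample_entropy <- function(x, cfg = entropy_config()) {
  m <- cfg$m
  n <- length(x)
  if (n < m + 2L) stop("series too short for sample entropy", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    warning("sample entropy undefined for a constant series")
    return(NA_real_)
  }
  tol <- cfg$r * s
  nt <- n - m            # start points shared by the m and m+1 template sets
  dm <- template_chebyshev(x, m, nt)
  dm1 <- template_chebyshev(x, m + 1L, nt)
  b <- sum(dm[upper.tri(dm)] <= tol)
  a <- sum(dm1[upper.tri(dm1)] <= tol)
  if (a == 0L || b == 0L) {
    warning("sample entropy undefined: no template matches at tolerance r")
    return(NA_real_)
  }
  -log(a / b)
}

#' Approximate entropy (Pincus)
#'
#' `Phi^m(r) - Phi^(m+1)(r)` with `Phi` the mean log relative frequency of
#' template matches, self-matches included (so counts never vanish).
#'
#' @inheritParams sample_entropy
#' @return entropy value
#' @export
approximate_entropy <- function(x, cfg = entropy_config()) {
  m <- cfg$m
  n <- length(x)
  if (n < m + 2L) stop("series too short for approximate entropy", call. = FALSE)
  s <- stats::sd(x)
  tol <- cfg$r * if (s > 0) s else 1
  phi <- function(mm) {
    nt <- n - mm + 1L
    d <- template_chebyshev(x, mm, nt)
    ci <- rowSums(d <= tol) / nt       # includes the self-match
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

#' Fuzzy entropy (Chen)
#'
#' Like sample entropy but with a smooth exponential membership
#' `mu(d) = exp(-(d / (r * SD))^n_fuzzy)` on mean-subtracted templates in
#' place of the hard threshold: `-ln(phi^(m+1) / phi^m)` with `phi` the mean
#' pairwise membership (self-pairs excluded).
#'
#' @inheritParams sample_entropy
#' @return nonnegative entropy value, or `NA` for a degenerate input
#' @export
fuzzy_entropy <- function(x, cfg = entropy_config()) {
  m <- cfg$m
  n <- length(x)
  if (n < m + 2L) stop("series too short for fuzzy entropy", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    warning("fuzzy entropy undefined for a constant series")
    return(NA_real_)
  }
  tol <- cfg$r * s
  phi <- function(mm) {
    nt <- n - m                        # common start points, as in SampEn
    # mean-subtract each template before measuring distance
    tmpl <- matrix(0, nt, mm)
    for (k in 0:(mm - 1L)) tmpl[, k + 1L] <- x[(1L + k):(nt + k)]
    tmpl <- tmpl - rowMeans(tmpl)
    d <- matrix(0, nt, nt)
    for (k in seq_len(mm)) d <- pmax(d, abs(outer(tmpl[, k], tmpl[, k], "-")))
    mu <- exp(-(d / tol)^cfg$n_fuzzy)
    (sum(mu) - nt) / (nt * (nt - 1L))  # exclude self-pairs
  }
  -log(phi(m + 1L) / phi(m))
}

#' Normalised spectral entropy
#'
#' Shannon entropy (natural log) of the Welch PSD restricted to `band` and
#' normalised to a probability distribution, divided by `log(#bins)` so the
#' result lies in `[0, 1]`: near 0 for a narrowband signal, near 1 for
#' broadband noise.
#'
#' @param x numeric vector, at least 1 s of samples
#' @param fs sampling rate in Hz
#' @param band `c(low, high)` Hz; default the EEG passband 0.15-40 Hz
#'   (clipped to Nyquist)
#' @return value in `[0, 1]`, or `NA` for a zero signal
#' @details Unlike [band_power()], the PSD here is a single full-epoch Hann
#'   periodogram rather than a segment-averaged Welch estimate: spectral
#'   entropy needs frequency resolution (so a pure tone concentrates into a
#'   few bins), not variance reduction.
#' @export
spectral_entropy <- function(x, fs, band = c(0.15, 40)) {
  if (length(x) < fs) stop("epoch must be at least 1 s long", call. = FALSE)
  band[2] <- min(band[2], fs / 2)
  sp <- welch_psd(x, fs, seg_len = length(x))
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  p <- sp$psd[sel]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) {
    warning("spectral entropy undefined for a zero signal")
    return(NA_real_)
  }
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(sum(sel))
}

#' Extract the 8-per-channel EEG feature table from an epoch set
#'
#' Per channel: delta/theta/alpha/beta band powers plus fuzzy, sample,
#' spectral and approximate entropy, named `"<channel>_<feature>"`
#' (e.g. `"P3_delta"`, `"P4_approx_en"`). Rows containing an undefined
#' entropy are dropped with a message.
#'
#' @param epochs an `epoch_set` of EEG modality (already preprocessed)
#' @param cfg an [entropy_config()]
#' @return a `feature_table` with `8 * n_channels` columns (plus `label`
#'   when the epoch set is labelled)
#' @export
extract_eeg_features <- function(epochs, cfg = entropy_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$modality != "EEG") stop("expected EEG epochs", call. = FALSE)
  feats <- c("delta", "theta", "alpha", "beta",
             "fuzzy_en", "sample_en", "spectral_en", "approx_en")
  bands <- eeg_bands()
  cols <- as.vector(t(outer(epochs$channel_names, feats, paste, sep = "_")))
  rows <- matrix(NA_real_, length(epochs$epochs), length(cols))
  fs <- epochs$fs
  for (i in seq_along(epochs$epochs)) {
    ep <- epochs$epochs[[i]]
    v <- numeric(0)
    for (ch in seq_len(nrow(ep))) {
      x <- ep[ch, ]
      bp <- vapply(bands, function(b) band_power(x, fs, c(b[1], min(b[2], fs / 2 - 1e-9))),
                   numeric(1))
      ent <- suppressWarnings(c(fuzzy_entropy(x, cfg), sample_entropy(x, cfg),
                                spectral_entropy(x, fs), approximate_entropy(x, cfg)))
      v <- c(v, bp, ent)
    }
    rows[i, ] <- v
  }
  keep <- apply(rows, 1L, function(r) all(is.finite(r)))
  if (!all(keep)) {
    message(sum(!keep), " epoch(s) dropped: undefined entropy feature")
  }
  feature_table(rows[keep, , drop = FALSE], feature_names = cols,
                labels = if (!is.null(epochs$labels)) epochs$labels[keep])
}
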