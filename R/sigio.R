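#' Uniformly sampled multichannel physiological signal
#'
#' A `signal_record` holds one or more equal-length channels sampled at a
#' common rate, together with the modality tag used by downstream stages to
#' select the right preprocessing chain.
#'
#' @param samples numeric matrix (one column per channel) or a numeric vector
#'   for a single channel.
#' @param fs sampling rate in Hz, > 0.
#' @param channel_names character vector of unique channel names; defaults to
#'   `"ch1"`, `"ch2"`, ... For two-channel EEG the conventional names are
#'   `"P3"` and `"P4"` (parietal electrodes of the 10-20 system).
#' @param modality `"EEG"` or `"ECG"`.
#' @return An object of class `signal_record` with elements `samples`
#'   (matrix, samples x channels), `fs`, `channel_names`, `modality`.
#' @export
signal_record <- function(samples, fs, channel_names = NULL,
                          modality = c("EEG", "ECG")) {
  modality <- match.arg(modality)
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, ncol = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix or vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(colnames(samples))) colnames(samples)
                     else paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_names) != ncol(samples)) {
    stop("`channel_names` length must match channel count", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs,
         channel_names = as.character(channel_names), modality = modality),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s, %d channel(s) [%s], %d samples @ %g Hz (%.2f s)\n",
              x$modality, ncol(x$samples),
              paste(x$channel_names, collapse = ", "),
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `signal_record`
#' @return integer sample count
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Select a subset of channels by name
#'
#' @param rec a `signal_record`
#' @param channels character vector of channel names, returned in the
#'   requested order.
#' @return a `signal_record` with only the requested channels
#' @export
select_channels <- function(rec, channels) {
  missing <- setdiff(channels, rec$channel_names)
  if (length(missing) > 0) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  signal_record(rec$samples[, channels, drop = FALSE], rec$fs,
                channel_names = channels, modality = rec$modality)
}

#' Read a multichannel signal from CSV
#'
#' The CSV dialect is: comma separator, mandatory header row with channel
#' names, one row per sample, decimal floats. Time is implicit
#' (row index / `fs`).
#'
#' @param path path to a CSV file.
#' @param fs sampling rate in Hz (not stored in the file).
#' @param modality `"EEG"` or `"ECG"`.
#' @param channels optional character vector: read only these channels, in
#'   this order (e.g. `c("P3", "P4")` from a 32-channel recording).
#' @return a `signal_record`
#' @export
read_signal <- function(path, fs, modality = c("EEG", "ECG"), channels = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty signal file: ", path, call. = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric or ragged columns in ", path, call. = FALSE)
  rec <- signal_record(m, fs, channel_names = colnames(df), modality = modality)
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec
}

#' Write a signal to CSV at full double precision
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces the samples exactly.
#'
#' @param rec a `signal_record`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_signal <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_names, collapse = ","), con)
  rows <- apply(rec$samples, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Cut a signal into fixed-length epochs
#'
#' Epochs tile the record from t = 0 with the stated fractional overlap; a
#' trailing partial epoch is dropped. The default epoch length of 5 s matches
#' the cadence of the 5 s fusion window.
#'
#' @param rec a `signal_record`
#' @param epoch_len_s epoch length in seconds; `epoch_len_s * fs` must be a
#'   whole number of samples.
#' @param overlap_frac fractional overlap between consecutive epochs, in
#'   `[0, 1)`.
#' @param labels optional: either a single state label recycled to all epochs
#'   or one label per epoch, each `"alert"` or `"fatigued"`.
#' @return an `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `epoch_len_s`, `fs`, `channel_names`, `modality`, `labels`.
#' @export
epoch_signal <- function(rec, epoch_len_s = 5, overlap_frac = 0, labels = NULL) {
  stopifnot(inherits(rec, "signal_record"))
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  }
  len <- epoch_len_s * rec$fs
  if (abs(len - round(len)) > 1e-9) {
    stop("epoch_len_s * fs must be an integer sample count", call. = FALSE)
  }
  len <- as.integer(round(len))
  n <- n_samples(rec)
  if (n < len) stop("record shorter than one epoch", call. = FALSE)
  step <- max(1L, as.integer(round(len * (1 - overlap_frac))))
  starts <- seq.int(1L, n - len + 1L, by = step)
  epochs <- lapply(starts, function(s) t(rec$samples[s:(s + len - 1L), , drop = FALSE]))
  if (!is.null(labels)) {
    if (length(labels) == 1L) labels <- rep(labels, length(epochs))
    if (length(labels) != length(epochs)) {
      stop("`labels` must have length 1 or one per epoch", call. = FALSE)
    }
    if (!all(labels %in% c("alert", "fatigued"))) {
      stop("labels must be 'alert' or 'fatigued'", call. = FALSE)
    }
  }
  structure(
    list(epochs = epochs, epoch_len_s = epoch_len_s, fs = rec$fs,
         channel_names = rec$channel_names, modality = rec$modality,
         labels = labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s, %d epoch(s) of %g s @ %g Hz, %d channel(s)%s\n",
              x$modality, length(x$epochs), x$epoch_len_s, x$fs,
              length(x$channel_names),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Per-epoch feature table
#'
#' @param features numeric matrix or data.frame, one row per epoch.
#' @param feature_names column names; taken from `features` if absent.
#' @param labels optional per-row state labels (`"alert"`/`"fatigued"` or
#'   integer codes).
#' @return a `feature_table`: data.frame of features with an attribute-free
#'   `label` column appended when labels are present, classed for dispatch.
#' @export
feature_table <- function(features, feature_names = NULL, labels = NULL) {
  df <- as.data.frame(features)
  if (!is.null(feature_names)) {
    if (length(feature_names) != ncol(df)) {
      stop("feature_names length mismatch", call. = FALSE)
    }
    names(df) <- feature_names
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("all features must be numeric", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(df)) stop("one label per row required", call. = FALSE)
    df$label <- labels
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Feature names of a feature table (excluding the label column)
#' @param ft a `feature_table`
#' @return character vector
#' @export
feature_names <- function(ft) setdiff(names(ft), "label")

#' Write / read a feature table as CSV
#'
#' The label column, when present, is written last under the header `label`.
#' Values round-trip with at least 12 significant digits.
#'
#' @param ft a `feature_table`
#' @param path CSV path
#' @return `path` invisibly (`write`), or a `feature_table` (`read`)
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  feature_table(df, labels = labels)
}

#' Read a run configuration file (JSON)
#'
#' Holds sampling rates, channel selections, epoching, filter settings and
#' seeds under the keys used by the command-line interface, e.g.
#' `preprocess.eeg`, `preprocess.ecg`, `epoch_len_s`, `channels`.
#'
#' @param path path to a JSON file
#' @return nested named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
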