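# Real-time feedback engine: a 4-row label matrix grows one column per
# second; a 5 s window slides over it (stride 1 s); per-row modes form a
# 4-tuple pattern; a pattern dictionary maps the tuple to a severity key;
# and the key must persist longer than a threshold before a non-normal
# level is emitted.
#
# Row semantics: row 1 EEG (0 alert / 1 fatigued), row 2 ECG (2 alert /
# 3 fatigued), row 3 phone (4 no-phone / 5 phone in use), row 4 lane
# (6 in lane / 7 lane departure).

#' Construct / validate a 4-row label matrix
#'
#' @param m a 4 x n integer matrix (or anything coercible), entries drawn
#'   from the per-row alphabets 0/1, 2/3, 4/5, 6/7
#' @return a `label_matrix`
#' @export
label_matrix <- function(m = matrix(integer(0), nrow = 4L)) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (nrow(m) != 4L) stop("a label matrix has exactly 4 rows", call. = FALSE)
  if (ncol(m) > 0L) apply(m, 2L, validate_fusion_labels)
  rownames(m) <- names(fusion_row_alphabets())
  class(m) <- c("label_matrix", class(m))
  m
}

#' Append one second (one column) of labels
#'
#' @param matrix a `label_matrix`
#' @param labels length-4 integer vector, one per row, in the row alphabets
#' @return the grown `label_matrix`
#' @export
append_second <- function(matrix, labels) {
  validate_fusion_labels(as.integer(labels))
  label_matrix(cbind(unclass(matrix), as.integer(labels)))
}

# mode of a small integer vector; ties broken toward `prefer`
mode_label <- function(v, prefer) {
  tab <- table(v)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1L && prefer %in% top) prefer else top[1L]
}

#' Per-row modes over the trailing window
#'
#' For each of the 4 rows, the most frequent label over the last `window`
#' columns ending at `end_col`. Ties (impossible at window 5 with binary
#' alphabets, possible for custom windows) break toward the row's abnormal
#' label (1, 3, 5, 7), favouring sensitivity. Returns `NULL` while fewer
#' than `window` columns are available ("warming up").
#'
#' @param matrix a `label_matrix`
#' @param end_col index of the window's last column (default: last column)
#' @param window window length in columns/seconds (default 5)
#' @return integer 4-tuple pattern, or `NULL` when warming up
#' @export
window_modes <- function(matrix, end_col = ncol(matrix), window = 5L) {
  if (end_col < window) return(NULL)
  abnormal <- c(1L, 3L, 5L, 7L)
  w <- matrix[, (end_col - window + 1L):end_col, drop = FALSE]
  vapply(1:4, function(r) mode_label(w[r, ], abnormal[r]), integer(1))
}

#' The default pattern dictionary
#'
#' Maps the 4-tuple `(1, 3, 4, 7)` to `"severe"`, the tuples `(1, 3, 5, 7)`,
#' `(1, 3, 5, 6)` and `(1, 3, 4, 6)` to `"mild"`, and every other tuple to
#' `"normal"` -- 1 severe and 3 mild patterns out of the 16 possible.
#'
#' @return a `pattern_dictionary`: named list keyed `"a,b,c,d"` plus a
#'   `default` entry
#' @export
default_pattern_dictionary <- function() {
  structure(list("1,3,4,7" = "severe",
                 "1,3,5,7" = "mild",
                 "1,3,5,6" = "mild",
                 "1,3,4,6" = "mild",
                 default = "normal"),
            class = "pattern_dictionary")
}

#' Alternative dictionary built from the prose decision rules
#'
#' An alternative reading of the feedback rules: phone use together with a
#' lane departure excuses the departure (driver distracted, not fatigued);
#' a lane departure without phone use plus at least one abnormal biosignal
#' is severe; otherwise any abnormal biosignal alone is mild. Selected via
#' config where the listed-tuple dictionary is not wanted.
#'
#' @return a `pattern_dictionary` covering all 16 tuples explicitly
#' @export
prose_rule_dictionary <- function() {
  d <- list()
  for (eeg in 0:1) for (ecg in 2:3) for (phone in 4:5) for (lane in 6:7) {
    bio <- (eeg == 1L) || (ecg == 3L)
    lvl <- if (lane == 7L && phone == 4L && bio) "severe"
           else if (lane == 7L && phone == 5L) "normal"
           else if (bio) "mild"
           else "normal"
    d[[paste(c(eeg, ecg, phone, lane), collapse = ",")]] <- lvl
  }
  d$default <- "normal"
  structure(d, class = "pattern_dictionary")
}

#' Map a 4-tuple pattern to its severity key
#'
#' @param pattern integer 4-tuple
#' @param dict a `pattern_dictionary`
#' @return `"severe"`, `"mild"` or `"normal"`
#' @export
map_pattern <- function(pattern, dict = default_pattern_dictionary()) {
  validate_fusion_labels(as.integer(pattern))
  key <- paste(as.integer(pattern), collapse = ",")
  lvl <- dict[[key]]
  if (is.null(lvl)) lvl <- dict$default
  if (is.null(lvl)) lvl <- "normal"
  lvl
}

#' Run the sliding-window feedback model over a label stream
#'
#' Emits one result per window position (stride 1 column). For each window
#' the per-row mode pattern is looked up in the dictionary; `delta_t` is the
#' number of seconds since the current non-normal key first appeared in an
#' unbroken run of windows (0 at first appearance, reset whenever the key
#' changes). The emitted level is `"severe_fatigue"` / `"mild_fatigue"` only
#' while the corresponding key persists with `delta_t > t_persist`;
#' otherwise `"normal"`.
#'
#' @param matrix a `label_matrix` with at least `window` columns
#' @param dict a `pattern_dictionary`
#' @param t_persist persistence threshold T in seconds (default 3); `Inf`
#'   suppresses non-normal output entirely
#' @param window window size in seconds (default 5)
#' @return data.frame with one row per window: `window_end_time` (s),
#'   `pattern` ("a,b,c,d"), `key` (dictionary key), `delta_t` (s), `level`
#' @export
feedback_stream <- function(matrix, dict = default_pattern_dictionary(),
                            t_persist = 3, window = 5L) {
  n <- ncol(matrix)
  if (n < window) stop("need at least ", window, " columns", call. = FALSE)
  ends <- window:n
  res <- data.frame(window_end_time = ends,
                    pattern = character(length(ends)),
                    key = character(length(ends)),
                    delta_t = numeric(length(ends)),
                    level = character(length(ends)))
  run_key <- "normal"; run_start <- NA_real_
  for (i in seq_along(ends)) {
    pat <- window_modes(matrix, ends[i], window)
    key <- map_pattern(pat, dict)
    if (key != run_key) {
      run_key <- key
      run_start <- ends[i]
    }
    dt <- if (run_key == "normal") 0 else ends[i] - run_start
    lvl <- if (key == "severe" && dt > t_persist) "severe_fatigue"
           else if (key == "mild" && dt > t_persist) "mild_fatigue"
           else "normal"
    res$pattern[i] <- paste(pat, collapse = ",")
    res$key[i] <- key
    res$delta_t[i] <- dt
    res$level[i] <- lvl
  }
  res
}

#' Read / write a label stream as 4-row CSV
#'
#' @param path CSV path (4 rows, no header, one column per second)
#' @param matrix a `label_matrix`
#' @return a `label_matrix` (`read`); `path` invisibly (`write`)
#' @export
read_label_stream <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  label_matrix(m)
}

#' @rdname read_label_stream
#' @export
write_label_stream <- function(matrix, path) {
  utils::write.table(unclass(matrix), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a pattern dictionary as JSON
#' @param dict a `pattern_dictionary`
#' @param path JSON path
#' @return `path` invisibly
#' @export
write_pattern_dictionary <- function(dict, path) {
  jsonlite::write_json(unclass(dict), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a pattern dictionary from JSON
#' @param path JSON path
#' @return a `pattern_dictionary`
#' @export
read_pattern_dictionary <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "pattern_dictionary")
}
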