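# Trial containers, delimited-text I/O, artifact exclusion and epoching.

#' Labelled single-channel EEG trials
#'
#' Bundles a trials-by-samples numeric matrix with its class labels and
#' acquisition metadata.  This is the raw input of the whole pipeline: one
#' electrode, many cue-aligned trials of identical length.
#'
#' @param data Numeric matrix, one trial per row, values in microvolts.
#' @param labels Integer vector, one per trial, each in `1:4`
#'   (1 = left hand, 2 = right hand, 3 = foot, 4 = tongue).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel Electrode name, e.g. `"C4"` or `"Fp2"`.
#' @param artifact Logical vector, one per trial; `TRUE` marks trials with
#'   visually identified artifacts.  Defaults to all `FALSE`.
#' @param trial_t0 Time in seconds of sample 0 relative to trial start
#'   (0 for a full trial, non-zero after windowing if not re-referenced).
#'
#' @return An object of class `trial_set` with fields `data`, `labels`,
#'   `fs`, `channel`, `artifact`, `trial_t0`.
#' @export
trial_set <- function(data, labels, fs, channel = "C3",
                      artifact = NULL, trial_t0 = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  if (is.null(artifact)) artifact <- rep(FALSE, nrow(data))
  ts <- structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel = as.character(channel), artifact = as.logical(artifact),
         trial_t0 = as.numeric(trial_t0)),
    class = "trial_set")
  validate_trial_set(ts)
  ts
}

validate_trial_set <- function(ts) {
  if (!is.matrix(ts$data) || !is.numeric(ts$data))
    stop("trial data must be a numeric matrix", call. = FALSE)
  if (anyNA(ts$data))
    stop("trial data contains missing values", call. = FALSE)
  n <- nrow(ts$data)
  if (length(ts$labels) != n)
    stop("need one label per trial (", n, " trials, ",
         length(ts$labels), " labels)", call. = FALSE)
  if (anyNA(ts$labels) || !all(ts$labels %in% 1:4))
    stop("labels must all lie in 1..4 (left hand, right hand, foot, tongue)",
         call. = FALSE)
  if (length(ts$fs) != 1L || is.na(ts$fs) || ts$fs <= 0)
    stop("fs must be a single positive sampling rate in Hz", call. = FALSE)
  if (length(ts$artifact) != n || anyNA(ts$artifact))
    stop("artifact flags must be one non-missing logical per trial",
         call. = FALSE)
  invisible(ts)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials x %d samples @ %g Hz, channel %s (%.3g s each)\n",
    nrow(x$data), ncol(x$data), x$fs, x$channel, ncol(x$data) / x$fs))
  cat("  labels:", paste(sprintf("%d:%d", 1:4, tabulate(x$labels, 4)),
                         collapse = " "),
      "| artifact-flagged:", sum(x$artifact), "\n")
  invisible(x)
}

#' Number of trials / samples per trial
#' @param ts A [trial_set()].
#' @return Integer count.
#' @export
n_trials <- function(ts) nrow(ts$data)

#' @rdname n_trials
#' @export
n_samples <- function(ts) ncol(ts$data)

#' Trial duration in seconds
#' @param ts A [trial_set()].
#' @return Duration of one trial, `n_samples / fs`.
#' @export
trial_duration <- function(ts) ncol(ts$data) / ts$fs

# Guess the field separator of a delimited text file from its first line.
sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Load labelled trials from a delimited matrix plus JSON sidecar
#'
#' The matrix file holds one trial per row (CSV, TSV or whitespace
#' delimited, no header).  The sidecar is a JSON document with keys
#' `labels` (array of int, 1-4), `fs` (Hz), `channel` (string) and
#' optionally `artifact` (array of bool, default all false) and
#' `trial_t0` (seconds, default 0).
#'
#' @param matrix_path Path to the delimited numeric matrix.
#' @param meta_path Path to the JSON sidecar.
#' @return A validated [trial_set()]; row order is preserved.
#' @export
load_trials <- function(matrix_path, meta_path) {
  sep <- sniff_sep(matrix_path)
  widths <- utils::count.fields(matrix_path, sep = sep)
  if (length(unique(widths)) != 1L)
    stop("malformed trial matrix: ragged rows (widths ",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  mat <- as.matrix(utils::read.table(matrix_path, sep = sep, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop("sidecar is missing the sampling rate 'fs'", call. = FALSE)
  if (is.null(meta$labels))
    stop("sidecar is missing 'labels'", call. = FALSE)
  trial_set(mat, meta$labels, meta$fs,
            channel  = if (is.null(meta$channel)) "unknown" else meta$channel,
            artifact = meta$artifact,
            trial_t0 = if (is.null(meta$trial_t0)) 0 else meta$trial_t0)
}

#' Write a trial set as a delimited matrix plus JSON sidecar
#'
#' Inverse of [load_trials()]; round-trips all fields.
#'
#' @param ts A [trial_set()].
#' @param matrix_path,meta_path Output paths.
#' @param sep Field separator for the matrix file.
#' @return Invisibly, `ts`.
#' @export
save_trials <- function(ts, matrix_path, meta_path, sep = ",") {
  utils::write.table(ts$data, matrix_path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(labels = ts$labels, fs = ts$fs, channel = ts$channel,
         artifact = ts$artifact, trial_t0 = ts$trial_t0),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(ts)
}

#' Exclude artifact-flagged trials
#'
#' Trials whose artifact flag is set (visually identified EOG/EMG
#' contamination in the source recordings) are removed before analysis;
#' retained trials keep their data, labels and relative order.
#'
#' @param ts A [trial_set()].
#' @return A [trial_set()] with only the unflagged trials.
#' @export
drop_artifacts <- function(ts) {
  keep <- !ts$artifact
  if (!any(keep))
    stop("every trial is artifact-flagged; nothing left to analyse",
         call. = FALSE)
  trial_set(ts$data[keep, , drop = FALSE], ts$labels[keep], ts$fs,
            channel = ts$channel, trial_t0 = ts$trial_t0)
}

#' Analysis window within a trial
#'
#' A half-open interval `[t_start, t_end)` in seconds relative to trial
#' start.  The standard windows follow the cue at 3 s: `[3,4)`, `[4,5)`,
#' `[5,6)`, `[6,7)`.
#'
#' @param t_start,t_end Window bounds in seconds, `0 <= t_start < t_end`.
#' @return An object of class `epoch_window`.
#' @export
epoch_window <- function(t_start, t_end) {
  t_start <- as.numeric(t_start); t_end <- as.numeric(t_end)
  if (length(t_start) != 1L || length(t_end) != 1L ||
      is.na(t_start) || is.na(t_end) || t_start < 0 || t_start >= t_end)
    stop("need 0 <= t_start < t_end", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end), class = "epoch_window")
}

#' @export
print.epoch_window <- function(x, ...) {
  cat(sprintf("<epoch_window> [%g, %g) s\n", x$t_start, x$t_end))
  invisible(x)
}

as_epoch_window <- function(w) {
  if (inherits(w, "epoch_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(epoch_window(w[1], w[2]))
  stop("window must be an epoch_window or a numeric length-2 vector",
       call. = FALSE)
}

#' Cut an analysis window out of every trial
#'
#' Keeps the samples whose time lies in `[t_start, t_end)`.  The mapping
#' is 0-based and half-open — sample index `floor(t * fs)` — so adjacent
#' windows such as `[3,4)` and `[4,5)` share no sample.  The returned
#' trials are re-referenced to the window start (`trial_t0 = 0`).
#'
#' @param ts A [trial_set()].
#' @param w An [epoch_window()] (or numeric `c(t_start, t_end)`); must lie
#'   within the trial duration.
#' @return A [trial_set()] of the same trials truncated to the window.
#' @export
extract_window <- function(ts, w) {
  w <- as_epoch_window(w)
  ns <- ncol(ts$data)
  i0 <- floor((w$t_start - ts$trial_t0) * ts$fs)   # 0-based, inclusive
  i1 <- floor((w$t_end   - ts$trial_t0) * ts$fs)   # 0-based, exclusive
  if (i0 < 0 || i1 > ns)
    stop(sprintf("window [%g, %g) s exceeds trial bounds [%g, %g) s",
                 w$t_start, w$t_end, ts$trial_t0, ts$trial_t0 + ns / ts$fs),
         call. = FALSE)
  trial_set(ts$data[, (i0 + 1L):i1, drop = FALSE], ts$labels, ts$fs,
            channel = ts$channel, artifact = ts$artifact, trial_t0 = 0)
}
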