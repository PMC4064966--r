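# Short-time Fourier transform: one channel -> frequency x time matrix.
#
# The spectrogram's frequency bins play the role of virtual channels for
# the CSP stage, which is what makes single-channel CSP possible at all.

#' STFT analysis parameters
#'
#' Defaults follow the single-channel motor-imagery setup: 100-sample
#' segments (0.4 s at 250 Hz) tapered with a Hamming window, zero-padded
#' to a 128-point FFT, advancing 50 samples per frame (50% overlap).
#'
#' @param segment_len Samples per analysis segment.
#' @param hop Samples between consecutive segment starts.
#' @param nfft FFT length; segments are zero-padded from `segment_len` to
#'   `nfft`.  Must satisfy `0 < hop <= segment_len <= nfft`.
#' @param window Taper name; only `"hamming"` and `"rectangular"` are
#'   recognised.  The taper has length `segment_len`.
#' @return An object of class `stft_params`.
#' @export
stft_params <- function(segment_len = 100L, hop = 50L, nfft = 128L,
                        window = "hamming") {
  segment_len <- as.integer(segment_len)
  hop <- as.integer(hop); nfft <- as.integer(nfft)
  if (!(hop > 0L && hop <= segment_len && segment_len <= nfft))
    stop("need 0 < hop <= segment_len <= nfft", call. = FALSE)
  window <- match.arg(window, c("hamming", "rectangular"))
  structure(list(segment_len = segment_len, hop = hop, nfft = nfft,
                 window = window),
            class = "stft_params")
}

stft_taper <- function(p) {
  switch(p$window,
         hamming     = as.numeric(signal::hamming(p$segment_len)),
         rectangular = rep(1, p$segment_len))
}

#' Frequency band of interest
#'
#' @param fmin,fmax Band edges in Hz, inclusive.  The default 8-30 Hz
#'   covers the mu (8-13 Hz) and beta (16-25 Hz) sensorimotor rhythms
#'   whose event-related power changes carry the motor-imagery signal.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(fmin = 8, fmax = 30) {
  fmin <- as.numeric(fmin); fmax <- as.numeric(fmax)
  if (is.na(fmin) || is.na(fmax) || fmin < 0 || fmin >= fmax)
    stop("need 0 <= fmin < fmax", call. = FALSE)
  structure(list(fmin = fmin, fmax = fmax), class = "band_spec")
}

#' Magnitude spectrogram container
#'
#' @param E Nonnegative real matrix, frequency bins (rows) by time frames
#'   (columns).
#' @param freqs Bin-centre frequencies in Hz, strictly increasing,
#'   `length(freqs) == nrow(E)`.
#' @param times Frame-centre times in seconds, strictly increasing,
#'   `length(times) == ncol(E)`.
#' @return An object of class `spectrogram`.
#' @export
spectrogram <- function(E, freqs, times) {
  E <- as.matrix(E)
  if (any(E < 0)) stop("spectrogram entries must be nonnegative", call. = FALSE)
  if (length(freqs) != nrow(E) || length(times) != ncol(E))
    stop("freqs/times lengths must match spectrogram dimensions",
         call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE) || is.unsorted(times, strictly = TRUE))
    stop("freqs and times must be strictly increasing", call. = FALSE)
  structure(list(E = E, freqs = as.numeric(freqs), times = as.numeric(times)),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d freq bins (%.3g-%.3g Hz) x %d frames (%.3g-%.3g s)\n",
    nrow(x$E), min(x$freqs), max(x$freqs), ncol(x$E),
    min(x$times), max(x$times)))
  invisible(x)
}

#' One-sided magnitude STFT of a single-channel signal
#'
#' Slides a tapered segment along the signal, zero-pads each segment to
#' `nfft` points and takes the magnitude of its DFT.  Only the one-sided
#' spectrum (bins `0..nfft/2`) is kept, as the input is real.  The number
#' of frames is `floor((length(signal) - segment_len) / hop) + 1`; bin
#' centres are `k * fs / nfft`; frame centres are
#' `(start + segment_len / 2) / fs`.
#'
#' @param x Numeric vector, at least `segment_len` samples.
#' @param fs Sampling rate in Hz.
#' @param p An [stft_params()].
#' @return A [spectrogram()].
#' @export
stft_magnitude <- function(x, fs, p = stft_params()) {
  x <- as.numeric(x)
  if (length(x) < p$segment_len)
    stop("signal shorter than one STFT segment (", length(x), " < ",
         p$segment_len, " samples)", call. = FALSE)
  n_frames <- (length(x) - p$segment_len) %/% p$hop + 1L
  starts <- (seq_len(n_frames) - 1L) * p$hop           # 0-based
  taper <- stft_taper(p)
  segs <- matrix(0, nrow = p$nfft, ncol = n_frames)
  for (j in seq_len(n_frames))
    segs[seq_len(p$segment_len), j] <-
      x[(starts[j] + 1L):(starts[j] + p$segment_len)] * taper
  S <- stats::mvfft(segs)
  keep <- seq_len(p$nfft %/% 2L + 1L)
  spectrogram(Mod(S[keep, , drop = FALSE]),
              freqs = (keep - 1L) * fs / p$nfft,
              times = (starts + p$segment_len / 2) / fs)
}

#' Restrict a spectrogram to a frequency band
#'
#' Keeps exactly the rows whose bin-centre frequency lies in
#' `[fmin, fmax]` (inclusive).  With the default 128-point FFT at 250 Hz
#' and the 8-30 Hz band this retains 11 bins (9.77 to 29.30 Hz).
#'
#' @param sp A [spectrogram()].
#' @param b A [band_spec()].
#' @return A [spectrogram()] with the retained rows.
#' @export
band_restrict <- function(sp, b = band_spec()) {
  keep <- sp$freqs >= b$fmin & sp$freqs <= b$fmax
  if (!any(keep))
    stop(sprintf("no frequency bin centre falls in [%g, %g] Hz",
                 b$fmin, b$fmax), call. = FALSE)
  spectrogram(sp$E[keep, , drop = FALSE], sp$freqs[keep], sp$times)
}

#' Serialise / load a spectrogram
#'
#' The matrix goes to a delimited text file (rows = frequency bins) and
#' the bin/frame coordinates to a JSON sidecar, the same dialect as
#' [save_trials()].
#'
#' @param sp A [spectrogram()].
#' @param matrix_path,meta_path File paths.
#' @param sep Field separator.
#' @return `write_spectrogram` returns `sp` invisibly; `read_spectrogram`
#'   returns a [spectrogram()].
#' @export
write_spectrogram <- function(sp, matrix_path, meta_path, sep = ",") {
  utils::write.table(sp$E, matrix_path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(freqs = sp$freqs, times = sp$times),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(sp)
}

#' @rdname write_spectrogram
#' @export
read_spectrogram <- function(matrix_path, meta_path) {
  E <- as.matrix(utils::read.table(matrix_path, sep = sniff_sep(matrix_path),
                                   header = FALSE, colClasses = "numeric"))
  dimnames(E) <- NULL
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  spectrogram(E, meta$freqs, meta$times)
}
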