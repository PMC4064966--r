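# Shared fixture builders: everything is generated in code at test time.

# Random symmetric positive-definite matrix of size F.
rpsd <- function(F_, jitter = 0.1) {
  A <- matrix(rnorm(F_ * F_), F_, F_)
  crossprod(A) / F_ + diag(jitter, F_)
}

# Four random PSD class covariances of a common size.
rpsd_quadruple <- function(F_) lapply(1:4, function(k) rpsd(F_))

# Write a trial set to temporary CSV + JSON files; returns the two paths.
write_tmp_trials <- function(data, labels, fs = 250, channel = "C3",
                             artifact = NULL, sep = ",") {
  mpath <- withr::local_tempfile(fileext = ".csv",
                                 .local_envir = parent.frame())
  jpath <- withr::local_tempfile(fileext = ".json",
                                 .local_envir = parent.frame())
  utils::write.table(data, mpath, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(labels = labels, fs = fs, channel = channel)
  if (!is.null(artifact)) meta$artifact <- artifact
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  list(matrix = mpath, meta = jpath)
}

# Independent DFT oracle: magnitude of the nfft-point DFT of a tapered,
# zero-padded segment, computed as an explicit exponential sum (no FFT).
dft_magnitude_oracle <- function(seg, nfft) {
  n <- seq_along(seg) - 1L
  vapply(0:(nfft %/% 2L), function(k)
    Mod(sum(seg * exp(-2i * pi * k * n / nfft))), numeric(1))
}

# Band-power oracle: variance of the FFT-masked band-passed samples of a
# time slice (independent of the package's spectrogram path).
bandpower_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * fs / n
  X[f < lo | f > hi] <- 0
  stats::var(Re(stats::fft(X, inverse = TRUE)) / n)
}

# Small strong-effect synthetic set for pipeline-level tests.
small_strong_ts <- function(n_per_class = 8, seed = 301) {
  generate_trials(synth_config(n_per_class = n_per_class, seed = seed))
}

# Reduced (C, gamma) grid to keep pipeline tests fast.
small_grid <- function() list(C = 2^c(-1, 3, 7), gamma = 2^c(-7, -3, 1))
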