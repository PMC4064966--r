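# Synthetic single-channel four-class motor-imagery EEG.
#
# Each trial is a 1/f^beta background plus band-limited oscillations
# whose amplitude is modulated after the cue, emulating event-related
# desynchronization (ERD, power drop) and synchronization (ERS, power
# rise) of the mu and beta rhythms.  The modulation acts on amplitude
# envelopes, not phase, and the oscillations are band-passed noise, so
# nothing is phase-locked to the cue.

#' Per-class band modulation profiles
#'
#' A profile is a data frame with columns `centre` (Hz), `bw` (full
#' bandwidth, Hz) and `depth` (relative post-cue amplitude change in
#' `[-1, 1]`; negative = ERD, positive = ERS).  All four classes carry
#' the same baseline bands so pre-cue statistics are identical; only the
#' depths differ.
#'
#' The default gives each class a sign-coded ERD/ERS pattern across both
#' rhythms (mu 8-13 Hz, beta 16-25 Hz) at magnitude `depth`: class 1
#' desynchronises both (the classic contralateral hand-imagery pattern),
#' class 2 pairs mu ERD with beta ERS (post-imagery beta rebound),
#' class 3 pairs mu ERS with beta ERD (surround ERS over the hand area
#' during foot imagery), and class 4 synchronises both.  Every pair of
#' classes thus differs by `2 * depth` in at least one rhythm, which is
#' what makes the four classes separable from a single channel.
#'
#' @param depth Modulation magnitude, `0 <= depth <= 1`.  `depth = 0`
#'   gives four statistically identical classes (the chance-level null).
#' @return List of four data frames, one per class.
#' @export
default_profiles <- function(depth = 0.7) {
  if (!(is.numeric(depth) && length(depth) == 1L && depth >= 0 && depth <= 1))
    stop("depth must be a scalar in [0, 1]", call. = FALSE)
  bands <- function(d_mu, d_beta)
    data.frame(centre = c(10.5, 20.5),   # mu 8-13 Hz, beta 16-25 Hz
               bw     = c(5, 9),
               depth  = c(d_mu, d_beta), row.names = NULL)
  list(bands(-depth, -depth), bands(-depth, depth),
       bands(depth, -depth), bands(depth, depth))
}

#' Synthetic-EEG generator configuration
#'
#' Defaults mirror the cued motor-imagery paradigm the pipeline targets:
#' 7 s trials sampled at 250 Hz with the imagery cue at 3 s, a pink
#' (1/f) background and mu/beta oscillations.
#'
#' @param n_per_class Trials per class (balanced design).
#' @param fs Sampling rate, Hz.
#' @param trial_dur Trial duration, s.
#' @param cue_time Cue onset, s (`< trial_dur`); band modulation begins
#'   here with a raised-cosine ramp.
#' @param beta_exp Background spectral exponent: power ~ 1/f^beta_exp.
#' @param background_amp Background standard deviation, microvolts.
#' @param osc_amp Baseline (pre-cue) oscillation standard deviation per
#'   band, microvolts.  The default matches the background, putting
#'   clear mu/beta peaks on top of the 1/f spectrum as in resting
#'   sensorimotor recordings.
#' @param ramp Modulation ramp duration at cue onset, s.
#' @param seed Integer; fixes the generator for bitwise-reproducible
#'   output.  `NULL` uses the current RNG state.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 40L, fs = 250, trial_dur = 7,
                         cue_time = 3, beta_exp = 1, background_amp = 10,
                         osc_amp = 10, ramp = 0.25, seed = NULL) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("need at least one trial per class", call. = FALSE)
  if (!(cue_time >= 0 && cue_time < trial_dur))
    stop("cue_time must lie inside the trial", call. = FALSE)
  if (fs <= 0 || trial_dur <= 0) stop("fs and trial_dur must be positive",
                                      call. = FALSE)
  structure(list(n_per_class = n_per_class, fs = fs, trial_dur = trial_dur,
                 cue_time = cue_time, beta_exp = beta_exp,
                 background_amp = background_amp, osc_amp = osc_amp,
                 ramp = ramp,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synth_config")
}

# 1/f^beta noise of unit variance via spectral shaping of white noise:
# multiply the DFT of white noise by f^(-beta/2) (zeroing DC) and invert.
# The filter is symmetric in k and N - k, so the result stays real.
noise_one_over_f <- function(n, fs, beta_exp) {
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  h <- ifelse(f > 0, f^(-beta_exp / 2), 0)
  x <- Re(stats::fft(X * h, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Unit-variance band-limited noise: white noise with all DFT bins
# outside [lo, hi] Hz zeroed.
noise_bandpass <- function(n, fs, lo, hi) {
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Amplitude envelope: 1 before the cue, raised-cosine ramp of `ramp`
# seconds to (1 + depth), held to trial end.
cue_envelope <- function(t, cue_time, ramp, depth) {
  u <- (t - cue_time) / max(ramp, .Machine$double.eps)
  g <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  1 + depth * g
}

#' Generate a balanced synthetic motor-imagery trial set
#'
#' Each trial is `background_amp` x (1/f noise) plus, per profiled band,
#' `osc_amp` x (band-passed white noise) scaled by an envelope rising
#' from 1 to `1 + depth` at the cue.  Pre-cue statistics are identical
#' across classes by construction; class identity lives entirely in the
#' post-cue band-power modulation.  Labels are shuffled with the seeded
#' generator.
#'
#' @param cfg A [synth_config()].
#' @param profiles List of four per-class band profiles
#'   ([default_profiles()]).
#' @return A [trial_set()] with `4 * n_per_class` trials on synthetic
#'   channel `"SYN1"`.
#' @export
generate_trials <- function(cfg = synth_config(), profiles = default_profiles()) {
  if (length(profiles) != 4L)
    stop("need one band profile per class", call. = FALSE)
  for (pr in profiles) {
    if (!all(c("centre", "bw", "depth") %in% names(pr)))
      stop("each profile needs centre, bw and depth columns", call. = FALSE)
    if (any(pr$centre - pr$bw / 2 <= 0) || any(pr$centre + pr$bw / 2 >= cfg$fs / 2))
      stop("band [centre - bw/2, centre + bw/2] must lie inside (0, fs/2)",
           call. = FALSE)
    if (any(abs(pr$depth) > 1))
      stop("modulation depth must lie in [-1, 1]", call. = FALSE)
  }
  ns <- round(cfg$trial_dur * cfg$fs)
  t <- (seq_len(ns) - 1L) / cfg$fs
  build <- function() {
    labels <- sample(rep.int(1:4, cfg$n_per_class))
    data <- matrix(0, nrow = length(labels), ncol = ns)
    for (i in seq_along(labels)) {
      x <- cfg$background_amp * noise_one_over_f(ns, cfg$fs, cfg$beta_exp)
      pr <- profiles[[labels[i]]]
      for (b in seq_len(nrow(pr))) {
        env <- cue_envelope(t, cfg$cue_time, cfg$ramp, pr$depth[b])
        x <- x + cfg$osc_amp * env *
          noise_bandpass(ns, cfg$fs, pr$centre[b] - pr$bw[b] / 2,
                         pr$centre[b] + pr$bw[b] / 2)
      }
      data[i, ] <- x
    }
    trial_set(data, labels, cfg$fs, channel = "SYN1")
  }
  if (is.null(cfg$seed)) build() else withr::with_seed(cfg$seed, build())
}

#' Permute labels to build a chance-level null
#'
#' Data are untouched; labels are independently permuted, preserving the
#' label multiset.
#'
#' @param ts A [trial_set()].
#' @param seed Integer for a reproducible permutation; `NULL` uses the
#'   current RNG state.
#' @return A [trial_set()] with permuted labels.
#' @export
null_labels <- function(ts, seed = NULL) {
  perm <- if (is.null(seed)) sample.int(n_trials(ts))
          else withr::with_seed(as.integer(seed), sample.int(n_trials(ts)))
  trial_set(ts$data, ts$labels[perm], ts$fs, channel = ts$channel,
            artifact = ts$artifact, trial_t0 = ts$trial_t0)
}
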