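# End-to-end pipeline and evaluation surfaces: the m-sweep, the
# electrode x time-window accuracy grid, and its two-way ANOVA.

#' Run the full single-channel classification pipeline
#'
#' Window extraction -> magnitude STFT per trial -> band restriction ->
#' stratified cross-validation in which, per fold, OVR-CSP filters are
#' fitted on the training trials only, train and test trials are
#' featurised with those filters, (C, gamma) is grid-searched on the
#' training features by an inner cross-validation, and the winning model
#' is scored on the held-out fold.  CSP fitting never sees test-fold
#' trials, so spatial filters cannot leak held-out information.
#'
#' @param ts A [trial_set()]; artifact-flagged trials are dropped first.
#' @param w Analysis [epoch_window()].  The default is the full imagery
#'   period from the 3 s cue to the 7 s trial end, which maximises the
#'   number of spectrogram frames behind each variance feature; the four
#'   one-second windows of [eval_grid()] are the per-second evaluation
#'   surface.
#' @param stft [stft_params()].
#' @param band [band_spec()].
#' @param m CSP filters per tail (default 7, where accuracy peaks).
#' @param proto Outer [cv_protocol()]; its seed fixes the partitions.
#' @param grid (C, gamma) grid for the inner search
#'   ([default_svm_grid()]).
#' @param inner_folds Folds of the inner grid-search CV (default 5, one
#'   repetition) — nested inside each outer training set.
#' @return An object of class `pipeline_result`: `accuracy` (mean
#'   held-out accuracy), `folds` (per-fold data frame with the selected
#'   C and gamma), `models` (per-fold `ovr_csp` fits of the first
#'   repetition), `partitions` (fold assignments per repetition), plus
#'   the call parameters.
#' @export
run_pipeline <- function(ts, w = epoch_window(3, 7), stft = stft_params(),
                         band = band_spec(), m = 7L,
                         proto = cv_protocol(n_repeats = 1L),
                         grid = default_svm_grid(), inner_folds = 5L) {
  if (any(ts$artifact)) ts <- drop_artifacts(ts)
  wts <- extract_window(ts, w)
  specs <- lapply(seq_len(n_trials(wts)), function(i)
    band_restrict(stft_magnitude(wts$data[i, ], wts$fs, stft), band))
  F_ <- nrow(specs[[1]]$E)
  if (2L * m > F_)
    warning("2m = ", 2L * m, " exceeds the ", F_,
            " frequency bins in band: CSP filter tails overlap",
            call. = FALSE)
  y <- wts$labels
  partitions <- draw_partitions(y, proto)
  models <- vector("list", proto$n_folds)
  rows <- do.call(rbind, lapply(seq_along(partitions), function(r) {
    fold <- partitions[[r]]
    do.call(rbind, lapply(seq_len(proto$n_folds), function(f) {
      te <- fold == f
      if (!any(te)) return(NULL)
      covs <- lapply(1:4, function(k)
        class_covariance(specs[!te & y == k], class_id = k))
      csp <- fit_ovr_csp(covs, m = m, warn_overlap = FALSE)
      if (r == 1L) models[[f]] <<- csp
      Xtr <- csp_features(csp, specs[!te])
      Xte <- csp_features(csp, specs[te])
      inner_seed <- if (is.null(proto$seed)) NULL
                    else (proto$seed + 131L * r + f) %% 2147483647L
      spec <- grid_search_cv(Xtr, y[!te],
                             proto = cv_protocol(n_folds = inner_folds,
                                                 n_repeats = 1L,
                                                 seed = inner_seed),
                             grid = grid)
      data.frame(rep = r, fold = f, n = sum(te),
                 C = spec$C, gamma = spec$gamma,
                 accuracy = fit_score_svm(Xtr, y[!te], Xte, y[te], spec))
    }))
  }))
  structure(list(accuracy = mean(rows$accuracy, na.rm = TRUE), folds = rows,
                 models = models, partitions = partitions,
                 m = m, F = F_, window = w,
                 channel = ts$channel, proto = proto),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> channel %s, window [%g, %g) s, m = %d: mean CV accuracy %.3f (sd %.3f over %d folds)\n",
    x$channel, x$window$t_start, x$window$t_end, x$m,
    x$accuracy, stats::sd(x$folds$accuracy), nrow(x$folds)))
  invisible(x)
}

#' Sweep the number of CSP filters per tail
#'
#' Runs the full pipeline at each `m` and reports the accuracy curve and
#' its argmax.  Values with `2m > F` are still evaluated (with
#' overlapping filter rows); the curve covers the whole range.
#'
#' @param ts A [trial_set()].
#' @param w Analysis window.
#' @param m_range Integer vector of `m` values (default `1:10`).
#' @param ... Passed to [run_pipeline()] (`stft`, `band`, `proto`,
#'   `grid`, `inner_folds`).
#' @return An object of class `msweep_result`: `sweep` (data frame `m`,
#'   `accuracy`), `best_m` (smallest argmax).
#' @export
sweep_m <- function(ts, w = epoch_window(3, 7), m_range = 1:10, ...) {
  m_range <- sort(unique(as.integer(m_range)))
  if (length(m_range) == 0L) stop("m_range is empty", call. = FALSE)
  acc <- vapply(m_range, function(m)
    run_pipeline(ts, w = w, m = m, ...)$accuracy, numeric(1))
  structure(list(sweep = data.frame(m = m_range, accuracy = acc),
                 best_m = m_range[which.max(acc)]),
            class = "msweep_result")
}

#' @export
print.msweep_result <- function(x, ...) {
  cat("<msweep_result> accuracy by m:\n")
  print(x$sweep, row.names = FALSE)
  cat("best m:", x$best_m, "\n")
  invisible(x)
}

#' Electrode x time-window accuracy grid
#'
#' Runs the pipeline for every (channel, window) pair — one trial set
#' per electrode — mirroring the per-electrode, per-second evaluation
#' design of the four post-cue windows [3,4), [4,5), [5,6), [6,7) s.
#'
#' @param ts_list Named list of [trial_set()]s, one per electrode.
#' @param windows List of [epoch_window()]s (default the four post-cue
#'   seconds).
#' @param ... Passed to [run_pipeline()].
#' @return An object of class `eval_grid`: `accuracy` (channels x
#'   windows matrix), `dispersion` (fold standard deviations, same
#'   shape), `channels`, `windows`.
#' @export
eval_grid <- function(ts_list,
                      windows = list(epoch_window(3, 4), epoch_window(4, 5),
                                     epoch_window(5, 6), epoch_window(6, 7)),
                      ...) {
  chans <- names(ts_list)
  if (is.null(chans))
    chans <- vapply(ts_list, function(ts) ts$channel, character(1))
  wlab <- vapply(windows, function(w)
    sprintf("%g-%g s", w$t_start, w$t_end), character(1))
  acc <- disp <- matrix(NA_real_, length(ts_list), length(windows),
                        dimnames = list(chans, wlab))
  for (i in seq_along(ts_list)) for (j in seq_along(windows)) {
    res <- run_pipeline(ts_list[[i]], w = windows[[j]], ...)
    acc[i, j] <- res$accuracy
    disp[i, j] <- stats::sd(res$folds$accuracy)
  }
  structure(list(accuracy = acc, dispersion = disp,
                 channels = chans, windows = windows),
            class = "eval_grid")
}

#' @export
print.eval_grid <- function(x, ...) {
  cat("<eval_grid> mean CV accuracy (channels x windows):\n")
  print(round(x$accuracy, 3))
  invisible(x)
}

#' Two-way fixed-effects ANOVA on an accuracy grid
#'
#' Tests whether classification accuracy differs across electrodes and
#' across time windows, treating participants or datasets as replicates.
#' The design must be complete and balanced.  With one replicate per
#' cell no interaction term is estimable and main effects are tested
#' against the residual; with several replicates the channel:window
#' interaction is included.
#'
#' @param df Data frame with columns `channel`, `window`, `accuracy` and
#'   optionally `replicate` (participant/dataset id).
#' @return An object of class `anova_grid`: `table` (data frame: term,
#'   df, sum of squares, mean square, F, p) and `fit` (the underlying
#'   `aov`).
#' @export
anova_two_way <- function(df) {
  need <- c("channel", "window", "accuracy")
  if (!all(need %in% names(df)))
    stop("data frame needs columns channel, window, accuracy", call. = FALSE)
  df$channel <- factor(df$channel)
  df$window <- factor(df$window)
  if (nlevels(df$channel) < 2L || nlevels(df$window) < 2L)
    stop("need at least two levels of each factor", call. = FALSE)
  counts <- table(df$channel, df$window)
  if (any(counts == 0L) || length(unique(as.vector(counts))) != 1L)
    stop("design must be complete and balanced (equal replicates per cell)",
         call. = FALSE)
  reps <- unique(as.vector(counts))
  form <- if (reps > 1L) accuracy ~ channel * window else accuracy ~ channel + window
  fit <- stats::aov(form, data = df)
  s <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(s)), df = s[["Df"]],
                    sumsq = s[["Sum Sq"]], meansq = s[["Mean Sq"]],
                    F = s[["F value"]], p = s[["Pr(>F)"]],
                    row.names = NULL)
  # zero between-group variance: F = 0, p = 1 by convention (avoids the
  # 0/0 that a constant response would otherwise produce)
  degen <- tab$term != "Residuals" &
    tab$sumsq <= 1e-12 * max(sum(tab$sumsq), .Machine$double.eps)
  tab$F[degen] <- 0
  tab$p[degen] <- 1
  structure(list(table = tab, fit = fit), class = "anova_grid")
}

#' @export
print.anova_grid <- function(x, ...) {
  cat("<anova_grid> two-way ANOVA on accuracy:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Published benchmark accuracy grid
#'
#' Cross-validated accuracies of the single-channel spectrogram-CSP
#' method on BCI Competition III dataset IIIa (participants K3, K6, L1):
#' six electrodes (Fp1, Fpz, Fp2, C3, Cz, C4) by four post-cue
#' one-second windows.  Shipped as a plain-text fixture so the two-way
#' ANOVA surface can be exercised without the external recordings.
#'
#' @return Data frame with columns `channel`, `replicate` (participant),
#'   `window`, `accuracy`.
#' @export
benchmark_accuracy_grid <- function() {
  path <- system.file("extdata", "bci3a_accuracy_grid.csv",
                      package = "stftcsp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
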