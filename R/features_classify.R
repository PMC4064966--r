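# Variance features and C-SVC/RBF classification with grid search and
# repeated stratified cross-validation.
#
# The quadratic program behind C-SVC is delegated to libsvm (via e1071),
# the solver conventionally used for this classifier; this module owns
# the feature construction, the (C, gamma) grid, fold construction and
# the scaling protocol.

#' Row-wise variance features of a filtered spectrogram
#'
#' Each CSP-filtered row's power over time is summarised by its sample
#' variance across frames (denominator `T - 1`), giving one nonnegative
#' feature per filter row.
#'
#' @param Z Numeric `2m x T` matrix from [apply_filters()], `T >= 2`.
#' @return Numeric vector of length `nrow(Z)`.
#' @export
variance_features <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 2L)
    stop("need at least two time frames to take a variance", call. = FALSE)
  apply(Z, 1L, stats::var)
}

#' Concatenate the four per-class feature vectors
#'
#' Class order 1, 2, 3, 4 is significant; the composite has length
#' `4 * 2m` (56 at the default m = 7).
#'
#' @param f1,f2,f3,f4 Equal-length per-class feature vectors.
#' @return Numeric vector of length `4 * length(f1)`.
#' @export
composite_features <- function(f1, f2, f3, f4) {
  fs <- list(f1, f2, f3, f4)
  if (length(unique(lengths(fs))) != 1L)
    stop("per-class feature vectors differ in length", call. = FALSE)
  c(f1, f2, f3, f4)
}

#' Feature matrix for a set of trials under a fitted OVR-CSP model
#'
#' Applies all four class filters to every trial's spectrogram and
#' concatenates the per-class variance features.
#'
#' @param model An [fit_ovr_csp()] model.
#' @param specs List of [spectrogram()]s (or F x T matrices).
#' @return Numeric matrix, `length(specs)` rows by `8m` columns
#'   (`f_1 .. f_8m`).
#' @export
csp_features <- function(model, specs) {
  X <- t(vapply(specs, function(sp) {
    fk <- lapply(1:4, function(k) variance_features(apply_filters(model, k, sp)))
    composite_features(fk[[1]], fk[[2]], fk[[3]], fk[[4]])
  }, numeric(8L * model$m)))
  colnames(X) <- paste0("f_", seq_len(ncol(X)))
  X
}

#' RBF support-vector classifier specification
#'
#' @param C Soft-margin penalty, `> 0`.
#' @param gamma RBF kernel width parameter, `> 0`.
#' @return An object of class `svm_spec` (kernel fixed to RBF).
#' @export
svm_spec <- function(C, gamma) {
  if (!(is.numeric(C) && length(C) == 1L && C > 0))
    stop("C must be a positive scalar", call. = FALSE)
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0))
    stop("gamma must be a positive scalar", call. = FALSE)
  structure(list(C = as.numeric(C), gamma = as.numeric(gamma),
                 kernel = "rbf"),
            class = "svm_spec")
}

#' Cross-validation protocol
#'
#' @param n_folds Folds per repetition (default 10).
#' @param n_repeats Independent repetitions with re-drawn partitions
#'   (default 10).
#' @param stratified Preserve class proportions per fold (default `TRUE`).
#' @param seed Integer driving fold assignment; `NULL` uses the current
#'   RNG state.
#' @return An object of class `cv_protocol`.
#' @export
cv_protocol <- function(n_folds = 10L, n_repeats = 10L, stratified = TRUE,
                        seed = NULL) {
  n_folds <- as.integer(n_folds); n_repeats <- as.integer(n_repeats)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n_repeats < 1L) stop("need at least 1 repeat", call. = FALSE)
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 stratified = stratified,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cv_protocol")
}

# Fold assignment for one repetition.  Stratified: within each class,
# shuffle and deal fold ids round-robin so fold sizes differ by at most
# one per class.
assign_folds <- function(y, n_folds, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

# Draw fold assignments for all repetitions under the protocol's seed.
draw_partitions <- function(y, proto) {
  draw <- function() lapply(seq_len(proto$n_repeats), function(r)
    assign_folds(y, proto$n_folds, proto$stratified))
  if (is.null(proto$seed)) draw() else withr::with_seed(proto$seed, draw())
}

# Per-feature affine map onto [0, 1], fitted on training data only.
# Constant features map to 0 (width clamped to 1) so test data cannot
# blow up.
fit_scaler <- function(X) {
  lo <- apply(X, 2L, min)
  width <- apply(X, 2L, max) - lo
  width[width <= 0] <- 1
  list(lo = lo, width = width)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$lo, "-"), 2L, scaler$width, "/")
}

# Fit an RBF C-SVC on scaled features and score held-out accuracy.
# Multiclass handling is libsvm's one-vs-one voting.  Degenerate folds
# (no held-out sample, or single-class training data on very small sets)
# score NA and are dropped from fold means.
fit_score_svm <- function(Xtr, ytr, Xte, yte, spec) {
  if (length(yte) == 0L || length(unique(ytr)) < 2L) return(NA_real_)
  scaler <- fit_scaler(Xtr)
  fit <- e1071::svm(apply_scaler(scaler, Xtr), factor(ytr, levels = 1:4),
                    kernel = "radial", cost = spec$C, gamma = spec$gamma,
                    scale = FALSE)
  pred <- predict(fit, apply_scaler(scaler, Xte))
  mean(as.integer(as.character(pred)) == yte)
}

#' Default (C, gamma) search grid
#'
#' The conventional coarse grid for RBF C-SVC model selection:
#' `C = 2^(-5), 2^(-3), ..., 2^15` and
#' `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @return List with numeric vectors `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5L, 15L, by = 2L), gamma = 2^seq(-15L, 3L, by = 2L))
}

#' Grid-search (C, gamma) by cross-validated accuracy
#'
#' Evaluates every grid point with the same seeded fold partitions and
#' returns the pair with maximal mean CV accuracy; ties break towards
#' smaller `C`, then smaller `gamma`.  Feature scaling is refit inside
#' each training fold, never on held-out data.
#'
#' @param X Numeric feature matrix, one row per trial.
#' @param y Integer labels in `1:4`, one per row of `X`.
#' @param proto A [cv_protocol()].
#' @param grid List with vectors `C` and `gamma` ([default_svm_grid()]).
#' @return The winning [svm_spec()], with attributes `cv_accuracy` (its
#'   mean CV accuracy) and `grid_results` (a data frame of all points).
#' @export
grid_search_cv <- function(X, y, proto = cv_protocol(n_repeats = 1L),
                           grid = default_svm_grid()) {
  X <- as.matrix(X); y <- as.integer(y)
  if (nrow(X) != length(y))
    stop("X rows and labels differ in number", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("need at least two classes to train a classifier", call. = FALSE)
  partitions <- draw_partitions(y, proto)
  pts <- expand.grid(C = sort(grid$C), gamma = sort(grid$gamma),
                     KEEP.OUT.ATTRS = FALSE)
  # order so the first maximum found is the smallest C, then gamma
  pts <- pts[order(pts$C, pts$gamma), , drop = FALSE]
  acc <- vapply(seq_len(nrow(pts)), function(i) {
    spec <- svm_spec(pts$C[i], pts$gamma[i])
    mean(unlist(lapply(partitions, function(fold) {
      vapply(seq_len(proto$n_folds), function(f) {
        te <- fold == f
        fit_score_svm(X[!te, , drop = FALSE], y[!te],
                      X[te, , drop = FALSE], y[te], spec)
      }, numeric(1))
    })), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)
  out <- svm_spec(pts$C[best], pts$gamma[best])
  attr(out, "cv_accuracy") <- acc[best]
  attr(out, "grid_results") <- cbind(pts, accuracy = acc)
  out
}

#' Repeated stratified cross-validated accuracy of a fixed (C, gamma)
#'
#' @inheritParams grid_search_cv
#' @param spec An [svm_spec()].
#' @return List with `mean` (overall mean held-out accuracy) and `folds`
#'   (data frame: repeat, fold, n held-out, accuracy) for dispersion
#'   reporting.
#' @export
cv_accuracy <- function(X, y, spec, proto = cv_protocol()) {
  X <- as.matrix(X); y <- as.integer(y)
  if (nrow(X) != length(y))
    stop("X rows and labels differ in number", call. = FALSE)
  partitions <- draw_partitions(y, proto)
  rows <- do.call(rbind, lapply(seq_along(partitions), function(r) {
    fold <- partitions[[r]]
    if (length(unique(y)) < 2L ||
        any(vapply(seq_len(proto$n_folds),
                   function(f) length(unique(y[fold != f])) < 2L, logical(1))))
      stop("a training fold lost all but one class; check stratification",
           call. = FALSE)
    do.call(rbind, lapply(seq_len(proto$n_folds), function(f) {
      te <- fold == f
      if (!any(te)) return(NULL)
      data.frame(rep = r, fold = f, n = sum(te),
                 accuracy = fit_score_svm(X[!te, , drop = FALSE], y[!te],
                                          X[te, , drop = FALSE], y[te],
                                          spec))
    }))
  }))
  list(mean = mean(rows$accuracy), folds = rows)
}
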