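# One-versus-rest common spatial patterns on spectrogram matrices.
#
# Frequency bins act as channels: per-class spatial covariances of the
# F x T magnitude matrices are whitened against the composite covariance
# and simultaneously diagonalised, class-vs-rest.  Because the whitened
# own-class and rest-class covariances sum to the identity, they share
# eigenvectors and their eigenvalues are complementary (sum to 1), so the
# leading filters maximise own-class variance while the trailing ones
# minimise it.

#' Spatial covariance container
#'
#' @param R Symmetric positive semi-definite F x F matrix.
#' @param class_id One of `1:4` or `"composite"`.
#' @return An object of class `cov_matrix`.
#' @export
cov_matrix <- function(R, class_id = "composite") {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-10)
    stop("covariance must be square and symmetric", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("covariance must be positive semi-definite", call. = FALSE)
  structure(list(R = (R + t(R)) / 2, class_id = class_id),
            class = "cov_matrix")
}

as_cov <- function(R) if (inherits(R, "cov_matrix")) R$R else as.matrix(R)

#' Per-class spatial covariance of spectrogram matrices
#'
#' For each trial's F x T matrix `E` computes `E %*% t(E)`, optionally
#' divides by its trace (removing per-trial amplitude scale, standard CSP
#' practice), and averages across trials.
#'
#' @param specs List of [spectrogram()]s (or bare F x T matrices), all
#'   with the same number of frequency bins.
#' @param class_id Label stored on the result.
#' @param normalise If `TRUE` (default) each trial's covariance is
#'   trace-normalised before averaging.
#' @return A [cov_matrix()].
#' @export
class_covariance <- function(specs, class_id = "composite", normalise = TRUE) {
  if (length(specs) == 0L) stop("no trials supplied", call. = FALSE)
  mats <- lapply(specs, function(s) if (inherits(s, "spectrogram")) s$E else as.matrix(s))
  F_ <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == F_))
    stop("all spectrograms must share the same number of frequency bins",
         call. = FALSE)
  acc <- matrix(0, F_, F_)
  for (E in mats) {
    C <- tcrossprod(E)
    if (normalise) {
      tr <- sum(diag(C))
      if (tr <= 0)
        stop("degenerate trial: zero spectrogram has no trace to normalise by",
             call. = FALSE)
      C <- C / tr
    }
    acc <- acc + C
  }
  cov_matrix(acc / length(mats), class_id = class_id)
}

#' Composite covariance: elementwise sum of the four class covariances
#'
#' @param R1,R2,R3,R4 Per-class [cov_matrix()] objects (or matrices) of a
#'   common size.
#' @return A [cov_matrix()] with `class_id = "composite"`.
#' @export
composite_covariance <- function(R1, R2, R3, R4) {
  Rs <- lapply(list(R1, R2, R3, R4), as_cov)
  d <- unique(vapply(Rs, nrow, 1L))
  if (length(d) != 1L)
    stop("class covariances differ in size", call. = FALSE)
  cov_matrix(Rs[[1]] + Rs[[2]] + Rs[[3]] + Rs[[4]])
}

#' Whitening transform of the composite covariance
#'
#' Eigen-decomposes `Rc = U %*% diag(d) %*% t(U)` and forms
#' `P = diag(1/sqrt(d)) %*% t(U)` so that `P %*% Rc %*% t(P) = I`.  When
#' the smallest eigenvalue falls below `ridge_scale * trace(Rc) / F` a
#' ridge of that size is added to the diagonal first (and recorded), so
#' near-singular composites still whiten stably.
#'
#' @param Rc A [cov_matrix()] or symmetric PSD matrix.
#' @param ridge_scale Relative ridge threshold (default `1e-8`).
#' @return An object of class `whitening_model` with fields `P` (F x F),
#'   `eigvals` (descending, of the possibly ridged matrix) and `ridge`
#'   (the scalar added to the diagonal, 0 if none).
#' @export
whitening <- function(Rc, ridge_scale = 1e-8) {
  R <- as_cov(Rc)
  if (max(abs(R - t(R))) > 1e-10)
    stop("composite covariance must be symmetric", call. = FALSE)
  F_ <- nrow(R)
  eps <- ridge_scale * sum(diag(R)) / F_
  ridge <- 0
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < eps) {
    ridge <- eps
    e <- eigen(R + diag(eps, F_), symmetric = TRUE)
  }
  P <- diag(1 / sqrt(e$values), F_) %*% t(e$vectors)
  structure(list(P = P, eigvals = e$values, ridge = ridge),
            class = "whitening_model")
}

# Deterministic sign convention: make each row's largest-magnitude entry
# positive, so filters do not depend on the eigen-solver's sign choices.
fix_row_signs <- function(W) {
  sgn <- apply(W, 1L, function(r) {
    s <- sign(r[which.max(abs(r))])
    if (s == 0) 1 else s
  })
  W * sgn
}

#' Fit one-versus-rest CSP filters from four class covariances
#'
#' For each class `k` the composite-whitened own-class covariance
#' `S_k = P %*% R_k %*% t(P)` is eigen-decomposed; since
#' `S_k + S_rest = I`, the eigenvectors simultaneously diagonalise the
#' own and rest covariances with complementary eigenvalues.  The
#' projection matrix is `W_k = t(B) %*% P` with rows ordered by
#' descending own-class eigenvalue; the spatial filter `Wtil_k` stacks
#' the first `m` rows (maximal own-class variance) on the last `m` rows
#' (minimal own-class / maximal rest variance).  When `2 * m > F` the two
#' row sets overlap and duplicated rows are kept, with a warning.
#'
#' @param Rs List of four per-class [cov_matrix()] objects (or matrices),
#'   classes 1-4 in order.
#' @param m Filters per tail, `1 <= m <= F`.
#' @param ridge_scale Passed to [whitening()].
#' @param warn_overlap Warn when `2 * m > F` (default `TRUE`).
#' @return An object of class `ovr_csp` with fields `W` (list of four
#'   F x F projection matrices), `lam` (list of own-class eigenvalues,
#'   descending, in `[0, 1]`), `Wtil` (list of 2m x F filters), `m`, `F`,
#'   and `whitening` (the [whitening()] model of the composite).
#' @export
fit_ovr_csp <- function(Rs, m, ridge_scale = 1e-8, warn_overlap = TRUE) {
  if (length(Rs) != 4L)
    stop("need exactly four class covariances", call. = FALSE)
  Rs <- lapply(Rs, as_cov)
  F_ <- nrow(Rs[[1]])
  if (!all(vapply(Rs, nrow, 1L) == F_))
    stop("class covariances differ in size", call. = FALSE)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > F_)
    stop("m must be an integer in 1..F (F = ", F_, ")", call. = FALSE)
  if (warn_overlap && 2L * m > F_)
    warning("2m = ", 2L * m, " exceeds F = ", F_,
            ": first-m and last-m filter rows overlap; duplicated rows kept",
            call. = FALSE)
  wh <- whitening(composite_covariance(Rs[[1]], Rs[[2]], Rs[[3]], Rs[[4]]),
                  ridge_scale = ridge_scale)
  P <- wh$P
  idx <- c(seq_len(m), (F_ - m + 1L):F_)
  W <- lam <- Wtil <- vector("list", 4L)
  for (k in 1:4) {
    Sk <- P %*% Rs[[k]] %*% t(P)
    Sk <- (Sk + t(Sk)) / 2
    e <- eigen(Sk, symmetric = TRUE)        # eigenvalues descending
    Wk <- fix_row_signs(t(e$vectors) %*% P)
    W[[k]] <- Wk
    lam[[k]] <- e$values
    Wtil[[k]] <- Wk[idx, , drop = FALSE]
  }
  structure(list(W = W, lam = lam, Wtil = Wtil, m = m, F = F_,
                 whitening = wh),
            class = "ovr_csp")
}

#' @export
print.ovr_csp <- function(x, ...) {
  cat(sprintf("<ovr_csp> F = %d virtual channels, m = %d filters per tail (%d rows per class)\n",
              x$F, x$m, 2L * x$m))
  invisible(x)
}

#' Apply a class's spatial filter to a spectrogram
#'
#' Computes `Z = Wtil_k %*% E`: the first `m` rows carry maximal
#' variance for class `k`, the last `m` minimal.
#'
#' @param model An [fit_ovr_csp()] model.
#' @param k Class id in `1:4`.
#' @param sp A [spectrogram()] (or F x T matrix) with `F` rows matching
#'   the model.
#' @return A `2m x T` numeric matrix.
#' @export
apply_filters <- function(model, k, sp) {
  E <- if (inherits(sp, "spectrogram")) sp$E else as.matrix(sp)
  if (nrow(E) != model$F)
    stop("spectrogram has ", nrow(E), " rows but the model expects ",
         model$F, call. = FALSE)
  model$Wtil[[k]] %*% E
}

#' Serialise / load an OVR-CSP model as JSON
#'
#' Filters and eigenvalues are stored row-major with `F`, `m` and the
#' class order recorded, so a model can be refit once and reused.
#'
#' @param model An [fit_ovr_csp()] model.
#' @param path Output (input) JSON path.
#' @return `write_csp_model` returns `model` invisibly; `read_csp_model`
#'   returns an `ovr_csp` model.
#' @export
write_csp_model <- function(model, path) {
  doc <- list(
    F = model$F, m = model$m, classes = 1:4,
    lam = model$lam,
    W = lapply(model$W, function(w) as.vector(t(w))),      # row-major
    Wtil = lapply(model$Wtil, function(w) as.vector(t(w))),
    ridge = model$whitening$ridge)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_csp_model
#' @export
read_csp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  F_ <- as.integer(doc$F); m <- as.integer(doc$m)
  # simplifyVector collapses lists of equal-length vectors to matrices
  as_rows <- function(x) if (is.matrix(x)) asplit(x, 1L) else x
  unflat <- function(v, nr) matrix(as.numeric(v), nrow = nr, ncol = F_,
                                   byrow = TRUE)
  W <- lapply(as_rows(doc$W), unflat, nr = F_)
  Wtil <- lapply(as_rows(doc$Wtil), unflat, nr = 2L * m)
  lam <- as_rows(doc$lam)
  structure(list(W = W, lam = lapply(lam, as.numeric), Wtil = Wtil,
                 m = m, F = F_,
                 whitening = list(P = NULL, eigvals = NULL,
                                  ridge = doc$ridge)),
            class = "ovr_csp")
}
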