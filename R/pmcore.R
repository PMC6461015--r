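# Posture-space PCA: assemble the pooled matrix, fit the basis, project
# trials to principal positions, differentiate, and reconstruct amplified
# single-component marker motions.

#' Stack preprocessed trials into one pooled data matrix
#'
#' Vertical concatenation of the trials' matrices, in the given order, with
#' each trial's contiguous row range recorded so pooled scores can be sliced
#' back per trial.
#'
#' @param trials list of `preprocessed_trial` objects sharing N and marker
#'   label order.
#' @return An `assembled_matrix` with fields `matrix`, `trial_ids`,
#'   `trial_spans` (list of `c(first, last)` row indices), `marker_labels`,
#'   `sampling_rates` and a preprocessing `fingerprint`.
#' @export
assemble <- function(trials) {
  if (!length(trials)) stop("need at least one trial")
  labs <- trials[[1L]]$marker_labels
  N <- ncol(trials[[1L]]$matrix)
  for (tr in trials) {
    if (ncol(tr$matrix) != N || !identical(tr$marker_labels, labs))
      stop("trial ", tr$trial_id, " has mismatched columns or marker labels")
  }
  rows <- vapply(trials, function(tr) nrow(tr$matrix), integer(1L))
  ends <- cumsum(rows)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(list(
    matrix = do.call(rbind, lapply(trials, `[[`, "matrix")),
    trial_ids = vapply(trials, function(tr)
      paste(tr$subject_id, tr$trial_id, sep = "/"), character(1L)),
    trial_spans = Map(c, starts, ends),
    marker_labels = labs,
    sampling_rates = vapply(trials, `[[`, numeric(1L), "sampling_rate"),
    fingerprint = preprocessing_fingerprint(trials[[1L]])
  ), class = "assembled_matrix")
}

preprocessing_fingerprint <- function(trial) {
  paste0("norm=", trial$normalization %||% "none",
         ";weighted=", !is.null(trial$weights),
         ";N=", ncol(trial$matrix))
}

#' Fit the posture-space basis by PCA
#'
#' Eigendecomposition of the pooled covariance matrix, implemented as an SVD
#' of the (residually re-centered) assembled matrix. Eigenvalues use the
#' sample-covariance divisor `rows - 1`. Relative eigenvalues `rEV_k` are
#' percentages of the total variance over all `min(rows - 1, N)` eigenvalues,
#' regardless of how many components `K` are retained. The sign of each
#' eigenvector is fixed by making its largest-magnitude coefficient positive;
#' exact eigenvalue ties are ordered lexicographically by component vector.
#'
#' @param assembled an [assemble] result (or a bare numeric matrix).
#' @param K number of components to retain; `NULL` keeps all.
#' @return A `posture_space`: `components` (N x K orthonormal columns PC_k),
#'   `eigenvalues` (EV_k, descending), `rel_eigenvalues` (rEV_k, percent,
#'   over all eigenvalues), `grand_center` (residual column means removed,
#'   ~0 for per-trial-centered cohorts), `marker_labels`, `fingerprint`.
#' @export
fit_posture_space <- function(assembled, K = NULL) {
  bare <- is.matrix(assembled)
  M <- if (bare) assembled else assembled$matrix
  if (nrow(M) < 2L) stop("need at least 2 pooled rows")
  N <- ncol(M)
  if (!is.null(K) && K > N) stop("K (", K, ") exceeds N (", N, ")")
  mu <- colMeans(M)
  C <- sweep(M, 2L, mu)
  sv <- svd(C)
  nev <- min(nrow(M), N)   # trailing eigenvalues beyond rank are exactly 0
  EV <- (sv$d^2 / (nrow(M) - 1L))[seq_len(nev)]
  EV[EV < 0] <- 0
  PC <- sv$v[, seq_len(nev), drop = FALSE]
  ord <- order_with_tiebreak(EV, PC)
  EV <- EV[ord]; PC <- PC[, ord, drop = FALSE]
  # deterministic sign: largest |coefficient| positive
  for (k in seq_len(ncol(PC))) {
    i <- which.max(abs(PC[, k]))
    if (PC[i, k] < 0) PC[, k] <- -PC[, k]
  }
  rEV <- EV / sum(EV) * 100
  keep <- seq_len(min(K %||% nev, nev))
  structure(list(
    components = PC[, keep, drop = FALSE],
    eigenvalues = EV[keep],
    rel_eigenvalues = rEV[keep],
    all_eigenvalues = EV,
    all_rel_eigenvalues = rEV,
    grand_center = mu,
    n_markers = N / 3L,
    marker_labels = if (bare) NULL else assembled$marker_labels,
    fingerprint = if (bare) NULL else assembled$fingerprint
  ), class = "posture_space")
}

# descending eigenvalue order; exact ties broken lexicographically on the
# component coefficients (stabilizes degenerate spectra)
order_with_tiebreak <- function(EV, PC) {
  ord <- order(-EV)
  i <- 1L
  while (i < length(ord)) {
    j <- i
    while (j < length(ord) && EV[ord[j + 1L]] == EV[ord[i]]) j <- j + 1L
    if (j > i) {
      tied <- ord[i:j]
      key <- apply(PC[, tied, drop = FALSE], 2L, paste, collapse = ",")
      ord[i:j] <- tied[order(key)]
    }
    i <- j + 1L
  }
  ord
}

#' @export
print.posture_space <- function(x, ...) {
  cat(sprintf("posture_space: %d components over N=%d columns\n",
              ncol(x$components), nrow(x$components)))
  k <- seq_len(min(5L, length(x$rel_eigenvalues)))
  cat("  rEV:", paste0(sprintf("%.2f", x$rel_eigenvalues[k]), "%",
                       collapse = " "),
      if (length(x$rel_eigenvalues) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Project a trial into posture space
#'
#' Principal positions `PP_k(t)`: the trial matrix (less the residual grand
#' center stored in the space, so pooled and per-trial scores coincide)
#' multiplied by the eigenvector basis.
#'
#' @param trial a `preprocessed_trial`, or a bare T x N matrix.
#' @param space a [fit_posture_space] result with matching N; a differing
#'   preprocessing fingerprint triggers a warning.
#' @return A `pm_timeseries` with the score matrix `PP` (T x K); `PV`/`PA`
#'   empty until [differentiate] is called.
#' @export
project <- function(trial, space) {
  bare <- is.matrix(trial)
  M <- if (bare) trial else trial$matrix
  if (ncol(M) != nrow(space$components))
    stop("trial has ", ncol(M), " columns, space expects ",
         nrow(space$components))
  if (!bare && !is.null(space$fingerprint)) {
    fp <- preprocessing_fingerprint(trial)
    if (!identical(fp, space$fingerprint))
      warning("preprocessing fingerprint mismatch: trial '", fp,
              "' vs space '", space$fingerprint, "'")
  }
  PP <- sweep(M, 2L, space$grand_center) %*% space$components
  structure(list(
    subject_id = if (bare) NA_character_ else trial$subject_id,
    trial_id = if (bare) NA_character_ else trial$trial_id,
    sampling_rate = if (bare) NA_real_ else trial$sampling_rate,
    PP = PP, PV = NULL, PA = NULL
  ), class = "pm_timeseries")
}

#' @export
print.pm_timeseries <- function(x, ...) {
  cat(sprintf("pm_timeseries: subject %s trial %s | %d frames x %d components | %s\n",
              x$subject_id, x$trial_id, nrow(x$PP), ncol(x$PP),
              if (is.null(x$PA)) "PP only" else "PP/PV/PA"))
  invisible(x)
}

#' Differentiate principal positions to velocities and accelerations
#'
#' Central differences scaled by the sampling rate (one-sided at the
#' endpoints) applied once for `PV_k` and again for `PA_k`.
#'
#' @param pm a `pm_timeseries` with `PP` filled and a known sampling rate.
#' @return the `pm_timeseries` with `PV` and `PA` filled.
#' @export
differentiate <- function(pm) {
  if (is.null(pm$PP) || nrow(pm$PP) < 3L) stop("PP with T >= 3 required")
  if (!isTRUE(pm$sampling_rate > 0)) stop("sampling_rate must be set")
  pm$PV <- diff_cols(pm$PP, pm$sampling_rate)
  pm$PA <- diff_cols(pm$PV, pm$sampling_rate)
  pm
}

diff_cols <- function(X, fs) {
  Tn <- nrow(X)
  D <- matrix(0, Tn, ncol(X))
  D[2:(Tn - 1L), ] <- (X[3:Tn, , drop = FALSE] -
                         X[1:(Tn - 2L), , drop = FALSE]) * fs / 2
  D[1L, ] <- (X[2L, ] - X[1L, ]) * fs
  D[Tn, ] <- (X[Tn, ] - X[Tn - 1L, ]) * fs
  D
}

#' Reconstruct the marker motion of a single principal movement
#'
#' Builds the coordinate stream a stick-figure animation would consume:
#' `mean_posture + amplification * pp_track(t) * PC_k'`, with the stored
#' preprocessing scalars inverted (multiply by `d_norm`, divide each column
#' by its mass weight) so the result lives in the original marker coordinate
#' units. Amplification exaggerates the excursion about the mean posture to
#' make small components visible.
#'
#' @param space a [fit_posture_space] result.
#' @param k component index.
#' @param pp_track numeric score sequence (e.g. a column of a projection's
#'   `PP`, or a synthetic sweep).
#' @param amplification positive scalar.
#' @param ref optional `preprocessed_trial` supplying `mean_posture`,
#'   `norm_factor` and `weights` from its stored provenance.
#' @param mean_posture length-N vector added after de-normalization
#'   (default: `ref$center_offset`, else 0).
#' @param norm_factor,weights override the inversion scalars explicitly.
#' @param sampling_rate frames/second of the output.
#' @return a [marker_dataset] of the reconstructed motion.
#' @export
reconstruct_pm <- function(space, k, pp_track, amplification = 1,
                           ref = NULL, mean_posture = NULL,
                           norm_factor = NULL, weights = NULL,
                           sampling_rate = NULL) {
  if (k > ncol(space$components)) stop("component ", k, " not in space")
  if (!isTRUE(amplification > 0)) stop("amplification must be positive")
  if (!is.null(ref)) {
    mean_posture <- mean_posture %||% ref$center_offset
    norm_factor <- norm_factor %||% ref$norm_factor
    weights <- weights %||% ref$weights
    sampling_rate <- sampling_rate %||% ref$sampling_rate
  }
  if (is.null(norm_factor)) {
    if (!is.null(space$fingerprint) &&
        !grepl("norm=none", space$fingerprint, fixed = TRUE))
      stop("space was fit on normalized data but no norm_factor/ref supplied; ",
           "cannot invert preprocessing")
    norm_factor <- 1
  }
  N <- nrow(space$components)
  M <- amplification * as.numeric(pp_track) %o% space$components[, k] *
    norm_factor
  if (!is.null(weights)) {
    if (any(weights == 0 & abs(space$components[, k]) > 1e-12))
      stop("cannot de-weight: zero mass weight on a column the component uses")
    pos <- weights > 0
    M[, pos] <- sweep(M[, pos, drop = FALSE], 2L, weights[pos], `/`)
  }
  M <- sweep(M, 2L, mean_posture %||% rep(0, N), `+`)
  labs <- space$marker_labels %||% sprintf("m%02d", seq_len(N / 3L))
  marker_dataset(M, labs, sampling_rate %||% 1,
                 subject_id = "reconstruction",
                 trial_id = sprintf("PM%d_x%g", k, amplification))
}
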