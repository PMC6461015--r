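# Basis-stability and filtering diagnostics: leave-one-out eigenvector
# angles, Welch power spectral density, cutoff-frequency sweep.

#' Leave-one-out stability angles of the posture-space basis
#'
#' For each trial x: refit the posture space on all trials except x and
#' measure, per component, the angle (degrees) between the full-cohort
#' eigenvector `PC_k` and the refitted `PC'_k`. Angles use the absolute
#' inner product, so they are sign-invariant and lie in [0, 90]. Small
#' angles mean the component is not driven by any single trial and may be
#' interpreted cohort-wide (the PM-inclusion criterion).
#'
#' @param trials list of `preprocessed_trial` objects (at least 3).
#' @param K number of components to assess (default: all with positive
#'   eigenvalue in the full fit).
#' @param match `"order"` pairs components by rank index k; `"best"` pairs
#'   each full-fit component with the left-out component of maximum absolute
#'   dot product (useful for near-degenerate spectra).
#' @param threshold optional inclusion threshold in degrees; adds a
#'   `max_angle <= threshold` flag per component. No default is asserted.
#' @return A `loocv_report`: data.frame `angles` (left_out, component,
#'   angle_deg), data.frame `summary` (component, max_angle, mean_angle and,
#'   if `threshold` given, `include`), and the full-fit `space`.
#' @export
loocv_angles <- function(trials, K = NULL, match = c("order", "best"),
                         threshold = NULL) {
  match <- match.arg(match)
  if (length(trials) < 3L) stop("leave-one-out needs at least 3 trials")
  full <- fit_posture_space(assemble(trials))
  K <- K %||% sum(full$all_eigenvalues > 1e-12 * full$all_eigenvalues[1L])
  K <- min(K, ncol(full$components))
  PC <- full$components[, seq_len(K), drop = FALSE]
  rows <- lapply(seq_along(trials), function(x) {
    sub <- fit_posture_space(assemble(trials[-x]))
    PCs <- sub$components
    ang <- vapply(seq_len(K), function(k) {
      j <- if (match == "order") k else
        which.max(abs(crossprod(PC[, k], PCs)))
      if (j > ncol(PCs)) return(90)
      subspace_angle_deg(PC[, k], PCs[, j])
    }, numeric(1L))
    data.frame(left_out = x, component = seq_len(K), angle_deg = ang)
  })
  angles <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(seq_len(K), function(k) {
    a <- angles$angle_deg[angles$component == k]
    data.frame(component = k, max_angle = max(a), mean_angle = mean(a))
  }))
  if (!is.null(threshold)) summ$include <- summ$max_angle <= threshold
  structure(list(angles = angles, summary = summ, space = full,
                 match = match, threshold = threshold),
            class = "loocv_report")
}

#' Angle between two unit vectors, sign-invariant, in degrees
#' @param u,v numeric vectors of equal length.
#' @export
subspace_angle_deg <- function(u, v) {
  d <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, d)) * 180 / pi
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("loocv_report: %d trials left out, %d components (match by %s)\n",
              length(unique(x$angles$left_out)), nrow(x$summary), x$match))
  print(x$summary)
  invisible(x)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the series is split into overlapping
#' segments, each mean-detrended, windowed and Fourier transformed; the
#' one-sided power densities are averaged. Useful for choosing a low-pass
#' cutoff frequency (power above the cutoff should be negligible).
#'
#' @param x numeric vector, matrix (one series per column), or a
#'   [marker_dataset] / `pm_timeseries` (its `PP`).
#' @param fs sampling rate in Hz (taken from the object when available).
#' @param segment_length samples per segment; default `min(256, floor(T/4))`.
#' @param overlap fractional segment overlap, default 0.5.
#' @param window `"hann"` or `"rectangular"`.
#' @return data.frame with `frequency` (Hz) and one `power` column per input
#'   column (units^2/Hz) plus `mean_power` for matrix input. The integral of
#'   the density over frequency approximates the series variance.
#' @export
welch_psd <- function(x, fs = NULL, segment_length = NULL, overlap = 0.5,
                      window = c("hann", "rectangular")) {
  window <- match.arg(window)
  if (inherits(x, "marker_dataset")) { fs <- fs %||% x$sampling_rate; x <- x$data }
  if (inherits(x, "pm_timeseries")) { fs <- fs %||% x$sampling_rate; x <- x$PP }
  if (is.null(fs)) stop("fs required")
  X <- as.matrix(x)
  Tn <- nrow(X)
  L <- segment_length %||% min(256L, floor(Tn / 4))
  if (L > Tn) stop("segment_length (", L, ") exceeds series length (", Tn, ")")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, Tn - L + 1L, by = step)
  win <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
         else rep(1, L)
  U <- fs * sum(win^2)
  nf <- floor(L / 2) + 1L
  P <- matrix(0, nf, ncol(X))
  for (s in starts) {
    seg <- X[s:(s + L - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg)) * win
    ft <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    p <- (Mod(ft)^2) / U
    # one-sided: double everything except DC (and Nyquist for even L)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    P <- P + p * dbl
  }
  P <- P / length(starts)
  out <- data.frame(frequency = (seq_len(nf) - 1L) * fs / L)
  cn <- colnames(X) %||% sprintf("s%d", seq_len(ncol(X)))
  for (j in seq_len(ncol(P))) out[[paste0("power.", cn[j])]] <- P[, j]
  if (ncol(P) > 1L) out$mean_power <- rowMeans(P)
  out
}

#' Run the full analysis pipeline on a cohort
#'
#' Preprocesses every trial (see [preprocess_trial]), assembles the pooled
#' matrix, fits the posture space, projects and differentiates each trial,
#' and computes the per-trial variable table.
#'
#' @param trials list of [marker_dataset] objects.
#' @param config a [preprocess_config].
#' @param K components to retain (default all).
#' @param m residual-variance order.
#' @return list with `space`, `pm` (list of `pm_timeseries`), `variables`
#'   (cohort-level long data.frame) and the preprocessed `trials`.
#' @export
pm_analyze <- function(trials, config = preprocess_config(), K = NULL, m = NULL) {
  prep <- lapply(trials, preprocess_trial, config = config)
  space <- fit_posture_space(assemble(prep), K = K)
  pm <- lapply(prep, function(tr) differentiate(project(tr, space)))
  vars <- do.call(rbind, lapply(pm, trial_variable_table, m = m))
  list(space = space, pm = pm, variables = vars, trials = prep)
}

#' Re-run the pipeline over a vector of filter cutoff frequencies
#'
#' For each cutoff the full pipeline is executed and its result tables are
#' written to a separate, cutoff-labelled folder; a combined long table of
#' every requested variable versus cutoff supports stability inspection
#' (statistical conclusions should not hinge on the cutoff choice).
#'
#' @param trials list of [marker_dataset] objects.
#' @param config a [preprocess_config]; its `filter_cutoff` is overridden.
#' @param cutoffs numeric vector of cutoff frequencies in Hz, all below the
#'   Nyquist frequency of every trial.
#' @param out_dir output directory (`NULL` to skip writing).
#' @param variables variable names to collect into the combined table.
#' @inheritParams pm_analyze
#' @return data.frame: `cutoff_hz` + the per-trial variable rows, invisibly
#'   carrying the per-cutoff results in attribute `"runs"`.
#' @export
cutoff_sweep <- function(trials, config, cutoffs, out_dir = NULL,
                         variables = c("rVAR", "rSTD", "N", "sigma"),
                         K = NULL, m = NULL) {
  nyq <- min(vapply(trials, `[[`, numeric(1L), "sampling_rate")) / 2
  if (any(cutoffs >= nyq))
    stop("cutoff(s) at or above Nyquist (", nyq, " Hz)")
  runs <- list()
  combined <- list()
  for (co in cutoffs) {
    cfg <- config
    cfg$filter_cutoff <- co
    res <- pm_analyze(trials, cfg, K = K, m = m)
    runs[[as.character(co)]] <- res
    tab <- res$variables
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, sprintf("cutoff_%gHz", co))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_table(tab, file.path(d, "variables.csv"))
      write_table(data.frame(component = seq_along(res$space$all_rel_eigenvalues),
                             EV = res$space$all_eigenvalues,
                             rEV = res$space$all_rel_eigenvalues),
                  file.path(d, "eigenvalues.csv"))
    }
    keep <- tab[tab$variable %in% variables, , drop = FALSE]
    combined[[as.character(co)]] <- cbind(cutoff_hz = co, keep)
  }
  out <- do.call(rbind, combined)
  rownames(out) <- NULL
  if (!is.null(out_dir))
    write_table(out, file.path(out_dir, "variables_vs_cutoff.csv"))
  attr(out, "runs") <- runs
  out
}
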