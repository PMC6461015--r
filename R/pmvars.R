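# Per-trial variable family on principal-movement time-series:
# movement structure (rVAR, rSTD, cumulative and residual variants) and
# movement control (acceleration zero-crossings and their timing
# variability), plus generic descriptors.

#' Trial-specific movement structure
#'
#' From a trial's principal-position scores: `VAR_k` = variance of `PP_k(t)`
#' (divisor `n - 1`, matching the posture-space eigenvalue convention, so for
#' a single-trial cohort `rVAR_k == rEV_k` exactly), `totVAR` = sum over all
#' K computed components, `rVAR_k = VAR_k / totVAR * 100`,
#' `rSTD_k = SD_k / sum(SD) * 100`, running-sum cumulative variants, and the
#' residual variance `RV_m = 100 - CUM_rVAR_m` left unexplained by the first
#' `m` components. When K < N the percentages are relative to the retained
#' subspace.
#'
#' @param pm a `pm_timeseries` with `PP` filled.
#' @param m order for the residual variance (default `min(3, K)`).
#' @return A `trial_metrics` list: per-component data.frame `structure`
#'   (VAR, rVAR, rSTD, CUM_rVAR, CUM_rSTD), scalars `totVAR`, `m`, `RV_m`,
#'   and the trial identity.
#' @export
movement_structure <- function(pm, m = NULL) {
  PP <- pm$PP
  K <- ncol(PP)
  m <- m %||% min(3L, K)
  if (m > K) stop("m (", m, ") exceeds number of components (", K, ")")
  VAR <- apply(PP, 2L, stats::var)
  totVAR <- sum(VAR)
  if (totVAR <= 0) stop("degenerate trial: total PP variance is 0")
  SD <- sqrt(VAR)
  rVAR <- VAR / totVAR * 100
  rSTD <- SD / sum(SD) * 100
  structure(list(
    subject_id = pm$subject_id, trial_id = pm$trial_id,
    structure = data.frame(
      component = seq_len(K), VAR = VAR, rVAR = rVAR, rSTD = rSTD,
      CUM_rVAR = cumsum(rVAR), CUM_rSTD = cumsum(rSTD)),
    totVAR = totVAR, m = m, RV_m = 100 - cumsum(rVAR)[m]
  ), class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("trial_metrics: subject %s trial %s | totVAR %.6g | RV_%d = %.3f%%\n",
              x$subject_id, x$trial_id, x$totVAR, x$m, x$RV_m))
  print(utils::head(x$structure, 6L))
  invisible(x)
}

#' Movement-control metrics from principal accelerations
#'
#' `N_k` counts the sign changes of `PA_k(t)` — each one a reversal of the
#' direction in which the net (gravitational + neuromuscular) action drives
#' the component. A run of exact zeros counts as a single crossing only when
#' the flanking signs differ. `sigma_k` is the sample standard deviation (in
#' seconds) of the intervals between successive crossing times; crossing
#' times are located by linear interpolation between the bracketing non-zero
#' samples (set `interpolate = FALSE` for integer frame indices). With fewer
#' than 3 crossings `sigma_k` is reported as `NA` with a warning.
#'
#' @param pm a `pm_timeseries` with `PA` filled (see [differentiate]).
#' @param k component indices (default all).
#' @param interpolate locate crossing times by linear interpolation.
#' @return data.frame with columns `component`, `N`, `sigma`.
#' @export
control_metrics <- function(pm, k = NULL, interpolate = TRUE) {
  if (is.null(pm$PA)) stop("PA required; call differentiate() first")
  k <- k %||% seq_len(ncol(pm$PA))
  fs <- pm$sampling_rate
  out <- lapply(k, function(kk) {
    zc <- zero_crossings(pm$PA[, kk], fs, interpolate)
    sigma <- if (zc$n >= 3L) stats::sd(diff(zc$times)) else {
      warning("component ", kk, ": fewer than 3 crossings, sigma undefined")
      NA_real_
    }
    data.frame(component = kk, N = zc$n, sigma = sigma)
  })
  do.call(rbind, out)
}

# strict sign changes with zero-run collapsing; returns count and times (s)
zero_crossings <- function(x, fs, interpolate = TRUE) {
  nz <- which(x != 0)
  if (length(nz) < 2L) return(list(n = 0L, times = numeric(0)))
  s <- sign(x[nz])
  flips <- which(s[-1L] != s[-length(s)])
  times <- vapply(flips, function(f) {
    i <- nz[f]; j <- nz[f + 1L]
    if (interpolate) (i - 1 + (j - i) * x[i] / (x[i] - x[j])) / fs
    else (j - 1) / fs
  }, numeric(1L))
  list(n = length(flips), times = times)
}

#' Generic descriptors of PM time-series
#'
#' RMS, mean and standard deviation per component for each requested series.
#'
#' @param pm a `pm_timeseries`.
#' @param series subset of `c("PP", "PV", "PA")` present in `pm`.
#' @return long data.frame: `series`, `component`, `RMS`, `mean`, `SD`.
#' @export
summary_stats <- function(pm, series = c("PP", "PV", "PA")) {
  series <- intersect(series, c("PP", "PV", "PA"))
  out <- lapply(series, function(s) {
    X <- pm[[s]]
    if (is.null(X)) return(NULL)
    data.frame(series = s, component = seq_len(ncol(X)),
               RMS = sqrt(colMeans(X^2)),
               mean = colMeans(X),
               SD = apply(X, 2L, stats::sd))
  })
  do.call(rbind, out)
}

#' Full per-trial variable table
#'
#' Combines [movement_structure], [control_metrics] and [summary_stats] into
#' one long-format data.frame `(subject, trial, component, variable, value)`
#' suitable for a cohort-level export.
#'
#' @param pm a `pm_timeseries` with `PP`, `PV`, `PA` filled.
#' @param m residual-variance order (see [movement_structure]).
#' @inheritParams control_metrics
#' @return long data.frame of all variables.
#' @export
trial_variable_table <- function(pm, m = NULL, interpolate = TRUE) {
  ms <- movement_structure(pm, m)
  st <- ms$structure
  long <- function(df, vars) {
    do.call(rbind, lapply(vars, function(v)
      data.frame(component = df$component, variable = v, value = df[[v]])))
  }
  rows <- long(st, c("VAR", "rVAR", "rSTD", "CUM_rVAR", "CUM_rSTD"))
  rows <- rbind(rows,
                data.frame(component = NA_integer_,
                           variable = c("totVAR", sprintf("RV_%d", ms$m)),
                           value = c(ms$totVAR, ms$RV_m)))
  cm <- suppressWarnings(control_metrics(pm, interpolate = interpolate))
  rows <- rbind(rows,
                data.frame(component = cm$component, variable = "N",
                           value = cm$N),
                data.frame(component = cm$component, variable = "sigma",
                           value = cm$sigma))
  ss <- summary_stats(pm)
  for (v in c("RMS", "mean", "SD"))
    rows <- rbind(rows, data.frame(component = ss$component,
                                   variable = paste(v, ss$series, sep = "_"),
                                   value = ss[[v]]))
  cbind(subject_id = pm$subject_id, trial_id = pm$trial_id, rows)
}
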