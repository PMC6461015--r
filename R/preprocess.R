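# Per-trial preprocessing: gap filling, mirroring, coordinate transforms,
# filtering, centering, weighting, normalization, center-of-mass re-centering.
#
# Pipeline order is fixed: gap_fill -> mirror -> com_recenter ->
# transform_coordinates -> lowpass_filter -> center_weight_normalize.
# Geometric steps act on raw coordinates; statistical steps act last.

#' Preprocessing configuration
#'
#' Collects the optional per-trial transformation steps and their parameters.
#' Steps set to `NULL`/`FALSE` are skipped. See [preprocess_trial] for the
#' fixed application order.
#'
#' @param do_gapfill fill gaps by iterated low-rank reconstruction.
#' @param gapfill_rank rank for gap filling; `NULL` = smallest rank explaining
#'   99\% of the interpolated matrix variance.
#' @param mirror_axis `NULL` or one of "x","y","z": negate this coordinate and
#'   swap left/right marker columns.
#' @param swap_map named character vector of left -> right marker label pairs.
#' @param com_recenter subtract the mass-weighted mean marker position per
#'   frame (requires `weighting`).
#' @param coord_system `NULL`, "spherical" or "cylindrical".
#' @param coord_origin length-3 origin for the transform, or "centroid".
#' @param filter_cutoff low-pass cutoff in Hz, or `NULL` for no filtering.
#' @param filter_order Butterworth order of one pass (default 4; 2 is also
#'   common since the zero-phase application doubles the effective order).
#' @param weighting a [build_mass_model] object, or `NULL`.
#' @param normalization "none", "MED", "height" or "range". MED divides by the
#'   mean Euclidean norm of the centered (and weighted) posture rows; height
#'   divides by the subject's stature; range by the largest per-column
#'   peak-to-peak excursion along `range_axis`.
#' @param height subject stature in the data's length units (scalar, or a
#'   named vector keyed by subject id) — required for height normalization.
#' @param range_axis "x", "y", "z" or "all" for range normalization.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(do_gapfill = FALSE, gapfill_rank = NULL,
                              mirror_axis = NULL, swap_map = NULL,
                              com_recenter = FALSE,
                              coord_system = NULL, coord_origin = c(0, 0, 0),
                              filter_cutoff = NULL, filter_order = 4L,
                              weighting = NULL,
                              normalization = c("none", "MED", "height", "range"),
                              height = NULL, range_axis = "all") {
  normalization <- match.arg(normalization)
  if (normalization == "height" && is.null(height))
    stop("height normalization requires a positive height")
  if (!is.null(coord_system))
    coord_system <- match.arg(coord_system, c("spherical", "cylindrical"))
  structure(list(
    do_gapfill = isTRUE(do_gapfill), gapfill_rank = gapfill_rank,
    mirror_axis = mirror_axis, swap_map = swap_map,
    com_recenter = isTRUE(com_recenter),
    coord_system = coord_system, coord_origin = coord_origin,
    filter_cutoff = filter_cutoff, filter_order = as.integer(filter_order),
    weighting = weighting, normalization = normalization,
    height = height, range_axis = range_axis
  ), class = "preprocess_config")
}

#' Fill marker gaps by iterated low-rank reconstruction
#'
#' Missing cells are initialized by linear interpolation along time (edge gaps
#' by the nearest observed value), then refined by repeating
#' \{center columns, SVD, rebuild with the top `rank` components, overwrite
#' only the missing cells\} until the relative change of the filled values
#' drops below `tol` or `max_iter` is reached. Observed cells are never
#' modified.
#'
#' @param trial a [marker_dataset] with gaps flagged in `missing_mask`.
#' @param rank number of components used in the reconstruction; `NULL` picks
#'   the smallest rank explaining 99\% of the interpolated matrix variance.
#' @param tol relative convergence tolerance on the filled cells.
#' @param max_iter iteration cap; non-convergence warns and returns the best
#'   iterate.
#' @return the trial with gaps filled and `missing_mask` cleared.
#' @export
gap_fill <- function(trial, rank = NULL, tol = 1e-6, max_iter = 100L) {
  mask <- trial$missing_mask
  if (!any(mask)) return(trial)
  if (any(colSums(!mask) == 0L))
    stop("unrecoverable gap: column(s) ",
         paste(which(colSums(!mask) == 0L), collapse = ", "),
         " have no observed samples")
  M <- trial$data
  Tn <- nrow(M)
  for (j in which(colSums(mask) > 0L)) {
    obs <- which(!mask[, j])
    M[, j] <- stats::approx(obs, M[obs, j], xout = seq_len(Tn),
                            rule = 2)$y
  }
  if (is.null(rank)) {
    sv <- svd(scale(M, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
    cum <- cumsum(sv^2) / sum(sv^2)
    rank <- which(cum >= 0.99)[1L]
  }
  rank <- min(rank, min(Tn, ncol(M)) - 1L)
  prev <- M[mask]
  for (it in seq_len(max_iter)) {
    mu <- colMeans(M)
    C <- sweep(M, 2L, mu)
    sv <- svd(C, nu = rank, nv = rank)
    R <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    R <- sweep(R, 2L, mu, `+`)
    M[mask] <- R[mask]
    delta <- sqrt(sum((M[mask] - prev)^2)) /
      max(sqrt(sum(prev^2)), .Machine$double.eps)
    prev <- M[mask]
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("gap_fill did not converge in ", max_iter,
            " iterations (relative change ", signif(delta, 3), ")")
  trial$data <- M
  trial$missing_mask[] <- FALSE
  validate_marker_dataset(trial)
}

#' Mirror a trial across a plane
#'
#' Negates the chosen coordinate axis for all markers and exchanges the
#' column triplets of left/right marker pairs, turning e.g. a left-foot-front
#' stance into its right-foot-front mirror image so both can share one
#' posture space. Applying the same mirror twice is the identity.
#'
#' @param trial a [marker_dataset].
#' @param axis "x", "y" or "z": the coordinate negated (normal of the mirror
#'   plane).
#' @param swap_map named character vector, `c(left_label = "right_label")`;
#'   each pair listed once. Unpaired markers keep their columns.
#' @return the mirrored [marker_dataset].
#' @export
mirror_trial <- function(trial, axis = c("x", "y", "z"), swap_map = NULL) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  n <- length(trial$marker_labels)
  M <- trial$data
  M[, seq(ai, by = 3L, length.out = n)] <-
    -M[, seq(ai, by = 3L, length.out = n)]
  perm <- seq_len(3L * n)
  if (length(swap_map)) {
    left <- names(swap_map); right <- unname(swap_map)
    miss <- setdiff(c(left, right), trial$marker_labels)
    if (length(miss))
      stop("swap_map labels not in marker_labels: ", paste(miss, collapse = ", "))
    for (i in seq_along(left)) {
      a <- match(left[i], trial$marker_labels)
      b <- match(right[i], trial$marker_labels)
      ca <- (3L * (a - 1L)) + 1:3; cb <- (3L * (b - 1L)) + 1:3
      perm[ca] <- cb; perm[cb] <- ca
    }
  }
  trial$data <- M[, perm, drop = FALSE]
  trial$missing_mask <- trial$missing_mask[, perm, drop = FALSE]
  trial
}

#' Transform marker coordinates to spherical or cylindrical systems
#'
#' Replaces each marker's `(x, y, z)` relative to `origin` by
#' `(r, azimuth, elevation)` (spherical) or `(rho, azimuth, z)` (cylindrical).
#' Azimuth is measured in the x-y plane from +x in `(-pi, pi]` and unwrapped
#' along time per marker so no 2*pi branch-cut jumps reach the PCA; elevation
#' is measured from the x-y plane in `[-pi/2, pi/2]`.
#'
#' @param trial a gap-free [marker_dataset].
#' @param system "spherical" or "cylindrical".
#' @param origin length-3 point, or "centroid" for the per-frame marker
#'   centroid (centroid transforms are not invertible by
#'   [inverse_transform_coordinates]).
#' @param eps degeneracy threshold on the (cylindrical) radius.
#' @return the transformed [marker_dataset]; the convention is recorded in
#'   fields `coord_system` and `coord_origin` so the transform can be
#'   inverted.
#' @export
transform_coordinates <- function(trial, system = c("spherical", "cylindrical"),
                                  origin = c(0, 0, 0), eps = 1e-9) {
  system <- match.arg(system)
  if (any(trial$missing_mask)) stop("fill gaps before transforming coordinates")
  n <- length(trial$marker_labels)
  M <- trial$data
  out <- M
  centroid <- NULL
  if (identical(origin, "centroid")) {
    xs <- M[, seq(1L, by = 3L, length.out = n), drop = FALSE]
    ys <- M[, seq(2L, by = 3L, length.out = n), drop = FALSE]
    zs <- M[, seq(3L, by = 3L, length.out = n), drop = FALSE]
    centroid <- cbind(rowMeans(xs), rowMeans(ys), rowMeans(zs))
  }
  for (j in seq_len(n)) {
    cols <- (3L * (j - 1L)) + 1:3
    P <- M[, cols, drop = FALSE]
    P <- if (is.null(centroid)) sweep(P, 2L, origin) else P - centroid
    rho <- sqrt(P[, 1L]^2 + P[, 2L]^2)
    r <- sqrt(rho^2 + P[, 3L]^2)
    rad <- if (system == "spherical") r else rho
    if (any(rad < eps))
      stop("degenerate radius (< ", eps, ") at frame ", which(rad < eps)[1L],
           " for marker ", trial$marker_labels[j])
    az <- unwrap_angle(atan2(P[, 2L], P[, 1L]))
    out[, cols] <- if (system == "spherical") {
      cbind(r, az, asin(P[, 3L] / r))
    } else {
      cbind(rho, az, P[, 3L])
    }
  }
  trial$data <- out
  trial$coord_system <- system
  trial$coord_origin <- origin
  trial$units <- paste0(trial$units, "+rad")
  trial
}

#' Invert a spherical/cylindrical coordinate transform
#'
#' @param trial output of [transform_coordinates] with a fixed origin.
#' @return the Cartesian [marker_dataset].
#' @export
inverse_transform_coordinates <- function(trial) {
  system <- trial$coord_system
  if (is.null(system)) stop("trial carries no coordinate-transform provenance")
  if (identical(trial$coord_origin, "centroid"))
    stop("per-frame centroid transforms are not invertible")
  origin <- trial$coord_origin
  n <- length(trial$marker_labels)
  M <- trial$data
  out <- M
  for (j in seq_len(n)) {
    cols <- (3L * (j - 1L)) + 1:3
    if (system == "spherical") {
      r <- M[, cols[1L]]; az <- M[, cols[2L]]; el <- M[, cols[3L]]
      out[, cols] <- cbind(r * cos(el) * cos(az) + origin[1L],
                           r * cos(el) * sin(az) + origin[2L],
                           r * sin(el) + origin[3L])
    } else {
      rho <- M[, cols[1L]]; az <- M[, cols[2L]]; z <- M[, cols[3L]]
      out[, cols] <- cbind(rho * cos(az) + origin[1L],
                           rho * sin(az) + origin[2L],
                           z + origin[3L])
    }
  }
  trial$data <- out
  trial$coord_system <- NULL
  trial$coord_origin <- NULL
  trial$units <- sub("\\+rad$", "", trial$units)
  trial
}

# remove 2*pi jumps between consecutive samples
unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}

#' Zero-phase Butterworth low-pass filter a trial
#'
#' Column-wise forward-backward filtering (see [filtfilt_cols]); zero phase
#' lag and unit DC gain. Gaps must be filled first.
#'
#' @param trial a gap-free [marker_dataset].
#' @param cutoff cutoff frequency in Hz, below Nyquist.
#' @param order Butterworth order of one pass.
#' @return the filtered [marker_dataset].
#' @export
lowpass_filter <- function(trial, cutoff, order = 4L) {
  if (any(trial$missing_mask))
    stop("trial has unfilled gaps; run gap_fill first")
  ba <- butter_lowpass(order, cutoff, trial$sampling_rate)
  trial$data <- filtfilt_cols(trial$data, ba$b, ba$a)
  trial
}

#' Center a trial on its mass-weighted mean position
#'
#' Per frame, subtracts the mass-weighted mean marker position from every
#' marker, removing whole-body displacement so it is not represented as a
#' movement component.
#'
#' @param trial a [marker_dataset].
#' @param mass a [build_mass_model] object with positive total weight.
#' @return the re-centered [marker_dataset].
#' @export
com_recenter <- function(trial, mass) {
  w <- mass$per_marker_mass[trial$marker_labels]
  if (anyNA(w)) stop("mass model lacks weights for some markers")
  tw <- sum(w)
  if (tw <= 0) stop("total mass weight must be positive")
  n <- length(trial$marker_labels)
  M <- trial$data
  for (ai in 1:3) {
    idx <- seq(ai, by = 3L, length.out = n)
    com <- as.vector(M[, idx, drop = FALSE] %*% w) / tw
    M[, idx] <- M[, idx, drop = FALSE] - com
  }
  trial$data <- M
  trial
}

#' Center, weight and normalize a trial
#'
#' The statistical tail of the preprocessing chain, applied in order:
#' (1) subtract each column's mean (stored as `center_offset`);
#' (2) multiply column i by its mass weight `w_i` when weighting is set;
#' (3) compute the normalization factor `d_norm` on the centered + weighted
#' matrix and divide the whole matrix by it. MED uses the mean over frames of
#' the Euclidean norm of the posture row vectors, so every trial contributes
#' mean posture-vector norm 1 to the pooled analysis; height uses the
#' subject's stature; range the largest per-column peak-to-peak excursion.
#'
#' @param trial a gap-free [marker_dataset].
#' @param config a [preprocess_config] (only `weighting`, `normalization`,
#'   `height`, `range_axis` are consulted here).
#' @return A `preprocessed_trial`: fields `matrix` (T x N), `center_offset`,
#'   `norm_factor`, `weights`, plus identity/provenance carried from the
#'   trial.
#' @export
center_weight_normalize <- function(trial, config = preprocess_config()) {
  if (any(trial$missing_mask)) stop("trial has unfilled gaps")
  M <- trial$data
  mu <- colMeans(M)
  M <- sweep(M, 2L, mu)
  w <- NULL
  if (!is.null(config$weighting)) {
    w <- config$weighting$column_weights
    if (length(w) != ncol(M))
      stop("mass model has ", length(w), " column weights, data has ", ncol(M))
    M <- sweep(M, 2L, w, `*`)
  }
  d <- switch(config$normalization,
    none = 1,
    MED = mean(sqrt(rowSums(M^2))),
    height = {
      h <- config$height
      h <- if (!is.null(names(h))) h[[trial$subject_id]] else h
      if (is.null(h) || !isTRUE(h > 0))
        stop("positive height required for subject ", trial$subject_id)
      h
    },
    range = {
      n <- length(trial$marker_labels)
      cols <- if (config$range_axis == "all") seq_len(ncol(M)) else
        seq(match(config$range_axis, c("x", "y", "z")), by = 3L,
            length.out = n)
      max(apply(M[, cols, drop = FALSE], 2L, function(v) diff(range(v))))
    })
  if (!isTRUE(d > 0))
    stop("degenerate trial: normalization factor is ", d,
         " (motionless trial under ", config$normalization, "?)")
  structure(list(
    subject_id = trial$subject_id,
    trial_id = trial$trial_id,
    sampling_rate = trial$sampling_rate,
    marker_labels = trial$marker_labels,
    matrix = M / d,
    center_offset = mu,
    norm_factor = d,
    weights = w,
    normalization = config$normalization,
    provenance = attr(trial, "provenance")
  ), class = "preprocessed_trial")
}

#' @export
print.preprocessed_trial <- function(x, ...) {
  cat(sprintf("preprocessed_trial: subject %s trial %s | %d x %d | %s d_norm=%.6g\n",
              x$subject_id, x$trial_id, nrow(x$matrix), ncol(x$matrix),
              x$normalization, x$norm_factor))
  invisible(x)
}

#' Run the full per-trial preprocessing chain
#'
#' Applies, in this fixed order, each step enabled in `config`:
#' gap filling, mirroring, center-of-mass re-centering, coordinate transform,
#' low-pass filtering, then centering/weighting/normalization. Each applied
#' step is echoed into the provenance of the result.
#'
#' @param trial a [marker_dataset].
#' @param config a [preprocess_config].
#' @return a `preprocessed_trial` (see [center_weight_normalize]).
#' @export
preprocess_trial <- function(trial, config = preprocess_config()) {
  prov <- list()
  if (config$do_gapfill || any(trial$missing_mask)) {
    trial <- gap_fill(trial, rank = config$gapfill_rank)
    prov <- c(prov, list(list(step = "gap_fill", rank = config$gapfill_rank)))
  }
  if (!is.null(config$mirror_axis)) {
    trial <- mirror_trial(trial, config$mirror_axis, config$swap_map)
    prov <- c(prov, list(list(step = "mirror", axis = config$mirror_axis)))
  }
  if (config$com_recenter) {
    if (is.null(config$weighting))
      stop("com_recenter requires a mass model in config$weighting")
    trial <- com_recenter(trial, config$weighting)
    prov <- c(prov, list(list(step = "com_recenter")))
  }
  if (!is.null(config$coord_system)) {
    trial <- transform_coordinates(trial, config$coord_system,
                                   config$coord_origin)
    prov <- c(prov, list(list(step = "transform", system = config$coord_system,
                              origin = config$coord_origin)))
  }
  if (!is.null(config$filter_cutoff)) {
    trial <- lowpass_filter(trial, config$filter_cutoff, config$filter_order)
    prov <- c(prov, list(list(step = "lowpass", cutoff = config$filter_cutoff,
                              order = config$filter_order)))
  }
  prov <- c(prov, list(list(step = "center_weight_normalize",
                            weighting = !is.null(config$weighting),
                            normalization = config$normalization)))
  attr(trial, "provenance") <- prov
  center_weight_normalize(trial, config)
}
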