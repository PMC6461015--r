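# Seeded generator of synthetic multi-trial marker data with planted
# orthonormal movement modes. Stands in for undeposited motion-capture
# cohorts in parameter-recovery and stability tests: the planted modes are
# the ground truth the fitted posture space should recover.

#' Sinusoidal amplitude recipe for a planted mode
#'
#' @param freq frequency in Hz.
#' @param amp peak amplitude (variance over whole periods is `amp^2 / 2`).
#' @param phase radians; `NULL` draws one uniform phase per trial.
#' @export
amp_sinusoid <- function(freq, amp = 1, phase = NULL) {
  list(type = "sinusoid", freq = freq, amp = amp, phase = phase)
}

#' Filtered-noise amplitude recipe for a planted mode
#'
#' Gaussian noise of standard deviation `sd`, optionally low-passed at
#' `cutoff` Hz (and re-scaled back to `sd`).
#'
#' @param sd target standard deviation of the amplitude series.
#' @param cutoff optional low-pass cutoff in Hz.
#' @export
amp_noise <- function(sd = 1, cutoff = NULL) {
  list(type = "noise", sd = sd, cutoff = cutoff)
}

#' Define a planted movement model
#'
#' A stated world for synthetic trials: marker rows are
#' `base_posture + sum_k a_k(t) v_k' + noise`, with mutually orthonormal
#' displacement modes `v_k`, per-mode amplitude recipes `a_k(t)`
#' ([amp_sinusoid], [amp_noise]) and isotropic Gaussian measurement noise.
#' Amplitude series are made zero-mean by construction so per-trial
#' centering is a near-no-op and recovery algebra stays clean.
#'
#' @param base_posture length-N vector of mean marker coordinates
#'   (N = 3 x markers).
#' @param modes N x K matrix of orthonormal mode columns.
#' @param amplitude_specs list of K amplitude recipes.
#' @param noise_sd isotropic additive noise standard deviation.
#' @param sampling_rate frames per second.
#' @param duration seconds per trial.
#' @param seed base seed; together with the subject/trial ids it makes every
#'   generated trial bit-reproducible.
#' @param marker_labels optional labels (default `m01..`).
#' @return A `planted_model` list.
#' @export
planted_model <- function(base_posture, modes, amplitude_specs, noise_sd = 0,
                          sampling_rate = 100, duration = 10, seed = 1L,
                          marker_labels = NULL) {
  modes <- as.matrix(modes)
  if (length(base_posture) != nrow(modes))
    stop("base_posture length must match mode rows")
  if (length(base_posture) %% 3L != 0L) stop("N must be a multiple of 3")
  G <- crossprod(modes)
  if (max(abs(G - diag(ncol(modes)))) > 1e-10)
    stop("modes are not orthonormal (max Gram deviation ",
         signif(max(abs(G - diag(ncol(modes)))), 3), ")")
  if (length(amplitude_specs) != ncol(modes))
    stop("need one amplitude spec per mode")
  structure(list(
    base_posture = as.numeric(base_posture), modes = modes,
    amplitude_specs = amplitude_specs, noise_sd = noise_sd,
    sampling_rate = sampling_rate, duration = duration, seed = as.integer(seed),
    marker_labels = marker_labels %||%
      sprintf("m%02d", seq_len(length(base_posture) / 3L))
  ), class = "planted_model")
}

# deterministic 31-bit sub-seed from the model seed and identity strings
trial_seed <- function(seed, subject_id, trial_id) {
  h <- sum(utf8ToInt(paste(subject_id, trial_id, sep = "/")) *
             seq_along(utf8ToInt(paste(subject_id, trial_id, sep = "/"))))
  (as.integer(seed) * 7919L + as.integer(h %% 262143)) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate one synthetic trial from a planted model
#'
#' @param model a [planted_model].
#' @param subject_id,trial_id identity tags; they also key the trial's
#'   random substream, so the same (model, subject, trial) always yields the
#'   identical matrix.
#' @return a [marker_dataset].
#' @export
generate_trial <- function(model, subject_id = "S1", trial_id = "T1") {
  Tn <- round(model$duration * model$sampling_rate)
  t <- (seq_len(Tn) - 1L) / model$sampling_rate
  N <- length(model$base_posture)
  with_seed(trial_seed(model$seed, subject_id, trial_id), {
    A <- vapply(model$amplitude_specs, function(sp) {
      a <- switch(sp$type,
        sinusoid = {
          ph <- sp$phase %||% stats::runif(1L, 0, 2 * pi)
          sp$amp * sin(2 * pi * sp$freq * t + ph)
        },
        noise = {
          v <- stats::rnorm(Tn, sd = sp$sd)
          if (!is.null(sp$cutoff)) {
            ba <- butter_lowpass(4L, sp$cutoff, model$sampling_rate)
            v <- filtfilt_cols(matrix(v), ba$b, ba$a)[, 1L]
            v <- v * sp$sd / stats::sd(v)
          }
          v
        },
        stop("unknown amplitude spec type: ", sp$type))
      a - mean(a)
    }, numeric(Tn))
    M <- matrix(model$base_posture, Tn, N, byrow = TRUE) +
      A %*% t(model$modes)
    if (model$noise_sd > 0)
      M <- M + matrix(stats::rnorm(Tn * N, sd = model$noise_sd), Tn, N)
    marker_dataset(M, model$marker_labels, model$sampling_rate,
                   subject_id = subject_id, trial_id = trial_id)
  })
}

#' Generate a single-marker circular-arc trial
#'
#' One marker sweeping a circular arc in the x-y plane at constant radius
#' and angular velocity — the canonical case where polar-type coordinate
#' transforms concentrate the variance into a single component.
#'
#' @param radius arc radius (length units).
#' @param arc_degrees swept angle, < 360.
#' @param frames number of frames.
#' @param origin arc center (length 3; the z offset is constant).
#' @param sampling_rate frames per second.
#' @return a [marker_dataset] with one marker.
#' @export
generate_arc_trial <- function(radius = 1, arc_degrees = 120, frames = 500L,
                               origin = c(0, 0, 0), sampling_rate = 100) {
  if (arc_degrees >= 360) stop("arc_degrees must be < 360")
  th <- seq(0, arc_degrees * pi / 180, length.out = frames)
  M <- cbind(origin[1L] + radius * cos(th),
             origin[2L] + radius * sin(th),
             origin[3L] + 0)
  marker_dataset(M, "arc", sampling_rate, subject_id = "synthetic",
                 trial_id = sprintf("arc%g", arc_degrees))
}

#' Generate a trial with planted gaps
#'
#' [generate_trial] output with `missing_mask` set over requested windows;
#' the pre-gap values stay in `data` as ground truth for gap-filling tests
#' (accessible via attribute `"truth"`, while the returned data has the
#' masked cells set to `NA`).
#'
#' @param model a [planted_model].
#' @param gap_spec list of `list(marker =, start =, length =, axes =)`;
#'   `axes` defaults to all three of the marker's columns.
#' @param subject_id,trial_id identity tags.
#' @return a [marker_dataset] with gaps; attribute `"truth"` holds the
#'   complete matrix.
#' @export
generate_gappy_trial <- function(model, gap_spec = list(),
                                 subject_id = "S1", trial_id = "T1") {
  tr <- generate_trial(model, subject_id, trial_id)
  truth <- tr$data
  for (g in gap_spec) {
    j <- if (is.character(g$marker)) match(g$marker, tr$marker_labels)
         else g$marker
    if (is.na(j) || j > length(tr$marker_labels))
      stop("gap_spec marker not found: ", g$marker)
    axes <- g$axes %||% 1:3
    rows <- g$start:(g$start + g$length - 1L)
    if (max(rows) > nrow(tr$data)) stop("gap exceeds trial length")
    cols <- 3L * (j - 1L) + axes
    tr$missing_mask[rows, cols] <- TRUE
  }
  if (any(colSums(!tr$missing_mask) == 0L))
    stop("gap_spec leaves a fully-missing column")
  tr$data[tr$missing_mask] <- NA_real_
  attr(tr, "truth") <- truth
  validate_marker_dataset(tr)
}

#' Random orthonormal displacement modes
#'
#' QR-orthonormalized Gaussian matrix; deterministic given the seed.
#'
#' @param N posture-vector length (3 x markers).
#' @param K number of modes.
#' @param seed RNG seed.
#' @return N x K matrix with orthonormal columns.
#' @export
random_orthonormal_modes <- function(N, K, seed = 1L) {
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(N * K), N, K)))
    # deterministic sign
    for (k in seq_len(K)) if (Q[which.max(abs(Q[, k])), k] < 0)
      Q[, k] <- -Q[, k]
    Q
  })
}

#' Default 28-marker humanoid scaffold
#'
#' A bilaterally symmetric static posture (units mm, subject standing along
#' +z, anteroposterior +x, left +y) used as the base posture of synthetic
#' cohorts, mirroring the reduced symmetric marker sets common in balance
#' studies. Columns are `(x, y, z)` per marker.
#'
#' @return list with `posture` (length 84), `labels` (28), `swap_map`
#'   (left -> right label pairs) and `mass_spec` (marker -> body-mass
#'   fraction, de Leva-style segment fractions split over the segment's
#'   markers; editable, not a normative table).
#' @export
humanoid_layout <- function() {
  # label, x, y (left +), z
  def <- rbind(
    c("LFHD",   60,  60, 1700), c("RFHD",   60, -60, 1700),
    c("LBHD",  -60,  60, 1700), c("RBHD",  -60, -60, 1700),
    c("LSHO",    0, 200, 1450), c("RSHO",    0, -200, 1450),
    c("LELB",    0, 250, 1150), c("RELB",    0, -250, 1150),
    c("LWRA",   20, 270,  900), c("RWRA",   20, -270,  900),
    c("LFIN",   40, 280,  800), c("RFIN",   40, -280,  800),
    c("LASI",   80, 120, 1000), c("RASI",   80, -120, 1000),
    c("LPSI",  -80,  60, 1000), c("RPSI",  -80,  -60, 1000),
    c("LTHI",   30, 150,  750), c("RTHI",   30, -150,  750),
    c("LKNE",    0, 120,  500), c("RKNE",    0, -120,  500),
    c("LTIB",   20, 110,  300), c("RTIB",   20, -110,  300),
    c("LANK",    0, 110,   80), c("RANK",    0, -110,   80),
    c("LHEE",  -60, 110,   30), c("RHEE",  -60, -110,   30),
    c("LTOE",  120, 110,   20), c("RTOE",  120, -110,   20))
  labels <- def[, 1L]
  posture <- as.numeric(t(matrix(as.numeric(def[, 2:4]), ncol = 3L)))
  left <- labels[startsWith(labels, "L")]
  swap <- stats::setNames(sub("^L", "R", left), left)
  # per-segment fractions split evenly over that segment's markers
  seg <- list(head = c("LFHD", "RFHD", "LBHD", "RBHD"),
              trunk = c("LSHO", "RSHO", "LASI", "RASI", "LPSI", "RPSI"),
              upperarm = c("LELB", "RELB"),
              forearm_hand = c("LWRA", "RWRA", "LFIN", "RFIN"),
              thigh = c("LTHI", "RTHI", "LKNE", "RKNE"),
              shank = c("LTIB", "RTIB", "LANK", "RANK"),
              foot = c("LHEE", "RHEE", "LTOE", "RTOE"))
  frac <- c(head = 0.0694, trunk = 0.4346, upperarm = 2 * 0.0271,
            forearm_hand = 2 * (0.0162 + 0.0061), thigh = 2 * 0.1416,
            shank = 2 * 0.0433, foot = 2 * 0.0137)
  mass <- numeric(0)
  for (s in names(seg))
    mass <- c(mass, stats::setNames(rep(frac[[s]] / length(seg[[s]]),
                                        length(seg[[s]])), seg[[s]]))
  list(posture = posture, labels = labels, swap_map = swap,
       mass_spec = mass[labels])
}
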