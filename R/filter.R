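# Zero-phase Butterworth low-pass filtering.
#
# Digital Butterworth design by bilinear transform of the analog prototype,
# applied forward and backward (filtfilt) with odd-reflection padding and
# steady-state initial conditions, so the net filter has zero phase lag and
# squared magnitude response.

#' Digital Butterworth low-pass coefficients
#'
#' @param order filter order (of the one-pass filter; the zero-phase
#'   application doubles the effective attenuation).
#' @param cutoff cutoff frequency in Hz (-3 dB point of one pass).
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` polynomial
#'   coefficients in z^-1.
#' @export
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff >= fs / 2) stop("cutoff (", cutoff, " Hz) must be below Nyquist (",
                             fs / 2, " Hz)")
  if (order < 1) stop("order must be >= 1")
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs * tan(pi * cutoff / fs)   # pre-warped analog cutoff
  p <- warped * p
  gain <- warped^order
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(prod(1 / (fs2 - p)))
  a <- Re(poly_from_roots(pz))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a)
}

# monic polynomial coefficients from complex roots (descending powers)
poly_from_roots <- function(r) {
  c <- 1 + 0i
  for (ri in r) c <- c(c, 0) - c(0, ri * c)
  c
}

# steady-state state vector of the direct-form-II-transposed filter for a
# unit step input; scaled by the first sample before filtering so transients
# at the signal edges are suppressed
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  comp <- rbind(-a[-1L] / a[1L], cbind(diag(1, n - 1L), 0))
  IminusA <- diag(n) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

# single-pass IIR filter on the columns of X with initial state zi (per unit
# of the first row value); time loop is over frames, vectorized over columns
lfilter_cols <- function(b, a, X, zi) {
  n <- length(a) - 1L
  Tn <- nrow(X); nc <- ncol(X)
  Y <- matrix(0, Tn, nc)
  z <- zi %o% X[1L, ]          # n x nc state
  for (t in seq_len(Tn)) {
    xt <- X[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (n > 1L) {
      z[seq_len(n - 1L), ] <- z[-1L, , drop = FALSE] +
        outer(b[2L:n], xt) - outer(a[2L:n], yt)
    }
    z[n, ] <- b[n + 1L] * xt - a[n + 1L] * yt
    Y[t, ] <- yt
  }
  Y
}

#' Zero-phase filtering of matrix columns
#'
#' Forward-backward application of an IIR filter with odd-reflection padding
#' at both ends (pad length `3 * (max(length(a), length(b)) - 1)`).
#'
#' @param X numeric matrix, one series per column.
#' @param b,a filter coefficients, e.g. from [butter_lowpass].
#' @return filtered matrix, same shape as `X`.
#' @export
filtfilt_cols <- function(X, b, a) {
  X <- as.matrix(X)
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (nrow(X) <= npad)
    stop("series too short (", nrow(X), " frames) for filter warm-up (needs > ",
         npad, ")")
  top <- 2 * matrix(X[1L, ], npad, ncol(X), byrow = TRUE) -
    X[(npad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(X[nrow(X), ], npad, ncol(X), byrow = TRUE) -
    X[(nrow(X) - 1L):(nrow(X) - npad), , drop = FALSE]
  ext <- rbind(top, X, bot)
  zi <- lfilter_zi(b, a)
  Y <- lfilter_cols(b, a, ext, zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- lfilter_cols(b, a, Y, zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(npad + 1L):(npad + nrow(X)), , drop = FALSE]
}
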