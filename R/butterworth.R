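# Butterworth low-pass design and zero-phase application.
#
# The design follows the classical route: analog Butterworth prototype poles,
# frequency pre-warping, bilinear transform, then pairing of conjugate poles
# into second-order sections (biquads) for numerical stability at high order.
# Application is forward-backward (zero phase) with odd-reflection padding and
# steady-state initial conditions, the standard "filtfilt" construction.

#' Design a low-pass Butterworth filter as second-order sections
#'
#' @param order Filter order (>= 1).
#' @param cutoff Normalized cutoff as a fraction of the Nyquist frequency,
#'   in (0, 1).
#' @return A numeric matrix with one row per biquad and columns
#'   `b0, b1, b2, a0, a1, a2` (with `a0 = 1`).
#' @export
butter_lowpass_sos <- function(order, cutoff) {
  stopifnot(order >= 1, cutoff > 0, cutoff < 1)
  n <- as.integer(order)
  # analog prototype poles on the left unit semicircle
  k <- seq_len(n)
  theta <- pi * (2 * k + n - 1) / (2 * n)
  p <- complex(modulus = 1, argument = theta)
  warped <- 4 * tan(pi * cutoff / 2)       # pre-warped cutoff, fs = 2
  p <- warped * p
  gain <- warped^n
  # bilinear transform (fs = 2, so 2*fs = 4)
  fs2 <- 4
  pd <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(1 / prod(fs2 - p))
  # all n zeros map to z = -1
  # pair conjugate poles; odd order leaves one real pole
  ord <- order(abs(Im(pd)), decreasing = TRUE)
  pd <- pd[ord]
  nsec <- ceiling(n / 2)
  sos <- matrix(0, nsec, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  i <- 1L
  for (s in seq_len(nsec)) {
    if (i + 1L <= n && abs(Im(pd[i])) > 1e-12) {
      pp <- pd[i]                          # conjugate partner is implied
      a <- c(1, -2 * Re(pp), Re(pp * Conj(pp)))
      b <- c(1, 2, 1)
      i <- i + 2L
    } else {
      a <- c(1, -Re(pd[i]), 0)
      b <- c(1, 1, 0)
      i <- i + 1L
    }
    sos[s, ] <- c(b, a)
  }
  # distribute the overall gain evenly so each biquad is well-scaled
  g <- gain^(1 / nsec)
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

# One pass of a biquad cascade over a matrix (rows = time, cols = channels),
# direct form II transposed, vectorized across channels.
sosfilt_mat <- function(sos, x, zi_scale = NULL) {
  x <- as.matrix(x)
  nt <- nrow(x); nc <- ncol(x)
  for (s in seq_len(nrow(sos))) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    if (is.null(zi_scale)) {
      z1 <- numeric(nc); z2 <- numeric(nc)
    } else {
      # steady-state initial conditions for a constant input zi_scale
      g <- (b0 + b1 + b2) / (1 + a1 + a2)
      z1 <- (g - b0) * zi_scale
      z2 <- (b2 - a2 * g) * zi_scale
      zi_scale <- g * zi_scale             # next section sees the DC output
    }
    y <- x
    for (t in seq_len(nt)) {
      xt <- x[t, ]
      yt <- b0 * xt + z1
      z1 <- b1 * xt + z2 - a1 * yt
      z2 <- b2 * xt - a2 * yt
      y[t, ] <- yt
    }
    x <- y
  }
  x
}

#' Zero-phase low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase, unit DC gain, squared magnitude response). Inputs are padded
#' by odd reflection at both ends to suppress edge transients. A matrix input
#' is filtered column-wise (one column per sensor), which is how per-sensor
#' filtering of a frame stack is vectorized.
#'
#' @param trace Numeric vector, or matrix with time along rows.
#' @param cutoff_norm Normalized cutoff frequency (fraction of Nyquist).
#' @param order Filter order.
#' @return Filtered trace, same shape as the input.
#' @export
lowpass <- function(trace, cutoff_norm = 0.1, order = 8) {
  vec <- is.null(dim(trace))
  x <- as.matrix(trace)
  nt <- nrow(x)
  if (nt <= 3 * order) stop("trace too short for order-", order, " filtering")
  sos <- butter_lowpass_sos(order, cutoff_norm)
  padlen <- min(nt - 1L, 3L * (2L * nrow(sos) + 1L))
  idx_pre <- (padlen + 1L):2L
  idx_post <- (nt - 1L):(nt - padlen)
  ext <- rbind(2 * matrix(x[1L, ], padlen, ncol(x), byrow = TRUE) - x[idx_pre, , drop = FALSE],
               x,
               2 * matrix(x[nt, ], padlen, ncol(x), byrow = TRUE) - x[idx_post, , drop = FALSE])
  y <- sosfilt_mat(sos, ext, zi_scale = ext[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- sosfilt_mat(sos, y, zi_scale = y[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- y[(padlen + 1L):(padlen + nt), , drop = FALSE]
  if (vec) drop(y) else y
}
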