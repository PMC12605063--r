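# Digital IIR filter design and application.
#
# Butterworth designs follow the classic zpk route: analog lowpass prototype,
# frequency transform (lp/hp/bp/bs), bilinear transform. Frequencies are
# given as fractions of the Nyquist frequency, as in common DSP toolboxes.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth filter via the bilinear transform and
#' returns transfer-function coefficients.
#'
#' @param n Filter order (of the analog prototype; band-pass/stop designs
#'   have `2n` poles).
#' @param w Critical frequency (scalar for low/high-pass) or band edges
#'   (length 2 for band-pass/stop), as fractions of Nyquist in (0, 1).
#' @param type One of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, w, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  stop_if_not(n >= 1 && n == round(n), "filter order must be a positive integer")
  stop_if_not(all(w > 0 & w < 1), "critical frequencies must lie in (0, 1) of Nyquist")
  if (type %in% c("pass", "stop")) {
    stop_if_not(length(w) == 2 && w[1] < w[2], "band edges must be increasing, length 2")
  } else {
    stop_if_not(length(w) == 1, "low/high-pass take a single edge")
  }

  # analog lowpass prototype (unit cutoff), poles only
  k_idx <- seq_len(n)
  p <- exp(1i * pi * (2 * k_idx + n - 1) / (2 * n))
  z <- complex(0)
  k <- 1

  fs <- 2
  warped <- 2 * fs * tan(pi * w / fs)

  degree <- length(p) - length(z)
  if (type == "low") {
    p <- warped * p
    k <- k * warped^degree
  } else if (type == "high") {
    # prototype constant term prod(-p) is 1 for Butterworth, so gain is unchanged
    p <- warped / p
    z <- rep(0 + 0i, degree)
  } else {
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    if (type == "pass") {
      plp <- p * bw / 2
      p <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
      z <- rep(0 + 0i, degree)
      k <- k * bw^degree
    } else {
      php <- (bw / 2) / p
      p <- c(php + sqrt(php^2 - wo^2), php - sqrt(php^2 - wo^2))
      z <- c(rep(1i * wo, degree), rep(-1i * wo, degree))
    }
  }

  # bilinear transform, matched at fs = 2
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Direct-form IIR filter using stats::filter (C speed): FIR stage then
# the recursive stage.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else {
    v
  }
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forwards and backwards with odd-reflection edge
#' padding, cancelling group delay.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric vector.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  npad <- 3 * (max(length(a), length(b)) - 1)
  stop_if_not(n > npad, "signal too short for zero-phase filtering (need > %d samples)", npad)
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xx <- c(pre, x, post)
  y <- iir_filter(b, a, xx)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(npad + 1, npad + n)]
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Real-valued numeric vector.
#' @return Complex vector; `Mod()` of it is the amplitude envelope.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stop_if_not(n >= 2, "need at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
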