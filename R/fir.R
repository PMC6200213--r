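#' @importFrom stats fft nextn
NULL

# Odd FIR length giving a Hamming-window transition width `tw` (Hz) at rate fs.
# The 3.3/N rule is the standard Hamming main-lobe approximation.
fir_length <- function(fs, tw) {
  n <- ceiling(3.3 * fs / tw)
  n + (1 - n %% 2)  # force odd tap count (type-I linear phase)
}

#' Design a band-pass FIR filter
#'
#' Hamming windowed-sinc design (via \code{signal::fir1}) with the tap count
#' chosen from the requested transition width. The returned object is meant
#' to be applied with [filter_zerophase()], which uses the filter
#' forward-backward so the effective magnitude response is \eqn{|H(f)|^2}
#' and the phase response is exactly zero.
#'
#' @param lo,hi Band edges in Hz (use \code{lo = 0} for a low-pass).
#' @param fs Sampling rate in Hz.
#' @param transition Transition width in Hz.
#' @return An object of class \code{fir_filter}.
#' @export
fir_bandpass <- function(lo, hi, fs, transition) {
  stopifnot(hi > lo, hi < fs / 2, transition > 0)
  n_taps <- fir_length(fs, transition)
  order <- n_taps - 1L
  nyq <- fs / 2
  h <- if (lo <= 0) {
    h0 <- as.numeric(signal::fir1(order, hi / nyq, type = "low"))
    h0 / sum(h0)  # exact unit DC gain: constant signals pass unchanged
  } else {
    as.numeric(signal::fir1(order, c(lo / nyq, hi / nyq), type = "pass"))
  }
  structure(list(h = h, fs = fs, lo = lo, hi = hi, transition = transition),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("FIR band-pass %g-%g Hz @ %g Hz, %d taps (transition %g Hz)\n",
              x$lo, x$hi, x$fs, length(x$h), x$transition))
  invisible(x)
}

# FFT length with small prime factors, at least n.
fft_length <- function(n) nextn(n, c(2L, 3L, 5L))

# Reflect-pad x by m samples on each side (m < length(x) required).
reflect_pad <- function(x, m) {
  n <- length(x)
  if (m >= n) stop("signal too short for filter edge padding (need length > ",
                   m, ", got ", n, ")")
  if (m == 0) return(x)
  c(x[(m + 1):2], x, x[(n - 1):(n - m)])
}

# Frequency response |H|^2 of taps h on an nf-point grid (zero-phase
# effective response of forward-backward application).
zp_response <- function(h, nf) Mod(fft(c(h, numeric(nf - length(h)))))^2

#' Zero-phase FIR filtering
#'
#' Applies a linear-phase FIR filter forward and backward, implemented in the
#' frequency domain: the spectrum of the (reflect-padded) signal is multiplied
#' by \eqn{|H(f)|^2}, which is real, so the output has exactly zero phase
#' shift at every frequency. Equivalent to \code{filtfilt} for FIR filters but
#' O(n log n) regardless of tap count.
#'
#' @param x Numeric signal.
#' @param filt A \code{fir_filter} from [fir_bandpass()].
#' @return Filtered signal, same length as \code{x}.
#' @export
filter_zerophase <- function(x, filt) {
  filterbank_apply(x, list(filt))[[1]]
}

# Apply several zero-phase filters to one signal with a single forward FFT.
# `analytic = TRUE` additionally applies the analytic-signal mask so the
# returned series are complex analytic band signals (Mod() = Hilbert
# envelope). Padding uses the longest kernel.
filterbank_apply <- function(x, filters, analytic = FALSE) {
  n <- length(x)
  m <- max(vapply(filters, function(f) length(f$h), integer(1)))
  xp <- reflect_pad(x, m)
  np <- length(xp)
  nf <- fft_length(np + m)
  X <- fft(c(xp, numeric(nf - np)))
  mask <- 1
  if (analytic) {
    mask <- numeric(nf)
    half <- nf %/% 2
    mask[1] <- 1
    mask[2:half] <- 2
    if (nf %% 2 == 0) mask[half + 1] <- 1 else mask[half + 1] <- 2
    # indices > Nyquist stay 0
  }
  lapply(filters, function(f) {
    G <- zp_response(f$h, nf)
    y <- fft(X * G * mask, inverse = TRUE) / nf
    y <- y[(m + 1):(m + n)]
    if (analytic) y else Re(y)
  })
}

# Analytic signal via FFT (no padding); x must be real.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  mask <- numeric(n)
  half <- n %/% 2
  mask[1] <- 1
  if (n > 1) mask[2:half] <- 2
  if (n %% 2 == 0) mask[half + 1] <- 1 else if (n > 1) mask[half + 1] <- 2
  fft(X * mask, inverse = TRUE) / n
}

# Equivalent-noise power normaliser of the zero-phase (squared-magnitude)
# response: mean over the FFT grid of |H|^4. Dividing a channel's output mean
# square by this gives the input variance back exactly for white input.
zp_noise_power <- function(filt, nf = NULL) {
  m <- length(filt$h)
  if (is.null(nf)) nf <- fft_length(max(8192L, 4L * m))
  mean(zp_response(filt$h, nf)^2)
}

# |H(f)|^2 gain of the zero-phase response at frequencies f (Hz).
zp_gain_at <- function(filt, f) {
  m <- length(filt$h)
  k <- seq_len(m) - 1
  vapply(f, function(fi) {
    Mod(sum(filt$h * exp(-2i * pi * fi / filt$fs * k)))^2
  }, numeric(1))
}

# Rational approximation p/q of x with denominator <= max_den
# (continued fractions).
rational_approx <- function(x, max_den = 1000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = p1, q = q1)
}
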