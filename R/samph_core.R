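#' Spectral band specification
#'
#' The first S-AMPH stage splits the signal into five adjacent spectral bands
#' between the channel edge frequencies 100, 300, 700, 1750, 3900 and
#' 7250 Hz. Band 1 (100-300 Hz) corresponds to the F0 region. Filters are
#' Hamming windowed-sinc FIR band-passes whose transition width is a fixed
#' fraction (default 25%) of each band's lower edge, applied zero-phase.
#'
#' @param edges Six strictly ascending edge frequencies in Hz.
#' @param transition_frac Transition width as a fraction of the band's lower
#'   edge.
#' @return An object of class \code{spectral_band_spec}.
#' @export
spectral_band_spec <- function(edges = c(100, 300, 700, 1750, 3900, 7250),
                               transition_frac = 0.25) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0), transition_frac > 0)
  structure(list(edges = edges, transition_frac = transition_frac,
                 n_bands = length(edges) - 1L),
            class = "spectral_band_spec")
}

# Build the FIR filters of a spectral_band_spec at sampling rate fs.
spectral_filters <- function(spec, fs) {
  if (fs <= 2 * max(spec$edges))
    stop("sampling rate ", fs, " Hz too low for top spectral edge ",
         max(spec$edges), " Hz")
  lapply(seq_len(spec$n_bands), function(b) {
    lo <- spec$edges[b]; hi <- spec$edges[b + 1]
    fir_bandpass(lo, hi, fs, spec$transition_frac * lo)
  })
}

#' Spectral filterbank (S-AMPH stage 1 filtering)
#'
#' Band-pass filters a z-scored segment into the five spectral bands,
#' zero-phase, preserving signal length.
#'
#' @param segment An [audio_segment()] (z-score it first with
#'   [zscore_segment()]).
#' @param spec A [spectral_band_spec()].
#' @return List of 5 numeric band signals, with attributes \code{rate} and
#'   \code{edges}.
#' @export
spectral_filterbank <- function(segment, spec = spectral_band_spec()) {
  stopifnot(inherits(segment, "audio_segment"))
  filts <- spectral_filters(spec, segment$rate)
  max_taps <- max(vapply(filts, function(f) length(f$h), integer(1)))
  if (length(segment$samples) < 3 * max_taps)
    stop("segment too short for spectral filtering: need >= ",
         3 * max_taps, " samples (3 x filter length), got ",
         length(segment$samples))
  bands <- filterbank_apply(segment$samples, filts)
  attr(bands, "rate") <- segment$rate
  attr(bands, "edges") <- spec$edges
  bands
}

#' Hilbert envelope
#'
#' Magnitude of the analytic signal: the instantaneous amplitude of a
#' band-limited signal. Same length as the input, nonnegative everywhere.
#'
#' @param band_signal Numeric band-limited signal.
#' @return Nonnegative numeric vector.
#' @export
hilbert_envelope <- function(band_signal) {
  if (!all(is.finite(band_signal))) stop("non-finite input")
  Mod(analytic_signal(band_signal))
}

#' Downsample envelopes to the envelope rate
#'
#' Anti-alias filters (zero-phase FIR low-pass at 45% of the target Nyquist)
#' and polyphase-resamples each envelope to \code{target_rate}. Non-integer
#' rate ratios are approximated by the nearest rational with denominator
#' <= 1000. Filter ringing can produce small negative values; these are
#' clipped to 0.
#'
#' @param envelopes List (or matrix columns) of envelopes at rate \code{fs}.
#' @param fs Original sampling rate in Hz.
#' @param target_rate Envelope rate in Hz (default 1050).
#' @param edges Spectral band edges carried along as metadata.
#' @return An \code{envelope_set}: list with \code{envelopes} (matrix, one
#'   column per spectral band), \code{env_rate} and \code{edges}.
#' @export
downsample_envelopes <- function(envelopes, fs = attr(envelopes, "rate"),
                                 target_rate = 1050,
                                 edges = attr(envelopes, "edges")) {
  if (target_rate <= 2 * 40)
    stop("target_rate must exceed 80 Hz to resolve beta/low-gamma modulations")
  if (is.matrix(envelopes))
    envelopes <- lapply(seq_len(ncol(envelopes)), function(j) envelopes[, j])
  ds <- lapply(envelopes, function(e) resample_to(e, fs, target_rate))
  env <- do.call(cbind, ds)
  env[env < 0] <- 0
  envelope_set(env, target_rate, edges)
}

# Resample x from rate fs to target (fs >= target) in two stages: anti-alias
# low-pass at 45% of the target Nyquist, integer decimation by floor(fs /
# target), then a small rational polyphase stage (upsample by p, decimate by
# q, p/q from the continued-fraction approximation with denominator <= 1000)
# for the residual ratio. For integer ratios the second stage is skipped.
resample_to <- function(x, fs, target) {
  stopifnot(fs >= target)
  cutoff <- 0.45 * target
  aa <- fir_bandpass(0, cutoff, fs, 0.2 * cutoff)
  y <- filter_zerophase(x, aa)
  d <- floor(fs / target + 1e-9)
  y <- y[seq(1, length(y), by = d)]
  fs2 <- fs / d
  if (abs(fs2 - target) < 1e-9 * target) return(y)
  pq <- rational_approx(fs2 / target)     # fs2/target = q/p -> up p, down q
  q <- unname(pq["p"]); p <- unname(pq["q"])
  up <- numeric(length(y) * p)
  up[seq(1, length(up), by = p)] <- y * p
  aa2 <- fir_bandpass(0, cutoff, fs2 * p, 0.2 * cutoff)
  up <- filter_zerophase(up, aa2)
  up[seq(1, length(up), by = q)]
}

#' Construct an envelope set
#'
#' @param envelopes Numeric matrix, one column per spectral band; all values
#'   must be nonnegative.
#' @param env_rate Envelope sampling rate in Hz.
#' @param edges Spectral band edge frequencies.
#' @return An object of class \code{envelope_set}.
#' @export
envelope_set <- function(envelopes, env_rate = 1050, edges = NULL) {
  envelopes <- as.matrix(envelopes)
  stopifnot(all(envelopes >= 0), env_rate > 0)
  structure(list(envelopes = envelopes, env_rate = env_rate, edges = edges),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("envelope_set: %d bands x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$envelopes), nrow(x$envelopes), x$env_rate,
              nrow(x$envelopes) / x$env_rate))
  invisible(x)
}

#' Extract the five spectral-band envelopes of a segment
#'
#' Convenience chain: [spectral_filterbank()] then [hilbert_envelope()] per
#' band at the full rate, then [downsample_envelopes()] (matching the order
#' of operations in the S-AMPH model).
#'
#' @param segment A z-scored [audio_segment()].
#' @param spec A [spectral_band_spec()].
#' @param env_rate Target envelope rate in Hz.
#' @return An [envelope_set()].
#' @export
extract_envelopes <- function(segment, spec = spectral_band_spec(),
                              env_rate = 1050) {
  bands <- spectral_filterbank(segment, spec)
  envs <- lapply(bands, hilbert_envelope)
  attr(envs, "rate") <- segment$rate
  attr(envs, "edges") <- spec$edges
  downsample_envelopes(envs, fs = segment$rate, target_rate = env_rate)
}
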