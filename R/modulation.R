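#' Amplitude-modulation band specification
#'
#' The second S-AMPH stage isolates three amplitude-modulation rate bands in
#' each spectral envelope: delta (0.9-2.5 Hz, stressed-syllable rate), theta
#' (2.5-12 Hz, syllable rate) and beta/low-gamma (12-40 Hz, phoneme rate).
#' Transition widths are 20% of each band's lower edge with a 1 Hz floor: at
#' a 0.9 Hz edge an unfloored rule would require a filter kernel of tens of
#' seconds, which no conversational speech segment could support, while the
#' beta/low-gamma band needs a reasonably sharp 12 Hz edge to admit
#' modulation content near the bottom of the band.
#'
#' @param bands Data frame with columns \code{name, lo, hi} (Hz).
#' @param transition_frac Transition width fraction of the lower edge.
#' @param transition_floor Minimum transition width in Hz.
#' @return An object of class \code{am_band_spec}.
#' @export
am_band_spec <- function(bands = data.frame(
                           name = c("delta", "theta", "beta_low_gamma"),
                           lo = c(0.9, 2.5, 12),
                           hi = c(2.5, 12, 40)),
                         transition_frac = 0.2,
                         transition_floor = 1.0) {
  stopifnot(all(bands$hi > bands$lo), all(diff(bands$lo) > 0),
            all(bands$lo[-1] == bands$hi[-nrow(bands)]))
  structure(list(bands = bands, transition_frac = transition_frac,
                 transition_floor = transition_floor),
            class = "am_band_spec")
}

am_filters <- function(spec, fs) {
  lapply(seq_len(nrow(spec$bands)), function(b) {
    lo <- spec$bands$lo[b]; hi <- spec$bands$hi[b]
    tw <- max(spec$transition_frac * lo, spec$transition_floor)
    fir_bandpass(lo, hi, fs, tw)
  })
}

#' AM filterbank (S-AMPH stage 2)
#'
#' Decomposes each spectral-band envelope into the three band-limited,
#' mean-removed AM waveforms whose instantaneous phases feed the phase
#' synchronisation analysis.
#'
#' @param env_set An [envelope_set()].
#' @param spec An [am_band_spec()].
#' @return An \code{am_decomposition}: list with \code{waveforms} (array of
#'   dim \code{n_samples x n_spectral_bands x 3}), \code{env_rate},
#'   \code{am_names}.
#' @export
am_filterbank <- function(env_set, spec = am_band_spec()) {
  stopifnot(inherits(env_set, "envelope_set"))
  fs <- env_set$env_rate
  if (fs < 2 * max(spec$bands$hi))
    stop("envelope rate ", fs, " Hz cannot resolve modulations up to ",
         max(spec$bands$hi), " Hz")
  filts <- am_filters(spec, fs)
  max_taps <- max(vapply(filts, function(f) length(f$h), integer(1)))
  n <- nrow(env_set$envelopes)
  if (n < 3 * max_taps)
    stop("envelope too short for AM filtering: need >= ", 3 * max_taps,
         " samples (3 x delta-filter length = ",
         sprintf("%.1f s", 3 * max_taps / fs), "), got ", n)
  nb <- ncol(env_set$envelopes)
  w <- array(NA_real_, dim = c(n, nb, nrow(spec$bands)),
             dimnames = list(NULL, NULL, spec$bands$name))
  for (b in seq_len(nb)) {
    out <- filterbank_apply(env_set$envelopes[, b], filts)
    for (k in seq_along(out)) w[, b, k] <- out[[k]] - mean(out[[k]])
  }
  structure(list(waveforms = w, env_rate = fs, am_names = spec$bands$name,
                 edges = env_set$edges),
            class = "am_decomposition")
}

#' @export
print.am_decomposition <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf("am_decomposition: %d samples x %d spectral bands x %d AM bands @ %g Hz\n",
              d[1], d[2], d[3], x$env_rate))
  invisible(x)
}

# 24-channel log-spaced modulation filterbank: geometric edges over the
# range, transition width 0.35 x each channel's lower edge (keeps adjacent
# channels separable while the slowest kernel stays ~10 s).
modulation_channels <- function(fs, n_channels = 24, range = c(0.9, 40),
                                transition_frac = 0.35) {
  edges <- exp(seq(log(range[1]), log(range[2]), length.out = n_channels + 1))
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  filts <- lapply(seq_len(n_channels), function(cch) {
    fir_bandpass(edges[cch], edges[cch + 1], fs, transition_frac * edges[cch])
  })
  list(edges = edges, centers = centers, filters = filts)
}

#' Envelope modulation spectrum
#'
#' Passes each spectral-band envelope through a 24-channel FIR modulation
#' filterbank with channels logarithmically spaced over 0.9-40 Hz. Channel
#' power is the mean square of the (zero-phase) filter output after trimming
#' \code{trim} seconds per end, normalised by the filter's equivalent noise
#' power so that a flat-spectrum envelope gives equal power in every channel.
#' Per spectral band the mean power across the 24 channels is computed and
#' each channel is expressed as the relative difference from that mean,
#' \eqn{D_c = (P_c - \bar P)/\bar P} (so each band's differenced spectrum has
#' exactly zero mean and is invariant to envelope scaling). The differenced
#' spectrum is finally averaged across the five spectral bands.
#'
#' @param env_set An [envelope_set()].
#' @param n_channels Number of modulation channels (default 24).
#' @param range Modulation frequency range in Hz (default \code{c(0.9, 40)}).
#' @param mode \code{"relative"} (default, \eqn{(P_c-\bar P)/\bar P}) or
#'   \code{"difference"} (plain \eqn{P_c-\bar P}).
#' @param trim Seconds trimmed per end before computing channel power.
#' @return A \code{modulation_spectrum}: list with \code{centers} (24 Hz
#'   values), \code{power} (raw normalised channel power, channels x bands),
#'   \code{differenced} (channels x bands) and \code{averaged} (length-24
#'   cross-band mean).
#' @export
modulation_spectrum <- function(env_set, n_channels = 24, range = c(0.9, 40),
                                mode = c("relative", "difference"),
                                trim = 0.5) {
  stopifnot(inherits(env_set, "envelope_set"))
  mode <- match.arg(mode)
  fs <- env_set$env_rate
  ch <- modulation_channels(fs, n_channels, range)
  pw_norm <- vapply(ch$filters, zp_noise_power, numeric(1))
  n <- nrow(env_set$envelopes)
  nb <- ncol(env_set$envelopes)
  tr <- round(trim * fs)
  if (n - 2 * tr < 2) stop("envelope too short for modulation spectrum")
  keep <- (tr + 1):(n - tr)
  P <- matrix(NA_real_, n_channels, nb)
  for (b in seq_len(nb)) {
    e <- env_set$envelopes[, b]
    if (all(e == 0)) stop("silent envelope (all zeros) in spectral band ", b)
    out <- filterbank_apply(e, ch$filters)
    P[, b] <- vapply(seq_len(n_channels),
                     function(k) mean(out[[k]][keep]^2) / pw_norm[k],
                     numeric(1))
  }
  pbar <- colMeans(P)
  if (any(pbar == 0)) stop("zero mean modulation power in spectral band ",
                           which(pbar == 0)[1])
  D <- switch(mode,
              relative  = sweep(sweep(P, 2, pbar, "-"), 2, pbar, "/"),
              difference = sweep(P, 2, pbar, "-"))
  structure(list(centers = ch$centers, edges = ch$edges, power = P,
                 differenced = D, averaged = rowMeans(D), mode = mode,
                 env_rate = fs),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf("modulation_spectrum: %d channels (%.2f-%.1f Hz) x %d spectral bands, mode=%s\n",
              length(x$centers), min(x$centers), max(x$centers),
              ncol(x$differenced), x$mode))
  invisible(x)
}

# Trapezoidal integral of piecewise-linear y(log10 f) over [lo, hi], with
# the limits inserted by interpolation so band integrals partition exactly.
trapz_log <- function(f, y, lo, hi) {
  lx <- log10(f)
  lo <- max(lo, f[1]); hi <- min(hi, f[length(f)])
  if (hi <= lo) return(0)
  llo <- log10(lo); lhi <- log10(hi)
  inside <- lx > llo & lx < lhi
  xs <- c(llo, lx[inside], lhi)
  ys <- c(stats::approx(lx, y, llo)$y, y[inside], stats::approx(lx, y, lhi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Band energies (area under the modulation spectrum)
#'
#' Integrates the differenced modulation spectrum over log10 frequency within
#' the delta, theta and beta/low-gamma band limits, per spectral band and
#' averaged across bands. Signed area is retained so the three band AUCs sum
#' exactly to the AUC over the full modulation range.
#'
#' @param mod_spec A [modulation_spectrum()].
#' @param spec An [am_band_spec()] giving the integration limits.
#' @return A \code{band_energy}: list with \code{per_band} (3 x n_spectral
#'   matrix), \code{averaged} (named length-3 vector), \code{full_range}
#'   (scalar AUC over the whole range, cross-band average).
#' @export
band_energy <- function(mod_spec, spec = am_band_spec()) {
  stopifnot(inherits(mod_spec, "modulation_spectrum"))
  f <- mod_spec$centers
  nb <- ncol(mod_spec$differenced)
  nbands <- nrow(spec$bands)
  per_band <- matrix(NA_real_, nbands, nb,
                     dimnames = list(spec$bands$name, NULL))
  full <- numeric(nb)
  for (b in seq_len(nb)) {
    y <- mod_spec$differenced[, b]
    for (k in seq_len(nbands))
      per_band[k, b] <- trapz_log(f, y, spec$bands$lo[k], spec$bands$hi[k])
    full[b] <- trapz_log(f, y, min(spec$bands$lo), max(spec$bands$hi))
  }
  structure(list(per_band = per_band, averaged = rowMeans(per_band),
                 full_range = mean(full), full_per_band = full),
            class = "band_energy")
}

#' @export
print.band_energy <- function(x, ...) {
  cat("band_energy (AUC of differenced modulation spectrum, cross-band mean):\n")
  print(round(x$averaged, 4))
  invisible(x)
}
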