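#' Instantaneous phase of an AM waveform
#'
#' The angle of the analytic signal of a zero-mean band-limited waveform,
#' wrapped to \eqn{(-\pi, \pi]}.
#'
#' @param am_waveform Zero-mean numeric vector.
#' @return Phase in radians, same length as the input.
#' @export
instantaneous_phase <- function(am_waveform) {
  if (!all(is.finite(am_waveform))) stop("non-finite input")
  if (all(am_waveform == 0)) stop("all-zero waveform has no defined phase")
  ph <- Arg(analytic_signal(am_waveform))
  ph[ph <= -pi] <- pi  # wrap convention (-pi, pi]
  ph
}

#' n:m Phase Synchronisation Index
#'
#' \deqn{PSI = | \langle e^{i (n\theta_1 - \theta_2)} \rangle |}
#' where \eqn{\theta_1} is the instantaneous phase of the slower AM band,
#' \eqn{\theta_2} of the faster, and \eqn{n} is the integer frequency
#' multiplier relating them (2 for delta-theta, 3 for theta-beta/low-gamma).
#' Averaging the complex unit phasors makes the statistic invariant to phase
#' wrapping; the result lies in \eqn{[0, 1]}: 0 for a sound random in rhythm,
#' 1 for perfect rhythmic regularity. By default 0.5 s is trimmed from each
#' end of the series to drop band-pass filter edge transients.
#'
#' @param theta1 Phase series (radians) of the slower AM.
#' @param theta2 Phase series of the faster AM, same length.
#' @param n Integer multiplier applied to \code{theta1}.
#' @param rate Sampling rate of the phase series in Hz (default 1050).
#' @param trim Seconds trimmed per end before averaging.
#' @return PSI value in \code{[0, 1]}.
#' @export
psi <- function(theta1, theta2, n, rate = 1050, trim = 0.5) {
  stopifnot(length(theta1) == length(theta2), n >= 1)
  len <- length(theta1)
  tr <- round(trim * rate)
  if (len - 2 * tr < 2 * rate)
    stop("phase series too short: need >= 2 s after trimming (",
         sprintf("%.2f s available", (len - 2 * tr) / rate), ")")
  keep <- (tr + 1):(len - tr)
  Mod(mean(exp(1i * (n * theta1[keep] - theta2[keep]))))
}

#' Segment-level PSI
#'
#' For each spectral band, computes the delta-theta PSI (n = 2) and the
#' theta-beta/low-gamma PSI (n = 3) from the instantaneous phases of the AM
#' waveforms, then averages each pair across the five spectral bands.
#'
#' @param am An [am_filterbank()] decomposition.
#' @param n_dt,n_tbg Integer multipliers for the two band pairs.
#' @param trim Seconds trimmed per end (see [psi()]).
#' @return A \code{psi_result}: list with \code{per_band} (n_spectral x 2
#'   matrix, columns \code{psi_delta_theta}, \code{psi_theta_betagamma}) and
#'   \code{segment} (named length-2 vector of cross-band means).
#' @export
segment_psi <- function(am, n_dt = 2, n_tbg = 3, trim = 0.5) {
  stopifnot(inherits(am, "am_decomposition"))
  nb <- dim(am$waveforms)[2]
  per_band <- matrix(NA_real_, nb, 2,
                     dimnames = list(NULL, c("psi_delta_theta",
                                             "psi_theta_betagamma")))
  for (b in seq_len(nb)) {
    ph_d <- instantaneous_phase(am$waveforms[, b, 1])
    ph_t <- instantaneous_phase(am$waveforms[, b, 2])
    ph_g <- instantaneous_phase(am$waveforms[, b, 3])
    per_band[b, 1] <- psi(ph_d, ph_t, n_dt, am$env_rate, trim)
    per_band[b, 2] <- psi(ph_t, ph_g, n_tbg, am$env_rate, trim)
  }
  structure(list(per_band = per_band, segment = colMeans(per_band)),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("psi_result: delta-theta %.3f, theta-beta/low-gamma %.3f (mean over %d spectral bands)\n",
              x$segment[1], x$segment[2], nrow(x$per_band)))
  invisible(x)
}

#' Participant-level PSI (grand mean over segments)
#'
#' Unweighted arithmetic mean of segment-level PSI values (and per-band
#' values), computed separately per register by the caller.
#'
#' @param segment_results List of [segment_psi()] results (>= 1).
#' @return A \code{psi_result} with the averaged \code{per_band} matrix and
#'   \code{segment} means, plus \code{n_segments}.
#' @export
participant_psi <- function(segment_results) {
  if (length(segment_results) == 0) stop("no segments to aggregate")
  stopifnot(all(vapply(segment_results, inherits, logical(1), "psi_result")))
  pb <- Reduce(`+`, lapply(segment_results, `[[`, "per_band")) /
    length(segment_results)
  structure(list(per_band = pb, segment = colMeans(pb),
                 n_segments = length(segment_results)),
            class = "psi_result")
}
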