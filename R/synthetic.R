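#' @importFrom stats rnorm runif pnorm approx uniroot sd
NULL

# --- von Mises utilities ----------------------------------------------------

#' Expected PSI under von Mises phase jitter
#'
#' If the generalised phase difference is i.i.d. von Mises with concentration
#' \eqn{\kappa}, the population PSI is the Bessel ratio
#' \eqn{I_1(\kappa)/I_0(\kappa)}.
#'
#' @param kappa Concentration parameter (>= 0; \code{Inf} allowed).
#' @return Expected PSI in \code{[0, 1]}.
#' @export
psi_for_kappa <- function(kappa) {
  ifelse(is.infinite(kappa), 1,
         ifelse(kappa == 0, 0,
                besselI(kappa, 1, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE)))
}

#' Concentration giving a target expected PSI
#'
#' Numerical inverse of [psi_for_kappa()].
#'
#' @param rho Target PSI in \code{[0, 1)} (1 maps to \code{Inf}).
#' @return Concentration \eqn{\kappa}.
#' @export
kappa_for_psi <- function(rho) {
  vapply(rho, function(r) {
    stopifnot(r >= 0, r <= 1)
    if (r == 0) return(0)
    if (r >= 1 - 1e-12) return(Inf)
    uniroot(function(k) psi_for_kappa(k) - r, c(1e-8, 1400),
            tol = 1e-10)$root
  }, numeric(1))
}

# Quantile function of the von Mises(0, kappa) distribution on (-pi, pi],
# returned as an interpolating function built from a dense CDF grid.
vonmises_quantile <- function(kappa, n_grid = 8192) {
  if (is.infinite(kappa)) return(function(u) numeric(length(u)) )
  if (kappa == 0) return(function(u) (2 * u - 1) * pi)
  th <- seq(-pi, pi, length.out = n_grid)
  dens <- exp(kappa * (cos(th) - 1))          # scaled density, stable for large kappa
  cdf <- cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(th))
  cdf <- c(0, cdf) / cdf[n_grid - 1]
  function(u) approx(cdf, th, xout = pmin(pmax(u, 0), 1), ties = "ordered")$y
}

# Band-limited unit-variance Gaussian-like process: sum of random-phase
# sinusoids with frequencies in [f_lo, f_hi] Hz; returns a function of t.
bandlimited_noise_fun <- function(f_lo = 0.05, f_hi = 0.5, n_comp = 48) {
  f <- runif(n_comp, f_lo, f_hi)
  ph <- runif(n_comp, 0, 2 * pi)
  amp <- sqrt(2 / n_comp)
  function(t) {
    z <- numeric(length(t))
    for (k in seq_len(n_comp)) z <- z + cos(2 * pi * f[k] * t + ph[k])
    amp * z
  }
}

# Slowly varying von Mises(0, kappa) jitter series over times t: a
# band-limited Gaussian process mapped through the probability integral
# transform, so the marginal distribution is von Mises while variation stays
# below `bw` Hz (i.i.d. jitter at the envelope rate would be unfilterable
# broadband noise; speech-like desynchronisation is slow).
vonmises_jitter <- function(t, kappa, bw = 0.5) {
  if (is.infinite(kappa)) return(numeric(length(t)))
  z <- bandlimited_noise_fun(f_hi = bw)(t)
  vonmises_quantile(kappa)(pnorm(z))
}

# --- synthesis spec ---------------------------------------------------------

#' Synthetic segment specification
#'
#' Describes a speech-like signal: broadband carriers in the five spectral
#' bands, each multiplied by the product of three nested amplitude
#' modulators (delta ~2 Hz, theta ~5 Hz, beta/low-gamma ~20 Hz). The theta
#' modulator's phase is twice the delta phase plus slowly varying von Mises
#' jitter of concentration \code{kappa_dt}; the beta/low-gamma phase is three
#' times the theta phase plus von Mises jitter of concentration
#' \code{kappa_tbg}. \code{kappa = Inf} is deterministic locking, \code{0}
#' means a fully independent modulator (generated at its own nominal rate,
#' \code{f_theta} or \code{f_bg}). Under exact coupling the realised rates
#' are \code{2 f_delta} and \code{6 f_delta}: for all three modulators to
#' sit inside their AM bands, \code{f_delta} must lie in (2, 2.5) Hz, hence
#' the 2.25 Hz default with a small (+-4%) per-realisation rate jitter that
#' keeps the hierarchy off the exact filterbank edges.
#'
#' @param duration Seconds (>= 3).
#' @param rate Audio sampling rate in Hz (default 44100, must exceed 14500).
#' @param carrier \code{"noise"} (default: a constant-modulus random-phase
#'   carrier per spectral band -- band-passed Gaussian noise reduced to its
#'   phase, so the carrier has no intrinsic envelope fluctuations and the
#'   imposed modulator product is exactly the band envelope),
#'   \code{"gaussian"} (raw band-passed Gaussian noise, whose Rayleigh
#'   envelope fluctuations act as realistic measurement noise) or
#'   \code{"tones"} (one sinusoid at each band's geometric centre, for
#'   closed-form tests).
#' @param f_delta,f_theta,f_bg Nominal modulator rates in Hz.
#' @param depths 3 x 5 matrix of modulation depths in \code{[0, 1]} (rows:
#'   delta, theta, beta/low-gamma; columns: spectral bands), or a length-3
#'   vector recycled across bands.
#' @param kappa_dt,kappa_tbg von Mises concentrations of the two couplings.
#' @param rate_jitter Relative jitter applied to the modulator rates.
#' @param jitter_bw Bandwidth (Hz) of the phase-jitter process.
#' @param edges Spectral band edges for the carriers.
#' @param seed Integer seed; identical seed + spec give identical waveforms.
#' @return An object of class \code{synth_spec}.
#' @export
synth_spec <- function(duration = 15, rate = 44100,
                       carrier = c("noise", "gaussian", "tones"),
                       f_delta = 2.25, f_theta = 5, f_bg = 20,
                       depths = c(0.3, 0.25, 0.25),
                       kappa_dt = 4, kappa_tbg = 4,
                       rate_jitter = 0.04, jitter_bw = 0.5,
                       edges = c(100, 300, 700, 1750, 3900, 7250),
                       seed = NULL) {
  carrier <- match.arg(carrier)
  if (is.vector(depths)) depths <- matrix(depths, 3, length(edges) - 1)
  stopifnot(duration >= 3, all(depths >= 0 & depths <= 1),
            kappa_dt >= 0, kappa_tbg >= 0, nrow(depths) == 3)
  structure(list(duration = duration, rate = rate, carrier = carrier,
                 f_delta = f_delta, f_theta = f_theta, f_bg = f_bg,
                 depths = depths, kappa_dt = kappa_dt, kappa_tbg = kappa_tbg,
                 rate_jitter = rate_jitter, jitter_bw = jitter_bw,
                 edges = edges, seed = seed),
            class = "synth_spec")
}

#' Generate the three nested modulators
#'
#' Draws realised modulator rates, constructs the delta phase ramp, couples
#' the theta phase to twice the delta phase (plus von Mises jitter) and the
#' beta/low-gamma phase to three times the theta phase (plus jitter).
#' With \code{kappa = 0} the faster modulator is generated independently
#' (its own rate and slow phase wander) rather than jitter-coupled.
#' Modulator waveforms are \eqn{1 + \cos(\phi)} scaled later by the
#' band-specific depths, hence nonnegative.
#'
#' Uses the current RNG state; seed via \code{set.seed()} or [synth_segment()].
#'
#' @param spec A [synth_spec()].
#' @param at_rate Sampling rate of the returned series (default: envelope
#'   rate 1050; the audio synthesiser asks for the audio rate).
#' @return List with \code{phase} (n x 3 matrix: delta, theta, beta/low-gamma
#'   unwrapped phases), \code{rates} (realised modulator rates) and
#'   \code{t} (time axis in seconds).
#' @export
make_modulators <- function(spec, at_rate = 1050) {
  n <- round(spec$duration * at_rate)
  t <- (seq_len(n) - 1) / at_rate
  jit <- function(f) f * (1 + runif(1, -spec$rate_jitter, spec$rate_jitter))
  fd <- jit(spec$f_delta)
  phi_d <- 2 * pi * fd * t + runif(1, 0, 2 * pi)

  # jitter processes evaluated on a coarse grid, then interpolated (they are
  # band-limited below jitter_bw, so this is exact up to linear interpolation)
  tg <- seq(0, spec$duration, by = 1 / (20 * spec$jitter_bw))
  interp <- function(vg) approx(tg, vg, xout = t, rule = 2)$y

  if (spec$kappa_dt == 0) {
    ft <- jit(spec$f_theta)
    wander <- bandlimited_noise_fun(f_hi = spec$jitter_bw)(tg) * (pi / 2)
    phi_t <- 2 * pi * ft * t + runif(1, 0, 2 * pi) + interp(wander)
    ft_real <- ft
  } else {
    eps <- vonmises_jitter(tg, spec$kappa_dt, spec$jitter_bw)
    phi_t <- 2 * phi_d + interp(eps)
    ft_real <- 2 * fd
  }
  if (spec$kappa_tbg == 0) {
    fg <- jit(spec$f_bg)
    wander <- bandlimited_noise_fun(f_hi = spec$jitter_bw)(tg) * (pi / 2)
    phi_g <- 2 * pi * fg * t + runif(1, 0, 2 * pi) + interp(wander)
    fg_real <- fg
  } else {
    eps <- vonmises_jitter(tg, spec$kappa_tbg, spec$jitter_bw)
    phi_g <- 3 * phi_t + interp(eps)
    fg_real <- 3 * ft_real
  }
  list(phase = cbind(delta = phi_d, theta = phi_t, beta_low_gamma = phi_g),
       rates = c(delta = fd, theta = ft_real, beta_low_gamma = fg_real),
       t = t)
}

#' Synthesise one speech-like audio segment with known AM structure
#'
#' Per spectral band, a carrier (band-passed Gaussian noise, or a tone at the
#' band centre) is multiplied by the product of the three modulator
#' waveforms \eqn{1 + d \cos\phi} with band-specific depths \eqn{d}; the five
#' bands are summed. The ground truth (true phases at the envelope rate,
#' realised rates, concentrations, depths, and the PSI of the true phases) is
#' returned alongside the audio.
#'
#' @param spec A [synth_spec()].
#' @param env_rate Rate at which ground-truth phases are stored.
#' @return A list with \code{segment} (an [audio_segment()]) and
#'   \code{truth} (list: \code{phase}, \code{rates}, \code{kappa_dt},
#'   \code{kappa_tbg}, \code{depths}, \code{true_psi_dt},
#'   \code{true_psi_tbg}).
#' @export
synth_segment <- function(spec, env_rate = 1050) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  fs <- spec$rate
  n <- round(spec$duration * fs)
  mods <- make_modulators(spec, at_rate = fs)
  nb <- length(spec$edges) - 1
  sfilts <- spectral_filters(spectral_band_spec(spec$edges), fs)
  centers <- sqrt(spec$edges[-1] * spec$edges[-length(spec$edges)])
  t <- mods$t
  x <- numeric(n)
  cosph <- cos(mods$phase)  # n x 3
  for (b in seq_len(nb)) {
    carrier <- switch(
      spec$carrier,
      noise = cos(Arg(analytic_signal(
        filter_zerophase(rnorm(n), sfilts[[b]])))),
      gaussian = filter_zerophase(rnorm(n), sfilts[[b]]),
      tones = cos(2 * pi * centers[b] * t + runif(1, 0, 2 * pi)))
    m <- (1 + spec$depths[1, b] * cosph[, 1]) *
         (1 + spec$depths[2, b] * cosph[, 2]) *
         (1 + spec$depths[3, b] * cosph[, 3])
    x <- x + carrier * m
  }
  seg <- audio_segment(x, fs)

  dec <- round(fs / env_rate)
  idx <- seq(1, n, by = dec)
  ph_env <- mods$phase[idx, , drop = FALSE]
  er <- fs / dec
  truth <- list(
    phase = ph_env, env_rate = er, rates = mods$rates,
    kappa_dt = spec$kappa_dt, kappa_tbg = spec$kappa_tbg,
    depths = spec$depths,
    true_psi_dt = psi(ph_env[, 1], ph_env[, 2], 2, rate = er),
    true_psi_tbg = psi(ph_env[, 2], ph_env[, 3], 3, rate = er))
  list(segment = seg, truth = truth)
}

# --- cohorts ----------------------------------------------------------------

#' Cohort specification for the synthetic generator
#'
#' Defaults reproduce the study conditions: 15 illiterate, 19 low-literate
#' and 12 high-literate participants; 89/107/90 conversational segments per
#' group (286 in total, mean 6.2 per participant) and 6 rhythmic segments per
#' participant. Group-level coupling is prescribed as target mean PSI per
#' band pair (converted internally to von Mises concentrations): the
#' illiterate group has lower conversational coupling, while rhythmic-speech
#' coupling is high and equal for all groups. Behavioural score
#' distributions follow the published cohort means and standard deviations.
#'
#' @param n Named integer vector of group sizes.
#' @param conversational_segments Total conversational segments per group
#'   (distributed as evenly as possible across participants).
#' @param rhythmic_segments Rhythmic segments per participant.
#' @param psi_dt,psi_tbg Named lists with \code{conversational} and
#'   \code{rhythmic} group-mean target PSI vectors (one value per group).
#' @param psi_sd Between-participant SD of the target PSI.
#' @param speech_rate_mean Named list of group mean speech rates
#'   (syllables/s) per register.
#' @param speech_rate_sd SD of participant speech rate.
#' @param duration_range Conversational segment duration range (s).
#' @param rhythmic_duration Rhythmic segment duration (s).
#' @param rate Audio sampling rate in Hz.
#' @param seed Integer seed for the whole cohort.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(
    n = c(illiterate = 15, low_literate = 19, high_literate = 12),
    conversational_segments = c(illiterate = 89, low_literate = 107,
                                high_literate = 90),
    rhythmic_segments = 6,
    psi_dt = list(conversational = c(illiterate = 0.45, low_literate = 0.56,
                                     high_literate = 0.58),
                  rhythmic = c(illiterate = 0.72, low_literate = 0.72,
                               high_literate = 0.72)),
    psi_tbg = list(conversational = c(illiterate = 0.40, low_literate = 0.44,
                                      high_literate = 0.50),
                   rhythmic = c(illiterate = 0.68, low_literate = 0.68,
                                high_literate = 0.68)),
    psi_sd = 0.04,
    speech_rate_mean = list(conversational = c(illiterate = 3.2,
                                               low_literate = 3.4,
                                               high_literate = 4.2),
                            rhythmic = c(illiterate = 3.0, low_literate = 3.0,
                                         high_literate = 3.0)),
    speech_rate_sd = 0.35,
    duration_range = c(12, 20),
    rhythmic_duration = 12,
    rate = 44100,
    seed = 1L) {
  stopifnot(all(n > 0), psi_sd >= 0, length(n) == 3)
  structure(list(n = n, conversational_segments = conversational_segments,
                 rhythmic_segments = rhythmic_segments,
                 psi_dt = psi_dt, psi_tbg = psi_tbg, psi_sd = psi_sd,
                 speech_rate_mean = speech_rate_mean,
                 speech_rate_sd = speech_rate_sd,
                 duration_range = duration_range,
                 rhythmic_duration = rhythmic_duration,
                 rate = rate, seed = seed),
            class = "cohort_spec")
}

# Published cohort behavioural distributions: mean (sd) per group, used as
# generator defaults. Columns: illiterate, low_literate, high_literate.
behavioural_defaults <- list(
  age               = list(mean = c(80.4, 77.9, 79.7), sd = c(4.4, 5.7, 6.3), max = Inf),
  years_literacy    = list(mean = c(0, 3.3, 15.5),     sd = c(0, 0.75, 2.47), max = Inf),
  syllabic_division = list(mean = c(11, 19.7, 23.8),   sd = c(3.4, 4.3, 0.5), max = 24),
  rhyme_detection   = list(mean = c(12.8, 16.1, 21),   sd = c(3.2, 3.8, 3.1), max = 24),
  phoneme_deletion  = list(mean = c(0, 22.6, 30.1),    sd = c(0, 6, 2.4),     max = 32),
  vocabulary        = list(mean = c(9.7, 26.5, 54.8),  sd = c(3.6, 11.5, 5.7), max = Inf),
  token_test        = list(mean = c(11.8, 16.6, 19.5), sd = c(3, 2.7, 1.7),   max = 22)
)

draw_behavioural <- function(group_idx) {
  out <- lapply(behavioural_defaults, function(d) {
    v <- rnorm(1, d$mean[group_idx], d$sd[group_idx])
    min(max(v, 0), d$max)
  })
  as.data.frame(out)
}

# Distribute `total` segments as evenly as possible over n participants.
split_segments <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  c(rep(base + 1, extra), rep(base, n - extra))
}

# Draw per-participant coupling targets and convert to concentrations.
draw_participant_kappa <- function(spec, gi, register) {
  tr <- function(x) min(max(x, 0.05), 0.92)
  rho_dt <- tr(rnorm(1, spec$psi_dt[[register]][gi], spec$psi_sd))
  rho_tbg <- tr(rnorm(1, spec$psi_tbg[[register]][gi], spec$psi_sd))
  c(kappa_dt = kappa_for_psi(rho_dt), kappa_tbg = kappa_for_psi(rho_tbg),
    rho_dt = rho_dt, rho_tbg = rho_tbg)
}

#' Generate a synthetic cohort dataset on disk
#'
#' Produces WAV files, a manifest CSV in the [load_manifest()] dialect and a
#' ground-truth CSV (per segment: true concentrations, target PSI, realised
#' modulator rates, true-phase PSI). Reproducible from (spec, seed) alone.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param audio If \code{FALSE}, write only the manifest and ground truth
#'   (audio paths are still listed; useful for manifest-level analyses).
#' @return A list with \code{manifest_path}, \code{manifest} (data frame),
#'   \code{ground_truth} (data frame).
#' @export
synth_cohort <- function(spec = cohort_spec(), dir, audio = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  set.seed(spec$seed)
  groups <- names(spec$n)
  rows <- list()
  truth_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_seg_conv <- split_segments(spec$conversational_segments[gi], spec$n[gi])
    for (p in seq_len(spec$n[gi])) {
      pid <- sprintf("%s_%02d", substr(g, 1, 4), p)
      beh <- draw_behavioural(gi)
      for (register in c("conversational", "rhythmic")) {
        kap <- draw_participant_kappa(spec, gi, register)
        sr <- max(rnorm(1, spec$speech_rate_mean[[register]][gi],
                        spec$speech_rate_sd), 0.5)
        n_seg <- if (register == "conversational") n_seg_conv[p]
                 else spec$rhythmic_segments
        for (s in seq_len(n_seg)) {
          dur <- if (register == "conversational")
            runif(1, spec$duration_range[1], spec$duration_range[2])
          else spec$rhythmic_duration
          seg_id <- sprintf("%s_%s_%02d", pid, substr(register, 1, 4), s)
          seg_seed <- sample.int(.Machine$integer.max - 1, 1)
          wav <- file.path(dir, paste0(seg_id, ".wav"))
          truth <- NULL
          if (audio) {
            sspec <- synth_spec(duration = dur, rate = spec$rate,
                                kappa_dt = kap["kappa_dt"],
                                kappa_tbg = kap["kappa_tbg"],
                                seed = seg_seed)
            res <- synth_segment(sspec)
            write_wav(res$segment$samples / max(abs(res$segment$samples)),
                      spec$rate, wav)
            truth <- res$truth
          }
          rows[[length(rows) + 1]] <- data.frame(
            participant_id = pid, group = g,
            years_literacy = beh$years_literacy, age = beh$age,
            register = register, audio_path = basename(wav),
            segment_id = seg_id,
            syllable_count = max(1L, as.integer(round(sr * dur))),
            syllabic_division = beh$syllabic_division,
            rhyme_detection = beh$rhyme_detection,
            phoneme_deletion = beh$phoneme_deletion,
            vocabulary = beh$vocabulary, token_test = beh$token_test)
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            segment_id = seg_id, participant_id = pid, group = g,
            register = register, duration = dur, seed = seg_seed,
            kappa_dt = unname(kap["kappa_dt"]),
            kappa_tbg = unname(kap["kappa_tbg"]),
            target_psi_dt = unname(kap["rho_dt"]),
            target_psi_tbg = unname(kap["rho_tbg"]),
            true_psi_dt = if (is.null(truth)) NA_real_ else truth$true_psi_dt,
            true_psi_tbg = if (is.null(truth)) NA_real_ else truth$true_psi_tbg)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  ground_truth <- do.call(rbind, truth_rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  list(manifest_path = manifest_path, manifest = manifest,
       ground_truth = ground_truth)
}

#' Simulate participant-level summaries directly
#'
#' Draws the per-participant measures (PSI pair values, speech rate,
#' behavioural scores) from the cohort spec's group distributions without
#' synthesising audio. This is the summary-level twin of [synth_cohort()]
#' used for statistical calibration, where thousands of replicate cohorts
#' are needed.
#'
#' @param spec A [cohort_spec()].
#' @param register Register to simulate.
#' @return A data frame with one row per participant.
#' @export
simulate_cohort_summaries <- function(spec = cohort_spec(),
                                      register = "conversational") {
  groups <- names(spec$n)
  out <- list()
  for (gi in seq_along(groups)) {
    for (p in seq_len(spec$n[gi])) {
      beh <- draw_behavioural(gi)
      tr <- function(x) min(max(x, 0.02), 0.98)
      out[[length(out) + 1]] <- data.frame(
        participant_id = sprintf("%s_%02d", substr(groups[gi], 1, 4), p),
        group = groups[gi], register = register,
        psi_delta_theta = tr(rnorm(1, spec$psi_dt[[register]][gi], spec$psi_sd)),
        psi_theta_betagamma = tr(rnorm(1, spec$psi_tbg[[register]][gi], spec$psi_sd)),
        speech_rate = max(rnorm(1, spec$speech_rate_mean[[register]][gi],
                                spec$speech_rate_sd), 0.5),
        beh)
    }
  }
  do.call(rbind, out)
}
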