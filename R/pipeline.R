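#' Analyse one segment through the full S-AMPH chain
#'
#' z-scoring, spectral filterbank, Hilbert envelopes, downsampling, AM
#' filterbank, modulation spectrum, band energies and segment-level PSI.
#'
#' @param segment An [audio_segment()].
#' @param spectral_spec A [spectral_band_spec()].
#' @param am_spec An [am_band_spec()].
#' @param env_rate Envelope rate in Hz.
#' @param n_channels Modulation spectrum channels.
#' @param trim Edge trim in seconds for PSI and channel power.
#' @param keep_intermediates Keep the envelope set and AM decomposition in
#'   the result (large); default drops them.
#' @return A list with \code{summary} (one-row data frame), \code{psi}
#'   (a \code{psi_result}), \code{mod_spec}, \code{energy}, and optionally
#'   \code{envelopes}, \code{am}.
#' @export
analyze_segment <- function(segment, spectral_spec = spectral_band_spec(),
                            am_spec = am_band_spec(), env_rate = 1050,
                            n_channels = 24, trim = 0.5,
                            keep_intermediates = FALSE) {
  seg <- zscore_segment(segment)
  env <- extract_envelopes(seg, spectral_spec, env_rate)
  am <- am_filterbank(env, am_spec)
  ps <- segment_psi(am, trim = trim)
  ms <- modulation_spectrum(env, n_channels = n_channels, trim = trim)
  en <- band_energy(ms, am_spec)
  summary <- data.frame(
    segment_id = segment$segment_id, participant_id = segment$participant_id,
    register = segment$register, duration = segment$duration,
    syllable_count = segment$syllable_count,
    psi_delta_theta = ps$segment["psi_delta_theta"],
    psi_theta_betagamma = ps$segment["psi_theta_betagamma"],
    delta_auc = en$averaged["delta"], theta_auc = en$averaged["theta"],
    beta_gamma_auc = en$averaged["beta_low_gamma"],
    row.names = NULL)
  for (b in seq_len(nrow(ps$per_band))) {
    summary[[paste0("psi_dt_band", b)]] <- ps$per_band[b, 1]
    summary[[paste0("psi_tbg_band", b)]] <- ps$per_band[b, 2]
  }
  out <- list(summary = summary, psi = ps, mod_spec = ms, energy = en)
  if (keep_intermediates) { out$envelopes <- env; out$am <- am }
  out
}

#' Analyse a whole cohort from its manifest
#'
#' Runs [analyze_segment()] on every manifest row, collecting per-segment
#' results and aggregating to participant level (grand mean over segments,
#' separately per register; unweighted means throughout). Per-segment
#' failures are logged and skipped.
#'
#' @param manifest A [load_manifest()] result.
#' @param ... Passed to [analyze_segment()].
#' @param audio_dir Optional directory prefixed to relative audio paths.
#' @param verbose Print progress.
#' @return List with \code{segments} (per-segment data frame),
#'   \code{participants} (per participant x register, behavioural scores
#'   joined), \code{errors} (data frame of failed segments).
#' @export
analyze_cohort <- function(manifest, ..., audio_dir = NULL, verbose = FALSE) {
  seg_rows <- list()
  errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- row$audio_path
    if (!is.null(audio_dir) && !grepl("^(/|[A-Za-z]:)", path))
      path <- file.path(audio_dir, path)
    res <- tryCatch({
      seg <- load_segment(path, row)
      analyze_segment(seg, ...)$summary
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- data.frame(
        segment_id = row$segment_id, audio_path = row$audio_path,
        message = conditionMessage(res))
      if (verbose) message("  FAILED ", row$segment_id, ": ",
                           conditionMessage(res))
    } else {
      seg_rows[[length(seg_rows) + 1]] <- res
      if (verbose) message("  ok ", row$segment_id)
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else NULL
  participants <- NULL
  if (!is.null(segments)) {
    sr <- speech_rate(segments)
    meas <- c("psi_delta_theta", "psi_theta_betagamma",
              "delta_auc", "theta_auc", "beta_gamma_auc",
              grep("^psi_(dt|tbg)_band", names(segments), value = TRUE))
    agg <- stats::aggregate(segments[, meas],
                            by = list(participant_id = segments$participant_id,
                                      register = segments$register),
                            FUN = mean)
    participants <- merge(agg, sr, by = c("participant_id", "register"))
    beh <- unique(manifest[, intersect(
      c("participant_id", "group", "years_literacy", "age",
        "syllabic_division", "rhyme_detection", "phoneme_deletion",
        "vocabulary", "token_test"), names(manifest))])
    participants <- merge(participants, beh, by = "participant_id")
  }
  list(segments = segments, participants = participants,
       errors = if (length(errors)) do.call(rbind, errors) else NULL)
}

#' Full statistical report for a participant summary table
#'
#' The cohort-level analysis: per register a MANOVA of the two PSI measures
#' by literacy group with Tukey post hocs, the mixed-design repeated-measures
#' ANOVA on per-band PSI, a speech-rate comparison (both multivariate
#' across registers and univariate), non-parametric behavioural group tests,
#' and the Spearman correlation table between behavioural scores and
#' modulation measures (conversational register).
#'
#' @param participants Participant summary data frame (from
#'   [analyze_cohort()] or [simulate_cohort_summaries()]).
#' @param alpha Significance level recorded in the report.
#' @return A list of \code{stat_report}s and tables.
#' @export
cohort_report <- function(participants, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  out <- list(alpha = alpha)
  for (reg in intersect(c("conversational", "rhythmic"),
                        unique(participants$register))) {
    p <- participants[participants$register == reg, ]
    out[[paste0("manova_psi_", reg)]] <- tryCatch(
      group_manova(p), error = function(e) conditionMessage(e))
    out[[paste0("tukey_psi_dt_", reg)]] <- tryCatch(
      posthoc_tukey(p, "psi_delta_theta"), error = function(e) conditionMessage(e))
    out[[paste0("tukey_psi_tbg_", reg)]] <- tryCatch(
      posthoc_tukey(p, "psi_theta_betagamma"), error = function(e) conditionMessage(e))
    band_cols <- grep("^psi_(dt|tbg)_band", names(p), value = TRUE)
    if (length(band_cols) == 10) {
      long <- stats::reshape(
        p[, c("participant_id", "group", band_cols)],
        varying = band_cols, v.names = "psi", timevar = "cell",
        times = band_cols, direction = "long")
      long$pair <- ifelse(grepl("_dt_", long$cell), "delta_theta",
                          "theta_betagamma")
      long$band <- sub("^.*band", "", long$cell)
      out[[paste0("rm_anova_", reg)]] <- tryCatch(
        rm_anova_psi(long), error = function(e) conditionMessage(e))
    }
    if ("speech_rate" %in% names(p))
      out[[paste0("speech_rate_anova_", reg)]] <- tryCatch({
        fit <- aov(speech_rate ~ factor(group), data = p)
        st <- summary(fit)[[1]]
        new_stat_report(paste("one-way ANOVA: speech_rate by group,", reg),
                        st[1, "F value"], c(st[1, "Df"], st[2, "Df"]),
                        st[1, "Pr(>F)"])
      }, error = function(e) conditionMessage(e))
  }
  conv <- participants[participants$register == "conversational", ]
  if (nrow(conv) > 3) {
    out$correlations <- tryCatch(
      correlation_table(conv), error = function(e) conditionMessage(e))
    for (m in c("syllabic_division", "rhyme_detection", "phoneme_deletion",
                "vocabulary", "token_test")) {
      if (m %in% names(conv))
        out[[paste0("nonparametric_", m)]] <- tryCatch(
          nonparametric_groups(conv, m), error = function(e) conditionMessage(e))
    }
    out$speech_rate_psi_pearson <- tryCatch(list(
      delta_theta = correlate(conv, "speech_rate", "psi_delta_theta",
                              method = "pearson"),
      theta_betagamma = correlate(conv, "speech_rate", "psi_theta_betagamma",
                                  method = "pearson")),
      error = function(e) conditionMessage(e))
  }
  out
}
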