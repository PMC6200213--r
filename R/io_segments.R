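#' Construct an audio segment
#'
#' The basic analysis unit: a mono, finite, real-valued signal with its
#' sampling rate and cohort metadata. The sampling rate must exceed twice the
#' top spectral band edge (7250 Hz by default) so that all five spectral
#' bands are representable.
#'
#' @param samples Numeric vector of audio samples.
#' @param rate Sampling rate in Hz.
#' @param segment_id,participant_id Identifiers (optional).
#' @param register \code{"conversational"} or \code{"rhythmic"} (optional).
#' @param syllable_count Manually counted syllables for the segment, or
#'   \code{NA} if not transcribed.
#' @param min_rate Minimum admissible sampling rate; defaults to twice the
#'   top spectral edge.
#' @return An object of class \code{audio_segment} with a \code{duration}
#'   field (seconds).
#' @export
audio_segment <- function(samples, rate, segment_id = NA_character_,
                          participant_id = NA_character_,
                          register = NA_character_,
                          syllable_count = NA_integer_,
                          min_rate = 2 * 7250) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("zero-length audio")
  if (!all(is.finite(samples))) stop("non-finite samples in audio segment")
  if (rate <= min_rate)
    stop("sampling rate ", rate, " Hz too low: need > ", min_rate,
         " Hz to represent the top spectral band")
  if (!is.na(register) && !register %in% c("conversational", "rhythmic"))
    stop("register must be 'conversational' or 'rhythmic'")
  if (!is.na(syllable_count) && syllable_count < 0)
    stop("syllable_count must be nonnegative")
  structure(
    list(samples = samples, rate = rate,
         duration = length(samples) / rate,
         segment_id = segment_id, participant_id = participant_id,
         register = register, syllable_count = syllable_count),
    class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("audio_segment '%s' (%s, %s): %.3f s @ %g Hz, %d samples\n",
              x$segment_id, x$participant_id, x$register,
              x$duration, x$rate, length(x$samples)))
  invisible(x)
}

#' Load one audio segment from a WAV file
#'
#' Stereo (or multi-channel) files are downmixed to mono by averaging
#' channels per sample. Segments shorter than 1 s are rejected (delta-rate
#' modulation content is unresolvable); segments shorter than 3 s trigger a
#' warning.
#'
#' @param path Path to a WAV file.
#' @param manifest_row Optional one-row data frame (or named list) carrying
#'   \code{segment_id}, \code{participant_id}, \code{register},
#'   \code{syllable_count}.
#' @return An [audio_segment()].
#' @export
load_segment <- function(path, manifest_row = NULL) {
  w <- read_wav(path)
  x <- if (ncol(w$samples) > 1) rowMeans(w$samples) else as.numeric(w$samples)
  g <- function(field, default) {
    if (!is.null(manifest_row) && !is.null(manifest_row[[field]]))
      manifest_row[[field]] else default
  }
  seg <- audio_segment(
    x, w$rate,
    segment_id = as.character(g("segment_id", basename(path))),
    participant_id = as.character(g("participant_id", NA_character_)),
    register = as.character(g("register", NA_character_)),
    syllable_count = as.integer(g("syllable_count", NA_integer_)))
  if (seg$duration < 1)
    stop("segment '", seg$segment_id, "' shorter than 1 s (",
         round(seg$duration, 3), " s): delta-band content unresolvable")
  if (seg$duration < 3)
    warning("segment '", seg$segment_id, "' shorter than 3 s (",
            round(seg$duration, 2), " s); modulation estimates will be poor")
  seg
}

#' Standardise a segment by z-scoring
#'
#' Removes the mean and scales to unit population standard deviation
#' (division by \eqn{\sqrt{n}}, not \eqn{\sqrt{n-1}}: the signal is a fixed
#' object being standardised, not a sample estimating a population).
#'
#' @param segment An [audio_segment()].
#' @return The segment with standardised samples (mean 0, population sd 1).
#' @export
zscore_segment <- function(segment) {
  stopifnot(inherits(segment, "audio_segment"))
  x <- segment$samples
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) stop("constant signal: cannot z-score (zero variance)")
  segment$samples <- (x - mu) / sdev
  segment
}

manifest_required_cols <- c(
  "participant_id", "group", "years_literacy", "age", "register",
  "audio_path", "syllable_count", "syllabic_division", "rhyme_detection",
  "phoneme_deletion", "vocabulary", "token_test")

manifest_groups <- c("illiterate", "low_literate", "high_literate")

#' Load and validate a cohort manifest
#'
#' The manifest is a UTF-8 CSV with a header and one row per speech segment;
#' participant attributes are repeated across that participant's rows.
#' Required columns: \code{participant_id, group, years_literacy, age,
#' register, audio_path, syllable_count} and the behavioural scores
#' \code{syllabic_division, rhyme_detection, phoneme_deletion, vocabulary,
#' token_test}. Group labels must be one of \code{illiterate},
#' \code{low_literate}, \code{high_literate}.
#'
#' @param path Path to the manifest CSV.
#' @param check_audio If \code{TRUE} (default), verify every referenced audio
#'   file exists (paths resolved relative to the manifest's directory when
#'   not absolute).
#' @return A data frame of class \code{cohort_manifest}.
#' @export
load_manifest <- function(path, check_audio = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(m) == 0) stop("manifest is empty: ", path)
  missing_cols <- setdiff(manifest_required_cols, names(m))
  if (length(missing_cols) > 0)
    stop("manifest missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(m$group), manifest_groups)
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(manifest_groups, collapse = "/"), ")")
  bad_reg <- setdiff(unique(m$register), c("conversational", "rhythmic"))
  if (length(bad_reg) > 0)
    stop("unknown register label(s): ", paste(bad_reg, collapse = ", "))
  # one group per participant
  gtab <- unique(m[, c("participant_id", "group")])
  dup <- gtab$participant_id[duplicated(gtab$participant_id)]
  if (length(dup) > 0)
    stop("participant(s) with inconsistent group labels: ",
         paste(unique(dup), collapse = ", "))
  if (!"segment_id" %in% names(m))
    m$segment_id <- paste0(m$participant_id, "_seg", seq_len(nrow(m)))
  if (check_audio) {
    p <- m$audio_path
    rel <- !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(dirname(path), p[rel])
    miss <- !file.exists(p)
    if (any(miss))
      stop("missing audio file(s): ", paste(utils::head(m$audio_path[miss], 5),
                                            collapse = ", "),
           if (sum(miss) > 5) sprintf(" (and %d more)", sum(miss) - 5) else "")
    m$audio_path <- p
  }
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

#' Summarise a cohort manifest
#'
#' Per-group participant and segment counts plus the overall mean number of
#' segments per participant, computed per register.
#'
#' @param manifest A [load_manifest()] result.
#' @param register Optionally restrict to one register.
#' @return A list with \code{per_group} (data frame), \code{n_participants},
#'   \code{n_segments} and \code{mean_segments_per_participant}.
#' @export
manifest_summary <- function(manifest, register = NULL) {
  m <- manifest
  if (!is.null(register)) m <- m[m$register == register, , drop = FALSE]
  if (nrow(m) == 0) stop("no manifest rows", if (!is.null(register))
    paste0(" for register '", register, "'") else "")
  per_group <- do.call(rbind, lapply(manifest_groups, function(g) {
    sub <- m[m$group == g, , drop = FALSE]
    data.frame(group = g,
               n_participants = length(unique(sub$participant_id)),
               n_segments = nrow(sub))
  }))
  list(per_group = per_group,
       n_participants = length(unique(m$participant_id)),
       n_segments = nrow(m),
       mean_segments_per_participant =
         nrow(m) / length(unique(m$participant_id)))
}
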