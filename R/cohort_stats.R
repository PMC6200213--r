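#' @importFrom stats manova aov TukeyHSD cor.test kruskal.test wilcox.test
#'   shapiro.test p.adjust complete.cases pf
NULL

new_stat_report <- function(test, statistic, df, p_value, effect = NULL,
                            pairwise = NULL, details = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, effect = effect, pairwise = pairwise,
                 details = details),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(x$test, "\n")
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %.4g, df = (%s), p = %.4g\n",
                x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$effect))
    for (nm in names(x$effect)) cat(sprintf("  %s = %.4g\n", nm, x$effect[[nm]]))
  if (!is.null(x$pairwise)) { cat("  pairwise:\n"); print(x$pairwise) }
  invisible(x)
}

#' Speech rate per participant
#'
#' Per-segment rate is the manually counted syllables divided by the segment
#' duration in seconds; the participant's rate is the unweighted mean of
#' segment rates (not the pooled-count rate), computed separately per
#' register.
#'
#' @param segments Data frame with columns \code{participant_id},
#'   \code{register}, \code{syllable_count}, \code{duration}.
#' @return Data frame with \code{participant_id}, \code{register},
#'   \code{speech_rate}, \code{n_segments}.
#' @export
speech_rate <- function(segments) {
  req <- c("participant_id", "register", "syllable_count", "duration")
  stopifnot(all(req %in% names(segments)))
  miss <- is.na(segments$syllable_count)
  if (any(miss))
    stop("missing syllable counts for segment(s): ",
         paste(utils::head(segments$segment_id[miss], 10), collapse = ", "))
  if (any(segments$duration <= 0))
    stop("non-positive duration for segment(s): ",
         paste(utils::head(segments$segment_id[segments$duration <= 0], 10),
               collapse = ", "))
  rate <- segments$syllable_count / segments$duration
  agg <- stats::aggregate(rate,
                          by = list(participant_id = segments$participant_id,
                                    register = segments$register),
                          FUN = mean)
  cnt <- stats::aggregate(rate,
                          by = list(participant_id = segments$participant_id,
                                    register = segments$register),
                          FUN = length)
  data.frame(participant_id = agg$participant_id, register = agg$register,
             speech_rate = agg$x, n_segments = cnt$x)
}

#' One-way MANOVA with Wilks' lambda
#'
#' Standard multivariate GLM: Wilks' \eqn{\Lambda}, Rao's F approximation
#' with its degrees of freedom, the p value, and multivariate partial
#' \eqn{\eta^2 = 1 - \Lambda^{1/s}} where \eqn{s = \min(p, k - 1)}.
#'
#' @param summaries Data frame of participant summaries.
#' @param dependents Character vector (>= 2) of dependent measure columns.
#' @param group Grouping column name (>= 3 levels expected, >= 2 accepted).
#' @return A \code{stat_report}.
#' @export
group_manova <- function(summaries,
                         dependents = c("psi_delta_theta",
                                        "psi_theta_betagamma"),
                         group = "group") {
  stopifnot(length(dependents) >= 2)
  d <- summaries[complete.cases(summaries[, c(dependents, group)]),
                 c(dependents, group)]
  g <- factor(d[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups")
  Y <- as.matrix(d[, dependents])
  fit <- manova(Y ~ g)
  sm <- summary(fit, test = "Wilks")$stats
  lambda <- sm[1, "Wilks"]
  if (!is.finite(lambda))
    stop("singular within-group covariance: Wilks' lambda undefined")
  s <- min(length(dependents), nlevels(g) - 1)
  new_stat_report(
    test = sprintf("MANOVA (Wilks) of (%s) by %s",
                   paste(dependents, collapse = ", "), group),
    statistic = sm[1, "approx F"],
    df = c(sm[1, "num Df"], sm[1, "den Df"]),
    p_value = sm[1, "Pr(>F)"],
    effect = list(wilks_lambda = lambda,
                  partial_eta_sq = 1 - lambda^(1 / s)))
}

# Greenhouse-Geisser epsilon for a within-subject effect, from the pooled
# covariance S of the subject x cell score matrix and the effect's contrast
# matrix C (rows orthonormal): eps = tr(CSC')^2 / (df * tr((CSC')^2)).
gg_epsilon <- function(scores, C) {
  S <- stats::cov(scores)
  M <- C %*% S %*% t(C)
  sum(diag(M))^2 / (nrow(C) * sum(M * M))
}

# Orthonormal contrast basis for a factor with k levels.
contrast_basis <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))  # k x (k-1), orthonormal columns
}

#' Mixed-design repeated-measures ANOVA for per-band PSI
#'
#' Fits the 3 (literacy group, between) x 2 (AM band pair, within) x 5
#' (spectral band, within) design with standard mixed-model sums of squares
#' (via \code{aov()} error strata on a balanced design), reporting F, df,
#' p and partial \eqn{\eta^2} for every between/within effect.
#' Greenhouse-Geisser correction of within-effect df is available.
#'
#' @param psi_table Long data frame with columns \code{participant_id},
#'   \code{group}, \code{pair} (AM band pair), \code{band} (spectral band)
#'   and \code{psi}; every participant must have all pair x band cells.
#' @param adjust \code{"none"} (default, matching conventionally reported
#'   uncorrected df) or \code{"greenhouse-geisser"}.
#' @return A \code{stat_report} whose \code{details} is the effect table.
#' @export
rm_anova_psi <- function(psi_table, adjust = c("none", "greenhouse-geisser")) {
  adjust <- match.arg(adjust)
  req <- c("participant_id", "group", "pair", "band", "psi")
  stopifnot(all(req %in% names(psi_table)))
  d <- psi_table
  d$participant_id <- factor(d$participant_id)
  d$group <- factor(d$group)
  d$pair <- factor(d$pair)
  d$band <- factor(d$band)
  n_cells <- nlevels(d$pair) * nlevels(d$band)
  tab <- table(d$participant_id)
  if (any(tab != n_cells))
    stop("unbalanced within-participant design: every participant needs all ",
         n_cells, " pair x band cells")
  fit <- aov(psi ~ group * pair * band +
               Error(participant_id / (pair * band)), data = d)
  sm <- summary(fit)
  eff <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- rownames(st)
    resid_i <- grep("^Residuals", trimws(terms))
    if (length(resid_i) == 0) next
    ss_err <- st[resid_i, "Sum Sq"]
    df_err <- st[resid_i, "Df"]
    for (i in setdiff(seq_along(terms), resid_i)) {
      nm <- trimws(terms[i])
      eff[[nm]] <- data.frame(
        effect = nm, df1 = st[i, "Df"], df2 = df_err,
        ss = st[i, "Sum Sq"], ss_error = ss_err,
        F = st[i, "F value"], p = st[i, "Pr(>F)"],
        partial_eta_sq = st[i, "Sum Sq"] / (st[i, "Sum Sq"] + ss_err))
    }
  }
  out <- do.call(rbind, eff)
  rownames(out) <- NULL
  out$gg_epsilon <- NA_real_

  if (adjust == "greenhouse-geisser") {
    # cell score matrix: participants x (pair:band cells), fixed cell order
    d <- d[order(d$participant_id, d$pair, d$band), ]
    scores <- matrix(d$psi, nrow = nlevels(d$participant_id), byrow = TRUE)
    kp <- nlevels(d$pair); kb <- nlevels(d$band)
    Qp <- contrast_basis(kp); Qb <- contrast_basis(kb)
    ones_p <- rep(1, kp) / sqrt(kp); ones_b <- rep(1, kb) / sqrt(kb)
    Cmap <- list(
      "pair" = t(kronecker(Qp, matrix(ones_b))),
      "band" = t(kronecker(matrix(ones_p), Qb)),
      "pair:band" = t(kronecker(Qp, Qb)))
    within_part <- sub("^group:", "", out$effect)
    for (row in seq_len(nrow(out))) {
      nm <- within_part[row]
      if (out$effect[row] != "group" && nm %in% names(Cmap)) {
        epsv <- gg_epsilon(scores, Cmap[[nm]])
        out$gg_epsilon[row] <- epsv
        out$p[row] <- pf(out$F[row], out$df1[row] * epsv,
                         out$df2[row] * epsv, lower.tail = FALSE)
      }
    }
  }
  main <- out[out$effect == "group", ]
  new_stat_report(
    test = sprintf("repeated-measures ANOVA: psi ~ group x pair x band (%s)",
                   adjust),
    statistic = main$F, df = c(main$df1, main$df2), p_value = main$p,
    effect = list(partial_eta_sq = main$partial_eta_sq),
    details = out)
}

#' Tukey HSD post-hoc group comparisons
#'
#' Studentised-range pairwise comparisons after a one-way ANOVA; unbalanced
#' groups are handled by the Tukey-Kramer form (as in
#' \code{stats::TukeyHSD}).
#'
#' @param summaries Data frame of participant summaries.
#' @param measure Dependent measure column.
#' @param group Grouping column.
#' @return A \code{stat_report} whose \code{pairwise} is the comparison
#'   table (columns \code{diff}, \code{lwr}, \code{upr}, \code{p_adj}).
#' @export
posthoc_tukey <- function(summaries, measure, group = "group") {
  d <- summaries[complete.cases(summaries[, c(measure, group)]), ]
  g <- factor(d[[group]])
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  y <- d[[measure]]
  fit <- aov(y ~ g)
  tk <- TukeyHSD(fit)$g
  tab <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  new_stat_report(test = paste("Tukey HSD:", measure, "by", group),
                  statistic = NULL, df = NULL, p_value = NULL,
                  pairwise = tab)
}

#' Correlation between two measures
#'
#' Pearson or Spearman (rank, with midranks for ties) correlation with its
#' p value; optionally Bonferroni-adjusted for a declared family of tests.
#'
#' @param summaries Data frame.
#' @param x,y Column names.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @param bonferroni_n Family size for Bonferroni adjustment (1 = none).
#' @return A \code{stat_report} with the correlation in \code{effect}.
#' @export
correlate <- function(summaries, x, y, method = c("spearman", "pearson"),
                      bonferroni_n = 1) {
  method <- match.arg(method)
  d <- summaries[complete.cases(summaries[, c(x, y)]), ]
  if (nrow(d) < 4) stop("need >= 4 complete pairs")
  if (sd(d[[x]]) == 0 || sd(d[[y]]) == 0)
    stop("constant variable: correlation undefined")
  ct <- suppressWarnings(cor.test(d[[x]], d[[y]], method = method,
                                  exact = FALSE))
  p_adj <- min(1, ct$p.value * bonferroni_n)
  new_stat_report(
    test = sprintf("%s correlation: %s vs %s (n = %d%s)", method, x, y,
                   nrow(d),
                   if (bonferroni_n > 1)
                     sprintf(", Bonferroni family %d", bonferroni_n) else ""),
    statistic = unname(ct$estimate), df = nrow(d) - 2, p_value = p_adj,
    effect = stats::setNames(list(unname(ct$estimate), ct$p.value),
                             c(if (method == "spearman") "rho" else "r",
                               "p_unadjusted")))
}

#' Correlation matrix between behavioural scores and modulation measures
#'
#' The standard report layout: behavioural and control variables as rows,
#' modulation measures as columns, with Bonferroni adjustment over the
#' number of cells actually computed (declared in the result).
#'
#' @param summaries Participant summary data frame.
#' @param rows Row variable names.
#' @param cols Column (modulation measure) names.
#' @param method Correlation method.
#' @return List with \code{estimate}, \code{p}, \code{p_bonferroni}
#'   matrices and \code{family_size}.
#' @export
correlation_table <- function(summaries,
                              rows = c("years_literacy", "syllabic_division",
                                       "rhyme_detection", "phoneme_deletion",
                                       "vocabulary", "token_test",
                                       "speech_rate", "age"),
                              cols = c("delta_auc", "theta_auc",
                                       "psi_delta_theta",
                                       "psi_theta_betagamma"),
                              method = "spearman") {
  fam <- length(rows) * length(cols)
  est <- p <- matrix(NA_real_, length(rows), length(cols),
                     dimnames = list(rows, cols))
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    r <- correlate(summaries, rows[i], cols[j], method = method)
    est[i, j] <- r$statistic
    p[i, j] <- r$effect$p_unadjusted
  }
  list(estimate = est, p = p, p_bonferroni = pmin(1, p * fam),
       family_size = fam, method = method)
}

#' Non-parametric group comparisons
#'
#' Shapiro-Wilk normality check per group, Kruskal-Wallis H across groups
#' and pairwise Mann-Whitney U tests (exact p where sample sizes permit and
#' there are no ties, as in \code{stats::wilcox.test}).
#'
#' @param summaries Data frame.
#' @param measure Dependent measure column.
#' @param group Grouping column.
#' @return A \code{stat_report}: Kruskal-Wallis in the main slots, pairwise
#'   Mann-Whitney in \code{pairwise}, Shapiro-Wilk p values in
#'   \code{details}.
#' @export
nonparametric_groups <- function(summaries, measure, group = "group") {
  d <- summaries[complete.cases(summaries[, c(measure, group)]), ]
  g <- factor(d[[group]])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 observations each")
  y <- d[[measure]]
  if (length(unique(y)) == 1) stop("all values tied: tests undefined")
  kw <- kruskal.test(y, g)
  lev <- levels(g)
  pw <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    yi <- y[g == lev[i]]; yj <- y[g == lev[j]]
    wt <- suppressWarnings(wilcox.test(yi, yj))
    pw[[length(pw) + 1]] <- data.frame(
      comparison = paste(lev[i], "vs", lev[j]),
      U = unname(wt$statistic), p = wt$p.value)
  }
  shap <- vapply(lev, function(l) {
    yy <- y[g == l]
    if (length(unique(yy)) < 3 || length(yy) < 3) NA_real_
    else shapiro.test(yy)$p.value
  }, numeric(1))
  new_stat_report(
    test = paste("Kruskal-Wallis:", measure, "by", group),
    statistic = unname(kw$statistic), df = unname(kw$parameter),
    p_value = kw$p.value,
    pairwise = do.call(rbind, pw),
    details = list(shapiro_p = shap))
}
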