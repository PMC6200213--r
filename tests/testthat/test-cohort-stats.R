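test_that("speech rate follows the mean-of-rates definition", {
  one <- data.frame(participant_id = "p", register = "conversational",
                    syllable_count = 14, duration = 7, segment_id = "s1")
  expect_equal(speech_rate(one)$speech_rate, 2.0)

  two <- data.frame(participant_id = "p", register = "conversational",
                    syllable_count = c(8, 8), duration = c(4, 2),
                    segment_id = c("s1", "s2"))
  expect_equal(speech_rate(two)$speech_rate, 3.0)  # mean(2, 4), not 16/6

  bad <- two; bad$duration[2] <- 0
  expect_error(speech_rate(bad), "duration")
  bad2 <- two; bad2$syllable_count[1] <- NA
  expect_error(speech_rate(bad2), "s1")
})

test_that("MANOVA Wilks' lambda matches a direct eigen-decomposition oracle", {
  Y <- cbind(c(1, 2, 3, 4, 5, 6), c(2, 4, 3, 6, 9, 8))
  g <- c("a", "a", "a", "b", "b", "b")
  d <- data.frame(psi_delta_theta = Y[, 1], psi_theta_betagamma = Y[, 2],
                  group = g)
  rep <- group_manova(d)
  expect_equal(rep$effect$wilks_lambda, manova_oracle(Y, g), tolerance = 1e-10)
  expect_equal(rep$effect$partial_eta_sq,
               1 - manova_oracle(Y, g),  # s = 1 for two groups
               tolerance = 1e-10)
  expect_gte(rep$p_value, 0); expect_lte(rep$p_value, 1)

  # duplicated groups: no between-group variance
  set.seed(2)
  base <- data.frame(psi_delta_theta = rnorm(10), psi_theta_betagamma = rnorm(10))
  dup <- rbind(cbind(base, group = "g1"), cbind(base, group = "g2"))
  rep2 <- group_manova(dup)
  expect_equal(rep2$effect$wilks_lambda, 1, tolerance = 1e-10)
  expect_lt(rep2$statistic, 1e-8)
})

test_that("mixed-design repeated-measures ANOVA matches the textbook SS oracle", {
  set.seed(5)
  d <- expand.grid(participant_id = sprintf("s%02d", 1:12),
                   pair = c("delta_theta", "theta_betagamma"),
                   band = as.character(1:5), stringsAsFactors = FALSE)
  d$group <- c("g1", "g2", "g3")[(as.integer(sub("s", "", d$participant_id)) - 1) %/% 4 + 1]
  d$psi <- 0.5 + 0.08 * (d$group == "g3") + 0.05 * (d$pair == "delta_theta") +
    0.01 * as.integer(d$band) + rnorm(nrow(d), 0, 0.04)
  rep <- rm_anova_psi(d)
  o <- rm_anova_oracle(d)
  expect_equal(rep$details$F[match(names(o), rep$details$effect)],
               unname(o), tolerance = 1e-6)
  expect_true(all(rep$details$partial_eta_sq >= 0 &
                    rep$details$partial_eta_sq <= 1))

  # Greenhouse-Geisser epsilons lie in the admissible range and only
  # within-effects are corrected
  gg <- rm_anova_psi(d, adjust = "greenhouse-geisser")
  eps <- gg$details$gg_epsilon
  expect_true(is.na(eps[gg$details$effect == "group"]))
  expect_true(all(eps[!is.na(eps)] > 0 & eps[!is.na(eps)] <= 1 + 1e-9))

  # constant group shift: group main effect, no interactions beyond noise
  d2 <- d
  d2$psi <- 0.5 + 0.2 * (d2$group == "g1") + rnorm(nrow(d2), 0, 0.01)
  rep2 <- rm_anova_psi(d2)
  det <- rep2$details
  expect_lt(det$p[det$effect == "group"], 1e-6)
  expect_gt(det$p[det$effect == "group:pair:band"], 0.001)

  # participant-only variation: every effect's sum of squares vanishes
  # (group offsets balanced to zero within each group)
  d3 <- d
  offs <- setNames(rep(c(-2, -1, 3, 0), 3), sprintf("s%02d", 1:12))
  d3$psi <- offs[d3$participant_id]
  rep3 <- rm_anova_psi(d3)
  expect_lt(max(rep3$details$ss), 1e-18)

  expect_error(rm_anova_psi(d[-1, ]), "unbalanced")
})

test_that("Tukey post hocs behave on identical, separated and relabelled groups", {
  set.seed(9)
  x <- rnorm(8)
  ident <- data.frame(y = c(x, x), group = rep(c("a", "b"), each = 8))
  rep1 <- posthoc_tukey(ident, "y")
  expect_gt(rep1$pairwise$p_adj, 0.999)

  sep <- data.frame(y = c(rnorm(6, 0, 1), rnorm(6, 0.2, 1), rnorm(6, 30, 1)),
                    group = rep(c("a", "b", "c"), each = 6))
  rep2 <- posthoc_tukey(sep, "y")
  pc <- rep2$pairwise
  expect_lt(pc$p_adj[pc$comparison == "c-a"], 0.001)
  expect_lt(pc$p_adj[pc$comparison == "c-b"], 0.001)

  relab <- sep
  relab$group <- c(a = "b", b = "a", c = "c")[relab$group]
  rep3 <- posthoc_tukey(relab, "y")
  expect_equal(sort(rep3$pairwise$p_adj), sort(rep2$pairwise$p_adj),
               tolerance = 1e-12)
  expect_error(posthoc_tukey(sep[c(1, 7:12), ], "y"), "n >= 2")
})

test_that("correlations match closed forms and respect monotone invariance", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = 2 * c(1, 2, 3, 4, 5) + 3)
  expect_equal(correlate(d, "x", "y", "spearman")$statistic, 1)
  expect_equal(correlate(d, "x", "y", "pearson")$statistic, 1)

  d2 <- data.frame(x = c(-2, -1, 0.5, 1, 2), y = -c(-2, -1, 0.5, 1, 2)^3)
  expect_equal(correlate(d2, "x", "y", "spearman")$statistic, -1)

  # hand-computed: ranks (1..5) vs (2,1,4,3,5), sum d^2 = 4, rho = 0.8
  d3 <- data.frame(x = 1:5, y = c(2, 1, 4, 3, 5))
  expect_equal(correlate(d3, "x", "y", "spearman")$statistic, 0.8)

  set.seed(3)
  d4 <- data.frame(x = rnorm(30), y = rnorm(30))
  r_raw <- correlate(d4, "x", "y", "spearman")$statistic
  d4$x <- exp(d4$x)          # strictly monotone transform
  d4$y <- atan(d4$y)
  expect_equal(correlate(d4, "x", "y", "spearman")$statistic, r_raw)

  expect_error(correlate(data.frame(x = rep(1, 10), y = rnorm(10)), "x", "y"),
               "constant")
  r_adj <- correlate(d3, "x", "y", "spearman", bonferroni_n = 10)
  expect_equal(r_adj$p_value, min(1, r_adj$effect$p_unadjusted * 10))
})

test_that("non-parametric group tests match enumeration and detect non-normality", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  group = rep(c("g_low", "g_upp"), each = 3))
  rep <- nonparametric_groups(d, "y")
  expect_equal(rep$pairwise$U[1], 0)   # {1,2,3} never exceeds {4,5,6}
  expect_gte(rep$p_value, 0)

  set.seed(12)
  same <- data.frame(y = rep(rnorm(8), 2), group = rep(c("a", "b"), each = 8))
  expect_lt(nonparametric_groups(same, "y")$statistic, 1e-10)

  bimodal <- data.frame(y = c(rnorm(25, -5, 0.3), rnorm(25, 5, 0.3)),
                        group = rep(c("a", "b"), 25))
  shap <- shapiro.test(bimodal$y)$p.value
  expect_lt(shap, 0.05)

  expect_error(nonparametric_groups(
    data.frame(y = rep(1, 8), group = rep(c("a", "b"), 4)), "y"), "tied")
})

test_that("the correlation table has the published 8 x 4 layout", {
  set.seed(33)
  s <- simulate_cohort_summaries(cohort_spec())
  s$delta_auc <- rnorm(nrow(s)); s$theta_auc <- rnorm(nrow(s))
  tab <- correlation_table(s)
  expect_equal(dim(tab$estimate), c(8, 4))
  expect_equal(tab$family_size, 32)
  expect_true(all(tab$p_bonferroni >= tab$p, na.rm = TRUE))
})
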