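test_that("kappa maps to expected PSI through the Bessel ratio and back", {
  expect_equal(psi_for_kappa(2), besselI(2, 1) / besselI(2, 0))
  expect_equal(psi_for_kappa(Inf), 1)
  expect_equal(psi_for_kappa(0), 0)
  for (r in c(0.1, 0.45, 0.7, 0.9))
    expect_equal(psi_for_kappa(kappa_for_psi(r)), r, tolerance = 1e-8)
})

test_that("von Mises jitter has the prescribed circular moment", {
  set.seed(14)
  for (k in c(0.5, 2, 8)) {
    q <- samph:::vonmises_quantile(k)
    eps <- q(runif(200000))
    expect_lt(abs(mean(cos(eps)) - psi_for_kappa(k)), 0.01)
    expect_lt(abs(mean(sin(eps))), 0.01)
  }
})

test_that("modulator coupling yields the target true-phase PSI", {
  # deterministic locking: PSI exactly 1
  set.seed(3)
  sp_inf <- synth_spec(duration = 30, rate = 16800, kappa_dt = Inf,
                       kappa_tbg = Inf)
  m <- make_modulators(sp_inf)
  expect_equal(psi(m$phase[, 1], m$phase[, 2], 2, 1050), 1, tolerance = 1e-12)
  expect_equal(psi(m$phase[, 2], m$phase[, 3], 3, 1050), 1, tolerance = 1e-12)

  # independent modulators: PSI small at 60 s
  set.seed(4)
  sp0 <- synth_spec(duration = 60, rate = 16800, kappa_dt = 0, kappa_tbg = 0)
  m0 <- make_modulators(sp0)
  expect_lt(psi(m0$phase[, 1], m0$phase[, 2], 2, 1050), 0.1)

  # kappa = 2: true-phase PSI near the Bessel ratio (long series, 3 seeds)
  vals <- vapply(1:3, function(s) {
    set.seed(40 + s)
    sp <- synth_spec(duration = 200, rate = 16800, kappa_dt = 2, kappa_tbg = 2)
    mm <- make_modulators(sp)
    psi(mm$phase[, 1], mm$phase[, 2], 2, 1050)
  }, numeric(1))
  expect_lt(abs(mean(vals) - psi_for_kappa(2)), 0.05)
})

test_that("segment synthesis is seed-deterministic and respects depths", {
  sp <- synth_spec(duration = 3, rate = 16800, carrier = "tones", seed = 77)
  s1 <- synth_segment(sp)
  s2 <- synth_segment(sp)
  expect_identical(s1$segment$samples, s2$segment$samples)
  expect_identical(s1$truth$rates, s2$truth$rates)

  # theta-dominant depths show up as the largest theta AUC
  spt <- synth_spec(duration = 30, rate = 16800,
                    depths = c(0.1, 0.9, 0.1), seed = 55)
  a <- analyze_segment(synth_segment(spt)$segment)
  expect_gt(a$summary$theta_auc, a$summary$delta_auc)
  expect_gt(a$summary$theta_auc, a$summary$beta_gamma_auc)
})

test_that("unmodulated gaussian noise shows neither coupling nor spectral peaks", {
  # Monte-Carlo: channel powers at the slowest modulation rates have few
  # cycles in 30 s, so the flatness bound is checked on the replicate mean
  res <- vapply(66:68, function(s) {
    sp <- synth_spec(duration = 30, rate = 16800, carrier = "gaussian",
                     depths = c(0, 0, 0), seed = s)
    a <- analyze_segment(synth_segment(sp)$segment)
    c(a$summary$psi_delta_theta, a$summary$psi_theta_betagamma,
      max(abs(a$mod_spec$averaged)))
  }, numeric(3))
  expect_lt(mean(res[1, ]), 0.2)
  expect_lt(mean(res[2, ]), 0.2)
  expect_lt(mean(res[3, ]), 0.5)
})

test_that("cohort generation writes a loadable, reproducible dataset", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  r1 <- tiny_cohort(d1, seed = 19)
  r2 <- tiny_cohort(d2, seed = 19)
  expect_identical(r1$ground_truth$true_psi_dt, r2$ground_truth$true_psi_dt)
  expect_identical(r1$manifest$syllable_count, r2$manifest$syllable_count)

  mf <- load_manifest(r1$manifest_path)
  expect_equal(nrow(mf), 6)  # 3 participants x (1 conversational + 1 rhythmic)
  expect_equal(sort(unique(mf$group)),
               c("high_literate", "illiterate", "low_literate"))
  w <- read_wav(mf$audio_path[1])
  expect_equal(w$rate, 16800)
  expect_true(all(is.finite(r1$ground_truth$true_psi_dt)))
})

test_that("summary-level simulation matches the prescribed group structure", {
  spec <- cohort_spec(seed = 5)
  set.seed(5)
  s <- simulate_cohort_summaries(spec)
  expect_equal(nrow(s), 46)
  expect_equal(as.vector(table(s$group)[c("illiterate", "low_literate",
                                          "high_literate")]), c(15, 19, 12))
  expect_true(all(s$psi_delta_theta > 0 & s$psi_delta_theta < 1))
  expect_true(all(s$phoneme_deletion[s$group == "illiterate"] == 0))
})
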