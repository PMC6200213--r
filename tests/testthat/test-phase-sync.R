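test_that("instantaneous phase tracks frequency, quadrature and sign", {
  fs <- 1050
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  keep <- (2 * fs):(8 * fs)
  ph <- instantaneous_phase(sin(2 * pi * 5 * t))
  slope <- mean(Arg(exp(1i * diff(ph)))[keep]) * fs  # unwrapped increments
  expect_lt(abs(slope - 2 * pi * 5) / (2 * pi * 5), 0.01)

  ph_cos <- instantaneous_phase(cos(2 * pi * 5 * t))
  ph_sin <- instantaneous_phase(sin(2 * pi * 5 * t))
  dphi <- Arg(exp(1i * (ph_cos - ph_sin)))
  expect_lt(max(abs(dphi[keep] - pi / 2)), 0.05)

  ph_neg <- instantaneous_phase(-sin(2 * pi * 5 * t))
  dneg <- Arg(exp(1i * (ph_neg - ph_sin)))
  expect_lt(max(abs(abs(dneg[keep]) - pi)), 0.05)

  expect_error(instantaneous_phase(numeric(100)), "all-zero")
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("PSI is 1 for n:m locked phases and invariant to constant offsets", {
  fs <- 1050
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  th1 <- 2 * pi * 2 * t
  th2 <- 2 * pi * 4 * t
  expect_equal(psi(th1, th2, 2, fs), 1, tolerance = 1e-9)
  for (phi0 in c(-2.5, 0.1, 3)) {
    expect_equal(psi(th1, 2 * th1 + phi0, 2, fs), 1, tolerance = 1e-12)
    expect_equal(psi(th1, 3 * th1 + phi0, 3, fs), 1, tolerance = 1e-12)
  }
  expect_error(psi(th1[1:2000], th2[1:2000], 2, fs), "too short")
})

test_that("PSI under i.i.d. von Mises jitter approaches the Bessel ratio", {
  fs <- 1050
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  th1 <- 2 * pi * 2 * t
  set.seed(8)
  for (k in c(1, 2, 4)) {
    q <- samph:::vonmises_quantile(k)
    eps <- q(runif(length(t)))
    value <- psi(th1, 2 * th1 + eps, 2, fs, trim = 0)
    expect_lt(abs(value - psi_for_kappa(k)), 0.02)
  }
})

test_that("PSI is bounded, phase-shift invariant and time-reversal invariant", {
  set.seed(21)
  fs <- 1050
  for (i in 1:20) {
    n <- sample(3000:8000, 1)
    th1 <- cumsum(rnorm(n, 0.01, 0.05))
    th2 <- cumsum(rnorm(n, 0.02, 0.05))
    v <- psi(th1, th2, sample(2:3, 1), fs, trim = 0)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(psi(th1 + 1.3, th2, 2, fs, trim = 0),
                 psi(th1, th2, 2, fs, trim = 0), tolerance = 1e-12)
    expect_equal(psi(rev(th1), rev(th2), 2, fs, trim = 0),
                 psi(th1, th2, 2, fs, trim = 0), tolerance = 1e-12)
  }
})

test_that("segment PSI detects perfect coupling and rejects independence", {
  sp <- synth_spec(duration = 20, rate = 16800, kappa_dt = Inf,
                   kappa_tbg = Inf, seed = 91)
  am <- am_filterbank(extract_envelopes(zscore_segment(
    synth_segment(sp)$segment)))
  ps <- segment_psi(am)
  expect_gte(ps$segment["psi_delta_theta"], 0.9)
  expect_true(all(ps$per_band >= 0 & ps$per_band <= 1))
  # bitwise determinism of the analysis
  expect_identical(segment_psi(am), segment_psi(am))

  # independent modulators: the filtered phase series are autocorrelated, so
  # the i.i.d. resultant bound does not apply; Monte-Carlo over 3 segments
  floor_vals <- vapply(92:94, function(s) {
    sp0 <- synth_spec(duration = 20, rate = 16800, kappa_dt = 0,
                      kappa_tbg = 0, seed = s)
    am0 <- am_filterbank(extract_envelopes(zscore_segment(
      synth_segment(sp0)$segment)))
    unname(segment_psi(am0)$segment["psi_delta_theta"])
  }, numeric(1))
  expect_lt(mean(floor_vals), 0.2)
})

test_that("participant PSI is the unweighted segment mean", {
  mk <- function(v) structure(list(
    per_band = matrix(v, 5, 2,
                      dimnames = list(NULL, c("psi_delta_theta",
                                              "psi_theta_betagamma"))),
    segment = c(psi_delta_theta = v, psi_theta_betagamma = v)),
    class = "psi_result")
  pp <- participant_psi(list(mk(0.4), mk(0.6)))
  expect_equal(unname(pp$segment["psi_delta_theta"]), 0.5)
  one <- participant_psi(list(mk(0.37)))
  expect_equal(unname(one$segment["psi_delta_theta"]), 0.37)
  expect_equal(participant_psi(list(mk(0.2), mk(0.3), mk(0.7)))$per_band,
               participant_psi(list(mk(0.7), mk(0.2), mk(0.3)))$per_band)
  expect_error(participant_psi(list()), "no segments")
})
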