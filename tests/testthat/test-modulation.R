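test_that("AM filterbank isolates modulation bands with little leakage", {
  es <- env_from_fun(function(t) 1 + 0.5 * sin(2 * pi * 5 * t), 30)
  am <- am_filterbank(es)
  fs <- 1050
  keep <- (round(0.5 * fs) + 1):(nrow(es$envelopes) - round(0.5 * fs))
  t <- (seq_len(nrow(es$envelopes)) - 1) / fs
  target <- 0.5 * sin(2 * pi * 5 * t)
  for (b in 1:5) {
    theta <- am$waveforms[, b, 2]
    expect_lt(sqrt(mean((theta[keep] - target[keep])^2)) /
                sqrt(mean(target^2)), 0.10)
    expect_lt(sqrt(mean(am$waveforms[keep, b, 1]^2)), 0.05)
    expect_lt(sqrt(mean(am$waveforms[keep, b, 3]^2)), 0.05)
    for (k in 1:3) expect_lt(abs(mean(am$waveforms[, b, k])), 1e-6)
  }

  # constant envelope: DC removed everywhere
  esc <- env_from_fun(function(t) rep(3, length(t)), 30)
  amc <- am_filterbank(esc)
  expect_lt(max(abs(amc$waveforms)), 1e-6)
})

test_that("2 Hz and 20 Hz envelope components separate with < 5% cross-leakage", {
  es <- env_from_fun(function(t)
    2 + 0.5 * sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 20 * t), 30)
  am <- am_filterbank(es)
  fs <- 1050
  d <- am$waveforms[, 1, 1]; g <- am$waveforms[, 1, 3]
  expect_lt(power_at(d, fs, 20) / power_at(g, fs, 20), 0.05)
  expect_lt(power_at(g, fs, 2) / power_at(d, fs, 2), 0.05)
  expect_gt(power_at(d, fs, 2) / (0.5^2 / 2), 0.8)
  expect_gt(power_at(g, fs, 20) / (0.5^2 / 2), 0.8)
})

test_that("AM filtering rejects envelopes shorter than 3 delta-filter lengths", {
  es <- env_from_fun(function(t) 1 + 0.1 * sin(2 * pi * 5 * t), 6)
  expect_error(am_filterbank(es), "3 x delta-filter length")
})

test_that("differenced modulation spectrum is mean-zero and scale-invariant", {
  set.seed(31)
  t <- seq(0, 30 - 1 / 1050, by = 1 / 1050)
  env <- vapply(1:5, function(b)
    abs(2 + 0.3 * sin(2 * pi * (1 + b) * t) + 0.2 * rnorm(length(t))),
    numeric(length(t)))
  es <- envelope_set(env, 1050)
  ms <- modulation_spectrum(es)
  expect_lt(max(abs(colMeans(ms$differenced))), 1e-9)
  # geometric channel spacing
  r <- ms$centers[-1] / ms$centers[-24]
  expect_lt(max(abs(r - r[1])), 1e-9)
  # overall envelope scaling cancels
  ms_k <- modulation_spectrum(envelope_set(3.5 * env, 1050))
  expect_lt(max(abs(ms_k$differenced - ms$differenced)), 1e-9)
  expect_error(modulation_spectrum(envelope_set(matrix(0, 40000, 5), 1050)),
               "silent")
})

test_that("a 5 Hz modulated envelope peaks in the channel nearest 5 Hz", {
  es <- env_from_fun(function(t) 1 + 0.4 * sin(2 * pi * 5 * t), 40)
  ms <- modulation_spectrum(es)
  expect_equal(which.max(ms$averaged),
               which.min(abs(ms$centers - 5)))
})

test_that("flat-spectrum envelopes give a near-flat differenced spectrum", {
  set.seed(99)
  maxd <- replicate(20, {
    env <- matrix(abs(10 + rnorm(15000 * 5)), ncol = 5)
    ms <- modulation_spectrum(envelope_set(env, 1050), trim = 0.5)
    max(abs(ms$averaged))
  })
  expect_lt(mean(maxd), 0.5)
})

test_that("modulation channels pass their centre >= 10x more than centres 2 away", {
  ch <- samph:::modulation_channels(1050)
  g <- vapply(seq_along(ch$filters), function(i)
    samph:::zp_gain_at(ch$filters[[i]], ch$centers), numeric(24))
  # g[f, c]: gain of channel c at centre frequency f
  for (cc in 1:24) {
    far <- setdiff(seq_len(24), (cc - 1):(cc + 1))
    expect_gte(g[cc, cc] / max(g[far, cc]), 10)
  }
})

test_that("band AUCs partition the full-range AUC and track modulation content", {
  # zero spectrum -> zero AUC
  edges <- exp(seq(log(0.9), log(40), length.out = 25))
  ms0 <- structure(list(centers = sqrt(edges[-1] * edges[-25]),
                        differenced = matrix(0, 24, 5)),
                   class = "modulation_spectrum")
  be0 <- band_energy(ms0)
  expect_true(all(be0$per_band == 0))

  es <- env_from_fun(function(t) 1 + 0.4 * sin(2 * pi * 5 * t), 40)
  ms <- modulation_spectrum(es)
  be <- band_energy(ms)
  expect_lt(max(abs(colSums(be$per_band) - be$full_per_band)), 1e-9)
  expect_gt(be$averaged["theta"], be$averaged["delta"])
  expect_gt(be$averaged["theta"], be$averaged["beta_low_gamma"])
})
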