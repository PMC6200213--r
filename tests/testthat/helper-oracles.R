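# Independent oracles used across tests. These re-derive expected values from
# first principles (eigen decompositions, textbook sums of squares, FFT power
# ratios) without touching the implementation under test.

# Wilks' lambda via direct eigen-decomposition of solve(W) %*% B.
manova_oracle <- function(Y, g) {
  g <- factor(g)
  grand <- colMeans(Y)
  W <- matrix(0, ncol(Y), ncol(Y))
  B <- matrix(0, ncol(Y), ncol(Y))
  for (lev in levels(g)) {
    Yg <- Y[g == lev, , drop = FALSE]
    mg <- colMeans(Yg)
    W <- W + crossprod(sweep(Yg, 2, mg))
    B <- B + nrow(Yg) * tcrossprod(mg - grand)
  }
  ev <- Re(eigen(solve(W) %*% B, only.values = TRUE)$values)
  prod(1 / (1 + ev))
}

# Balanced mixed-design ANOVA (one between factor A, two within factors B and
# C) from the textbook mean-based sums of squares; returns the F value of
# every effect. Data must have columns participant_id, group, pair, band,
# psi, and equal group sizes.
rm_anova_oracle <- function(d) {
  d$participant_id <- as.character(d$participant_id)
  mu <- mean(d$psi)
  p <- length(unique(d$pair)); q <- length(unique(d$band))
  subj <- unique(d[, c("participant_id", "group")])
  N <- nrow(subj)
  a <- length(unique(subj$group))
  n_per <- table(subj$group)
  stopifnot(length(unique(n_per)) == 1)  # oracle requires balanced groups
  n <- unname(n_per[1])
  gof <- setNames(as.character(subj$group), subj$participant_id)

  m <- function(...) tapply(d$psi, lapply(c(...), function(v) d[[v]]), mean)
  Yg <- c(m("group")); Yp <- c(m("pair")); Yc <- c(m("band"))
  Ys <- c(m("participant_id"))
  Ygp <- m("group", "pair"); Ygc <- m("group", "band")
  Ypc <- m("pair", "band"); Ygpc <- m("group", "pair", "band")
  Ysp <- m("participant_id", "pair"); Ysc <- m("participant_id", "band")

  SS_A  <- p * q * n * sum((Yg - mu)^2)
  SS_SA <- p * q * sum((Ys - Yg[gof[names(Ys)]])^2)
  SS_B  <- q * N * sum((Yp - mu)^2)
  SS_C  <- p * N * sum((Yc - mu)^2)
  SS_AB <- q * n * sum((sweep(sweep(Ygp, 1, Yg), 2, Yp) + mu)^2)
  SS_AC <- p * n * sum((sweep(sweep(Ygc, 1, Yg), 2, Yc) + mu)^2)
  SS_BC <- a * n * sum((sweep(sweep(Ypc, 1, Yp), 2, Yc) + mu)^2)
  SS_cells <- n * sum((Ygpc - mu)^2)
  SS_ABC <- SS_cells - SS_A - SS_B - SS_C - SS_AB - SS_AC - SS_BC

  dev_sp <- Ysp - outer(Ys, rep(1, p)) -
    Ygp[cbind(gof[rownames(Ysp)], rep(colnames(Ysp), each = nrow(Ysp)))] +
    Yg[gof[rownames(Ysp)]]
  SS_BS <- q * sum(dev_sp^2)
  dev_sc <- Ysc - outer(Ys, rep(1, q)) -
    Ygc[cbind(gof[rownames(Ysc)], rep(colnames(Ysc), each = nrow(Ysc)))] +
    Yg[gof[rownames(Ysc)]]
  SS_CS <- p * sum(dev_sc^2)
  SS_total <- sum((d$psi - mu)^2)
  SS_BCS <- SS_total - SS_A - SS_SA - SS_B - SS_AB - SS_BS -
    SS_C - SS_AC - SS_CS - SS_BC - SS_ABC

  df <- list(A = a - 1, SA = N - a, B = p - 1, AB = (a - 1) * (p - 1),
             BS = (N - a) * (p - 1), C = q - 1, AC = (a - 1) * (q - 1),
             CS = (N - a) * (q - 1), BC = (p - 1) * (q - 1),
             ABC = (a - 1) * (p - 1) * (q - 1),
             BCS = (N - a) * (p - 1) * (q - 1))
  c(group = (SS_A / df$A) / (SS_SA / df$SA),
    pair = (SS_B / df$B) / (SS_BS / df$BS),
    "group:pair" = (SS_AB / df$AB) / (SS_BS / df$BS),
    band = (SS_C / df$C) / (SS_CS / df$CS),
    "group:band" = (SS_AC / df$AC) / (SS_CS / df$CS),
    "pair:band" = (SS_BC / df$BC) / (SS_BCS / df$BCS),
    "group:pair:band" = (SS_ABC / df$ABC) / (SS_BCS / df$BCS))
}

# Amplitude^2/2 of the f0 (Hz) component of x, interior samples only.
power_at <- function(x, fs, f0, trim = round(0.5 * fs)) {
  xi <- x[(trim + 1):(length(x) - trim)]
  xi <- xi - mean(xi)
  k <- seq_along(xi) - 1
  a <- sum(xi * exp(-2i * pi * f0 / fs * k))
  2 * Mod(a)^2 / length(xi)^2
}

# Construct an envelope_set with identical envelopes in all 5 bands from a
# generating function of time (values must be nonnegative).
env_from_fun <- function(fun, duration, env_rate = 1050, n_bands = 5) {
  t <- seq(0, duration - 1 / env_rate, by = 1 / env_rate)
  e <- fun(t)
  envelope_set(matrix(rep(e, n_bands), ncol = n_bands), env_rate,
               edges = c(100, 300, 700, 1750, 3900, 7250))
}

# Tone audio segment helper.
tone_segment <- function(freq, duration = 2, rate = 16800, amp = 1, ...) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  audio_segment(amp * sin(2 * pi * freq * t), rate, ...)
}

# Write a small synthetic cohort to a temp dir; returns synth_cohort output.
tiny_cohort <- function(dir, n = c(illiterate = 1, low_literate = 1,
                                   high_literate = 1),
                        conv_segments = n, rhythmic_segments = 1,
                        duration = 12, rate = 16800, seed = 11, ...) {
  spec <- cohort_spec(n = n, conversational_segments = conv_segments,
                      rhythmic_segments = rhythmic_segments,
                      duration_range = c(duration, duration),
                      rhythmic_duration = duration, rate = rate, seed = seed,
                      ...)
  synth_cohort(spec, dir = dir)
}
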