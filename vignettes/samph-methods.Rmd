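---
title: "Measuring the amplitude-modulation hierarchy of speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the amplitude-modulation hierarchy of speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(samph)
```

## The model

Speech carries quasi-rhythmic energy fluctuations at several nested
timescales: stressed syllables recur at delta rates (0.9–2.5 Hz), syllables
at theta rates (2.5–12 Hz) and phoneme-scale events at beta/low-gamma rates
(12–40 Hz). The S-AMPH representation makes this hierarchy measurable in two
filtering stages:

1. **Spectral stage.** The z-scored waveform is split into five spectral
   bands with adjacent FIR band-passes (edges 100, 300, 700, 1750, 3900,
   7250 Hz; band 1 covers the F0 region). The Hilbert envelope of each band
   — the magnitude of its analytic signal — tracks that band's instantaneous
   amplitude, and is downsampled to 1050 Hz.
2. **Modulation stage.** Each envelope is decomposed by a second FIR
   filterbank into delta, theta and beta/low-gamma AM waveforms.

Two families of measures are derived. The *envelope modulation spectrum*
passes each envelope through 24 log-spaced channels spanning 0.9–40 Hz and
expresses each channel's power as the relative difference from the
cross-channel mean, \((P_c-\bar P)/\bar P\); areas under this differenced
spectrum within the three AM bands summarise where modulation energy
concentrates. The *phase synchronisation index*

\[
\mathrm{PSI} = \bigl|\langle e^{\,i(n\theta_1-\theta_2)}\rangle\bigr|,
\qquad n = 2 \text{ (delta–theta)},\; n = 3 \text{ (theta–beta/low gamma)}
\]

quantifies n:m phase locking between nested AM bands from their
instantaneous phases \(\theta_1\) (slower band, multiplied by \(n\)) and
\(\theta_2\) (faster band). Averaging complex unit phasors makes the
statistic insensitive to phase wrapping and to any constant phase offset;
it ranges from 0 (random rhythm) to 1 (perfect rhythmic regularity).
Per-segment PSIs are means over the five spectral bands, per-participant
values are unweighted means over segments, separately per speech register.
Unweighted aggregation is a deliberate choice: segment durations vary
several-fold and no principled duration weighting presents itself.

## Filter design and numerical choices

All filters are Hamming windowed-sinc FIR designs (via `signal::fir1`)
applied **zero-phase**: the spectrum of the reflect-padded signal is
multiplied by \(|H(f)|^2\), the exact frequency-domain equivalent of
forward–backward filtering, at \(O(n\log n)\) cost for any tap count.
Zero-phase application is load-bearing: the PSI compares instantaneous
phases across independently filtered bands, and any group delay would appear
as spurious (de)synchronisation. The test suite verifies that a click passes
every filter with its cross-correlation peak exactly at lag zero.

Tap counts follow the transition-width rule \(N \approx 3.3 f_s / \Delta f\):

* **Spectral bands**: transition width 25% of each band's lower edge
  (band 1: 25 Hz).
* **AM bands**: transition width 20% of the lower edge with a 1 Hz floor.
  The floor is a resolution compromise — an unfloored rule at the 0.9 Hz
  delta edge would demand a kernel of tens of seconds, longer than any
  conversational segment. The resulting delta kernel is ~3.3 s, and inputs
  shorter than three kernel lengths (~10 s) are rejected as unanalysable.
  The 20% fraction (rather than the spectral stage's 25%) keeps the
  beta/low-gamma band's 12 Hz edge sharp enough to admit modulation content
  near the bottom of that band.
* **Modulation-spectrum channels**: transition width 35% of each channel's
  lower edge, which preserves ≥10× separation between a channel's centre and
  centres two channels away while keeping the slowest kernel ~10.5 s.

Channel powers in the modulation spectrum are normalised by each filter's
equivalent noise power (the mean of \(|H|^4\) over the frequency grid), so a
flat-spectrum envelope produces equal power in every channel. Without this,
log-spaced channels — whose absolute bandwidths span a ~38× range — would
report bandwidth, not spectral shape. Band AUCs integrate the differenced
spectrum against \(\log_{10} f\) (log spacing weights octaves evenly), retain
sign, and insert the exact band boundaries by interpolation so that the
delta + theta + beta/low-gamma areas partition the full-range area to
machine precision.

Other numerical conventions: envelopes are clipped at zero after resampling
(anti-alias ringing can produce small negative values); resampling uses an
anti-alias low-pass at 45% of the target Nyquist, integer decimation, and a
rational polyphase stage for non-integer ratios (denominator ≤ 1000);
z-scoring uses the population standard deviation (a fixed signal is being
standardised, not a sample estimating a population); 0.5 s is trimmed from
each end of phase series and channel outputs before averaging, dropping
filter edge transients; constant signals, silent envelopes, all-zero AM
waveforms and too-short inputs raise immediate errors rather than produce
numbers.

## The synthetic generator

The generator provides ground truth the field's recordings cannot: audio
whose AM hierarchy is known exactly. Per spectral band a carrier is
multiplied by the product of three modulator waveforms \(1 + d\cos\phi\):
the delta phase advances at \(f_\delta\), the theta phase is
\(2\phi_\delta\) plus slowly varying von Mises jitter of concentration
\(\kappa_{dt}\), and the beta/low-gamma phase is \(3\phi_\theta\) plus
jitter of concentration \(\kappa_{tbg}\). Under i.i.d. von Mises jitter the
population PSI is the Bessel ratio \(I_1(\kappa)/I_0(\kappa)\), giving every
upstream stage a closed-form target. Jitter is a band-limited (< 0.5 Hz)
Gaussian process mapped through the von Mises quantile function: the
marginal distribution is exactly von Mises while the variation stays slow,
as i.i.d. jitter at 1050 Hz would be unfilterable broadband noise and
speech-like desynchronisation is slow. \(\kappa = 0\) switches to a fully
independent modulator at its own nominal rate (5 Hz theta, 20 Hz
beta/low-gamma); \(\kappa = \infty\) is deterministic locking.

Three design choices deserve explanation:

* **Modulator geometry.** Exact 2:1 and 3:1 locking forces the beta/low-gamma
  modulator to \(6 f_\delta\). For all three modulators to sit inside their
  AM bands, \(f_\delta\) must lie in (2, 2.5) Hz; the default is 2.25 Hz
  with ±4% per-realisation jitter (enough to stay off exact filterbank
  edges, small enough to keep \(6 f_\delta\) inside 12–40 Hz).
* **Carriers.** The default carrier is a constant-modulus random-phase
  carrier: band-passed Gaussian noise reduced to its phase. Raw Gaussian
  carriers have Rayleigh envelope fluctuations spread across the carrier
  bandwidth; in the narrow low spectral bands this intrinsic modulation
  noise swamps the imposed phoneme-rate AM, making coupling recovery
  untestable. With a constant-modulus carrier the imposed modulator product
  *is* the band envelope. A `"gaussian"` mode retains the noisy-carrier
  behaviour (useful as realistic measurement noise) and a `"tones"` mode
  gives closed-form tests.
* **Depths.** Default modulation depths are (0.3, 0.25, 0.25) for
  delta/theta/beta. Product modulators create intermodulation lines — e.g.
  \(\cos(\phi_\theta-\phi_\delta)\) sits exactly at \(f_\delta\) and carries
  the coupling jitter — which coherently bias recovered phases; the bias
  scales with the co-modulators' depths, so depths are kept shallow enough
  that it stays second-order.

Cohorts are simulated by drawing each participant's target PSI from a group
distribution (defaults: three groups of 15/19/12 participants with
89/107/90 conversational segments — 286 in total, a mean of 6.2 per
participant — plus rhythmic segments; the illiterate group's conversational
coupling is set lower, while rhythmic-register coupling is high and equal
across groups), converting the target to \(\kappa\) by inverting the Bessel
ratio, and synthesising per-segment audio. Behavioural covariates are drawn
from the published group means and standard deviations. Group-level PSI
levels themselves are calibration choices: the source figures are graphical
only. A summary-level twin (`simulate_cohort_summaries()`) draws
participant-level measures directly for statistical calibration at
thousands of replicates. Conversational segment durations default to
12–20 s: the delta AM kernel and the lowest modulation-spectrum channel
need ~10 s of support, so the short end of naturalistic segment durations
(and 1–3 s proverb utterances) is not analysable at this resolution — the
generator's rhythmic "segments" should be read as proverb *sequences*.

What the generator does **not** emulate: formant structure, phones or
phonotactics; pauses and silences within segments; f0 declination; any
correlation between behavioural scores and acoustics within a group.
Passing tests therefore demonstrate that the measurement chain recovers
known coupling from signals with speech-like AM statistics — not that it
behaves identically on real recordings.

## Validation design and what it shows

The acceptance suite (in `tests/testthat/test-acceptance.R`) checks, with
fixed seeds and stated problem sizes:

* **PSI anchors**: exactly 1 for 2:1-locked series; in [0, 1] always; mean
  \(\sqrt{\pi/4T}\) for independent uniform phases (200 replicates).
* **Coupling recovery**: across \(\kappa \in \{0.5, 1, 2, 4, 8\}\), the
  pipeline-recovered delta–theta PSI from full synthetic audio (four 30 s
  replicates per \(\kappa\) at 16.8 kHz — the analysis is rate-invariant
  above twice the top spectral edge since envelopes land at 1050 Hz) is
  strictly increasing in \(\kappa\) and within ±0.1 of the ground-truth-phase
  PSI. Replicates share random numbers across the \(\kappa\) grid (the same
  underlying jitter process mapped through each \(\kappa\)'s quantile
  function), a variance-reduction design that makes the true coupling
  pathwise monotone in \(\kappa\).
* **Theta–beta/low-gamma recovery** is checked for strict monotonicity only.
  Its absolute level reads low through the chain: theta-phase errors are
  tripled by \(n = 3\), and the 3:1-locked modulator at
  \(6f_\delta \approx 13.5\) Hz has phase-modulation sidebands that the
  12 Hz band edge truncates. This is a structural property of measuring
  3:1 coupling in these band geometries, not an implementation defect;
  between-condition *differences* in theta–beta/low-gamma PSI remain
  interpretable, absolute values should not be compared with the Bessel
  ratio.
* **Modulation-spectrum identities**: per-band differenced spectra are
  mean-zero to 1e−9; a 5 Hz-modulated envelope peaks in the channel nearest
  5 Hz; band AUCs partition the full-range AUC to 1e−9.
* **Statistical calibration**: under a null cohort (no group differences)
  the MANOVA rejects at α = 0.05 in 5% ± 2% of 1000 summary-level
  replicates; a 0.08 PSI group gap with 0.04 within-group SD at the study's
  group sizes is detected in ≥80% of 100 replicates.
* **Qualitative cohort pattern**: a full-audio cohort (5/5/5 participants,
  two conversational and two rhythmic 12 s segments each) built with low
  illiterate-group coupling shows the illiterate group below both literate
  groups for conversational speech and no such deficit for rhythmic speech.

## Known limitations

* Absolute theta–beta/low-gamma PSI is attenuated by the chain (above).
* Delta-band estimates from segments near the 10 s minimum rest on a handful
  of delta cycles and are accordingly noisy; the lowest modulation-spectrum
  channels share this caveat.
* The MANOVA/ANOVA layer assumes approximate normality of participant-level
  PSI; the non-parametric tests are provided for the behavioural scores,
  which are bounded and skewed.
* The repeated-measures ANOVA reports conventional uncorrected degrees of
  freedom by default; Greenhouse–Geisser correction is available via
  `adjust = "greenhouse-geisser"` and is advisable for the five-level
  spectral-band factor.
* WAV input is limited to integer PCM and IEEE float encodings; compressed
  audio must be converted externally.
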