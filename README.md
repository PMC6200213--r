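# samph

Tools for analysing the **temporal modulation structure of speech**: how
energy in the speech signal rises and falls at the timescales of stressed
syllables (delta rate, 0.9–2.5 Hz), syllables (theta rate, 2.5–12 Hz) and
phonemes (beta/low-gamma rate, 12–40 Hz), and how tightly these nested
amplitude modulations (AMs) are phase-coupled to one another. Measures of
this kind are used in the cognitive neuroscience of language to compare
speech registers and speaker populations — for example conversational versus
deliberately rhythmic speech, or speakers differing in literacy — because the
AM hierarchy of speech mirrors the delta/theta/gamma hierarchy of neuronal
oscillations that encode it.

## What it computes

**S-AMPH decomposition** (Spectral–Amplitude Modulation Phase Hierarchy).
Each z-scored speech segment is band-pass filtered into five spectral bands
(channel edge frequencies 100, 300, 700, 1750, 3900, 7250 Hz) with zero-phase
FIR filters; the Hilbert envelope of each band is extracted and downsampled
to 1050 Hz; a second zero-phase FIR filterbank isolates the delta, theta and
beta/low-gamma AM components of each envelope.

**Envelope modulation spectrum.** Each envelope is passed through a 24-channel
FIR filterbank with channels logarithmically spaced over 0.9–40 Hz. Channel
power is expressed as the relative difference from the cross-channel mean,
`D_c = (P_c − P̄) / P̄`, averaged over the five spectral bands; band energies
are areas under this differenced spectrum over the three AM bands (signed,
integrated against log frequency, so the three bands partition the full-range
area exactly).

**Phase synchronisation index.** For each spectral band the coupling between
nested AM pairs is

&nbsp;&nbsp;&nbsp;&nbsp;PSI = | ⟨ e^{ i (n·θ₁ − θ₂) } ⟩ |

where θ₁, θ₂ are the instantaneous (Hilbert) phases of the slower and faster
AM and n is the integer frequency ratio between them: n = 2 for delta–theta,
n = 3 for theta–beta/low gamma. PSI is 0 for a sound random in rhythm and 1
for perfect rhythmic regularity. PSIs are averaged over the five spectral
bands per segment and over segments per participant, separately for
conversational and rhythmic speech.

**Cohort statistics.** Speech rate (syllables/second from manual counts),
MANOVA with Wilks' Λ and partial η², mixed-design repeated-measures ANOVA
(AM band pair × spectral band × group, with a Greenhouse–Geisser option),
Tukey–Kramer post hocs, Spearman/Pearson correlations with Bonferroni
adjustment, and Kruskal–Wallis / Mann–Whitney tests with a Shapiro–Wilk
normality gate.

**Synthetic ground truth.** Because recorded cohorts are rarely shareable,
the package includes a generator of speech-like signals whose AM hierarchy is
known exactly: per-band carriers modulated by nested delta/theta/beta
modulators whose phase coupling is controlled by von Mises concentrations
(κ), so the expected PSI is the Bessel ratio I₁(κ)/I₀(κ). Whole cohorts with
prescribed group-level coupling differences can be simulated, both as audio
(WAV + manifest) and at summary level for statistical calibration.

## Worked example

Synthesise a 20 s speech-like segment whose delta–theta and
theta–beta/low-gamma couplings are both set to κ = 4 (expected PSI
I₁(4)/I₀(4) = 0.864), then run the full measurement chain:

```r
library(samph)

spec <- synth_spec(duration = 20, rate = 44100,
                   kappa_dt = 4, kappa_tbg = 4, seed = 42)
out <- synth_segment(spec)
round(out$truth$true_psi_dt, 3)   # PSI of the generator's true phases: 0.929
res <- analyze_segment(out$segment)
res$psi
#> psi_result: delta-theta 0.924, theta-beta/low-gamma 0.756 (mean over 5 spectral bands)
res$energy
#> band_energy (AUC of differenced modulation spectrum, cross-band mean):
#>          delta          theta beta_low_gamma
#>         0.1433         0.2287        -0.3064
```

The recovered delta–theta PSI (0.924) matches the PSI of the generator's
true phases for this realisation (0.929); the theta–beta/low-gamma estimate
reads lower than the true coupling because phase errors on the theta AM are
tripled by n = 3 (see the methods vignette). The positive delta and theta
band energies reflect the imposed ~2.25 Hz and ~4.5 Hz modulators.

Cohort-level use follows the same pattern from the command line:

```sh
Rscript inst/cli/samph.R simulate --out cohort/ --seed 7 --groups 3,3,3
Rscript inst/cli/samph.R analyze  --manifest cohort/manifest.csv --out results/
Rscript inst/cli/samph.R stats    --participants results/participants.csv --out results/
```

`analyze` writes per-segment and per-participant CSVs (PSI per band pair and
spectral band, band energies, speech rate); `stats` writes the MANOVA /
repeated-measures ANOVA / post-hoc / correlation report as JSON and text.

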