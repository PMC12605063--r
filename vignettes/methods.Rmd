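---
title: "Models, simulation and numerical choices in chordaffect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation and numerical choices in chordaffect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The experiment being modelled

Participants hear isolated four-note piano chords — consonant (major
triads in root position or six-four voicing), dissonant (fixed patterns
of tritones and minor seconds on the same diatonic roots), or neutral
metronome clicks — and categorise each sound as pleasant, unpleasant or
neutral while 64-channel EEG is recorded at 500 Hz against an FCz
reference. Each of the 42 stimuli is presented five times in seeded
random order with 200–300 ms inter-stimulus intervals. A trial is
*congruent* (scored accurate) when the response matches the a-priori
category: consonant→pleasant, dissonant→unpleasant, neutral→neutral.

## 2. Stimulus construction

Pitch is 12-tone equal temperament anchored at A4 = 440 Hz. This anchor
is a design decision: only rounded octave endpoints (130.8–246.9 Hz,
261.6–493.9 Hz) are fixed by the protocol, and 440-based equal
temperament reproduces all of them to one decimal. Chord voicings that
would dip below C3 are raised one octave, which reproduces the published
six-four spellings (G–C–E–G, A–D–F#–A) and keeps every note within
C3–B4. The second dissonant pattern is encoded as cumulative offsets
{0, 1, 6, 12}: the protocol's verbal rule and its C and D examples agree
on this pattern, while its E example implies {0, 1, 5, 12}; the
consistent pattern is implemented and the discrepancy simply noted.

Timbre is a reproducible stand-in for a sampled grand piano: 8 harmonics
with 1/h amplitude rolloff, exponential decay with t60 ≈ 1 s at the
fundamental and faster decay for higher harmonics, 5 ms cosine ramps.
"Normalised in amplitude" is realised as equal RMS across stimuli
(within 1%); no loudness model is attempted. Clicks default to 14
pitches (the natural diatonic tones of both octaves, balancing the
other stimulus classes); their count is configurable because the
protocol does not state it.

## 3. The synthetic EEG generator

`simulate_recording()` adds four components, all seeded and pure in
their arguments:

* **ERP kernels.** Per condition, a sum of Gaussian-in-time components
  (N1 at 100 ms, σ = 12 ms, centred on Cz; P2 at 200 ms, σ = 15 ms, Cz;
  P3 at 300 ms, σ = 20 ms, Pz) spread across channels with a Gaussian
  falloff in great-circle distance. Default amplitudes (µV, N1/P2/P3):
  consonant −3.0/2.5/2.5, dissonant −3.5/4.0/5.0, neutral −2.5/2.0/3.0 —
  dissonant strongest at P2/P3, the contrast the cluster test is meant
  to detect at n = 30 with default noise. These sizes were fixed once by
  pilot simulation, before the acceptance experiments were run.
* **Band oscillations.** Eight spatial sources per band (alpha/beta/
  gamma at 4/2/1 µV), each a band-limited unit-variance noise carrier
  multiplied by a strictly positive envelope exp(0.3·fGn) with Hurst
  exponent 0.7. The fractional Gaussian noise is synthesised spectrally
  (power ∝ f^(1−2H), random phases) and low-passed at 2 Hz before the
  exponential: a scale-free full-band series is not a physically
  possible amplitude envelope for a narrowband rhythm (a carrier cannot
  transport modulation faster than its own bandwidth), and the low-pass
  leaves detrended fluctuations at the 5–50 s DFA scales — hence the
  exponent — untouched.
* **1/f background**, 10 µV RMS per channel, independent across
  channels.
* **Blinks** (off by default): Poisson events with a 300 ms biphasic
  waveform on a frontal spatial map, used to exercise the FastICA path.

What the generator deliberately does **not** emulate: volume conduction
from dipolar sources (spatial maps are smooth Gaussians, not forward
fields), electrode drift and line-noise nonstationarity, trial-to-trial
latency jitter, trial exclusions, and subject-level ERP amplitude
variability (the between-subject variance in window maps comes from
finite-trial noise only). A green test therefore establishes that the
*estimators* behave as specified on data with the assumed statistical
structure — not that the pipeline is robust to every pathology of real
recordings.

The behavioural generator draws congruency from the same mixed-effects
logistic model the analysis fits (section 6 below), so parameter
recovery is a
well-posed exercise; type intercepts derive from the congruent-response
probabilities (defaults 0.75/0.70/0.60 for consonant/dissonant/neutral),
and reaction times are log-normal with the six reported type ×
congruency means (464/522/747 ms congruent, 1158/1123/688 ms
incongruent) and σ_log = 0.35.

## 4. Preprocessing

Stage order: downsample to 250 Hz → zero-phase 2nd-order Butterworth
45–55 Hz band-stop → 1–45 Hz band-pass (4th order; the band-pass order
is unstated in the protocol and 4th-order is common practice) → common
average reference → bad channels (|amplitude| > 100 µV at any sample,
plus an optional |z| > 3 log-power rule; flagged channels are dropped,
not interpolated) → FastICA ocular cleaning → −100…800 ms epochs
baselined on −100…0 ms. ICA runs after downsampling, following the
protocol's own motivation for downsampling.

Butterworth filters are designed from first principles (analog
prototype, band transforms, bilinear transform) because no DSP package
is available in the target environment; the design was verified
coefficient-exact against an independent reference implementation during
development, and the suite asserts the behavioural contracts
(attenuation, passband flatness, zero group delay).

FastICA is the deflationary fixed-point algorithm with tanh contrast on
whitened data. A component is removed only when its spatial pattern
correlates with a frontal template (>0.7) **and** its time course
correlates with detected blink events (>0.5). Blink detection uses a
robust z > 8 threshold on the 1–10 Hz frontal average — ocular
deflections are an order of magnitude above background there — and when
no blinks are detected the ICA pass is skipped entirely: the rejection
rule is then unsatisfiable, and the recording passes through unchanged.

One numerical caveat the tests encode explicitly: the 1 Hz high-pass
removes about 14% of the energy of a σ = 20 ms Gaussian P3 bump, so the
noise-free pipeline output correlates >0.99 with the template *passed
through the same filters* but only ≈0.97 with the raw template. This is
a property of the stated filter, not an implementation defect.

## 5. ERP statistics

GFP is the spatial standard deviation of the grand average at each time
point. Analysis windows are ±10 ms around the three most prominent
post-stimulus GFP peaks (prominence in the topographic sense: height
above the higher of the two flanking bases; ties broken by earlier
latency). The unit of observation for contrasts is the per-subject,
per-channel mean over a window.

The cluster test forms per-channel Wilcoxon signed-rank z statistics on
paired condition differences, thresholds them at two-sided p < 0.05
(the cluster-forming threshold is unstated in the protocol; this is the
conventional default), groups suprathreshold channels of common sign
into connected components of the adjacency graph, and uses cluster mass
Σ|z|. The null distribution is the maximum mass over random
within-subject condition swaps (sign flips), 800 permutations by
default, with the add-one permutation p — valid and FWER-controlling by
construction. Adjacency connects channels within a great-circle
threshold chosen so the median neighbour count is ≈6, because no cap
adjacency file exists; the montage itself is an idealised 10–20
construction on the unit sphere (rows every 10% of the nasion–inion
arc), adequate for adjacency and smooth spatial weighting but not a
digitised cap.

## 6. Band dynamics and the accuracy model

Per channel and band: zero-phase 4th-order Butterworth band-pass, the
Hilbert (analytic-signal) envelope, its mean as the amplitude, and DFA
of the envelope: integrate the mean-centred series, detrend linearly in
50%-overlapping windows at 10 log-spaced sizes between 5 and 50 s, and
regress log10 RMS fluctuation on log10 window size. With only one decade
of window sizes the single-realisation estimator has Monte-Carlo sd
≈0.034 on white noise; the tests therefore assert tolerances on means
over a few fixed-seed realisations rather than widening the tolerance.
Channel-level values are reduced to subject scalars by the
across-channel mean (the reduction is unstated in the protocol; a
configurable electrode subset is provided).

The accuracy model is a binomial-logit GLMM: stimulus type (reference
consonant) × one standardised neural predictor, with a subject random
intercept, uncorrelated per-type subject slopes, and item random
intercepts. Estimation is maximum likelihood via the Laplace
approximation (lme4 backend behind the package's own model surface);
`random = FALSE` constrains all variances to zero, reducing the model
exactly to plain logistic regression — the invariant the tests check
against a hand-rolled IRLS oracle. Model comparison uses likelihood
ratios; effects are reported as odds ratios with Wald 95% CIs, flagging
intervals whose upper/lower ratio exceeds 10³ as numerically extreme.

## 7. Known limitations

* Integer-factor downsampling only (the chain needs only 500→250 Hz).
* Spatio-temporal (time-resolved) clustering, the rank-correlation
  cluster variant, and source reconstruction are out of scope.
* The generator's envelope positivity transform biases the envelope DFA
  exponent slightly toward 0.5 (the suite allows ±0.10 after the
  transform, ±0.05 for raw fGn).
* A raw sample-wise correlation between an imposed envelope and the
  recovered Hilbert envelope of a *noise* carrier is bounded near 0.5
  by the carrier's Rayleigh-distributed modulus; envelope-tracking
  tests therefore smooth the Hilbert envelope at the modulation
  timescale before comparing.
* Heavier Monte-Carlo suites (GLMM recovery, permutation FWER/power)
  run at reduced replicate counts in the test suite, with the original
  statistical tolerances; the acceptance script runs the full-size
  30-subject GFP experiment.
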