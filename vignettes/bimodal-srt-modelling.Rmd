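---
title: "Modelling speech reception thresholds of bimodal CI listeners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling speech reception thresholds of bimodal CI listeners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bimodal listeners combine a cochlear implant (CI) on one ear with a hearing
aid (HA) on the other. Their speech-in-noise performance, and how much a
hearing-aid beamformer helps them, depends on an interaction of spatial
acoustics, device signal processing, and two very different modes of
hearing: broadband acoustic hearing shaped by a sloping hearing loss, and
electric hearing that transmits mostly temporal envelopes in a few
frequency channels. `bimodalsrt` implements two complementary model chains
that each map a spatial listening scenario to a predicted speech reception
threshold (SRT), so that predictions can be cross-checked against each
other and against an instrumental SNR metric.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test bench does and
does not show.

# The synthetic test bench

**Corpus.** Matrix sentence tests use a fixed syntax (name, verb, number,
adjective, object) with 10 alternatives per slot. The licensed recordings
of real matrix tests cannot be shipped, so each vocabulary word is a
deterministic synthetic token: a harmonic complex (f0 between 90 and
258 Hz) with a word-specific three-formant spectral envelope, 300–500 ms
long, with raised-cosine edges and slow amplitude modulation. Tokens are
acoustically distinct per word identity — which is what a whole-word
recognizer needs — while sharing a broadly speech-like long-term spectrum.
Per-utterance f0 (±3 %) and level (±1 dB) jitter emulates the intrinsic
variability of words recorded several times. `generate_corpus()` enforces
exact balance: every word occurs `n_sentences / n_alternatives` times
(12 times for the default 120 sentences).

**Maskers.** `make_speech_shaped_noise()` shapes Gaussian noise to the
one-third-octave-smoothed long-term spectrum of the concatenated corpus
(the standard construction of matrix-test noise).
`make_babble()` sums four independent sentence-stream permutations per
stream; five such streams from five azimuths form the diffuse 20-talker
scenario.

**Head model.** Measured behind-the-ear HRIRs are replaced by a parametric
4-microphone model: Woodworth-type ITD with `itd_max = 700` µs, a
first-order head-shadow low-pass giving up to 12 dB broadband ILD at ±90°,
and 1 cm front/rear microphone spacing per side. This preserves exactly the
cues the two beamformers exploit (interaural and front/rear phase, level
differences, diffuse-field coherence) while remaining analytic — left/right
mirror symmetry holds to numerical precision, which the tests use. Measured
4-channel impulse responses can be substituted via `head_model(hrir = )`.
An optional exponential reverberation tail exists and is off by default;
the scenarios are therefore anechoic, unlike a real cafeteria.

**SNR convention.** Spatial-scenario SNRs need a reference point that the
scenario definitions themselves leave open; we define it over speech-active samples
(envelope above −40 dB re max), averaged across the two *front*
microphones, and calibrate every mixture to ±0.1 dB by construction.

# Front end

**ADM.** Per side, fixed front/rear cardioids are formed by
delay-and-subtract with the acoustic travel-time delay of the 1 cm spacing;
the output is `y = cF − β·cB` with β adapted per 8 ms block by a normalized
gradient step (step size 0.1) on the output energy and clamped to [0, 1] so
the null stays in the rear half-plane. The adaptation constants are not
standardized anywhere; both are configuration. The test suite checks the
converged β against a brute-force energy grid search.

**MVDR.** A fixed binaural beamformer: per STFT bin,
`w = Σ⁻¹d / (dᴴΣ⁻¹d)` with the steering vector `d` taken from the head
model's frontal transfer function (normalized to the reference front
microphone of each side, so each output preserves that ear's frontal
response) and `Σ` the spherically isotropic diffuse-field coherence
`sinc(2πf·d_ij/c)` of the microphone geometry, diagonally loaded at
`1e-3·trace/N`. Processing uses a 256-point STFT with sqrt-Hann
analysis/synthesis at 50 % overlap (exact COLA).

**HA compression.** Nine complementary log-spaced bands (exact
reconstruction by construction), one-pole level tracking with 20 ms attack
and 100 ms release, and a CAMFIT-style prescription: linear insertion gain
proportional to the hearing loss (0.48 dB/dB), computed from HL capped at
90 dB, with no gain prescribed at or above 5 kHz — the modification used
for bimodal fittings, where only low-frequency residual hearing is worth
amplifying. Compression ratio 2:1 above a 50 dB SPL knee.

**Separation.** `hagerman_separate()` implements phase inversion: process
`s+n` and `s−n`, then half-sum and half-difference. For linear chains the
recovery is exact; for any chain the re-addition identity
`speech_hat + noise_hat = P(s+n)` holds to numerical precision, which is
the invariant the SII chain relies on.

# Feature pathways

**Acoustic (HA side).** 31-band log-Mel spectrogram (25 ms frames, 10 ms
shift, normalized Hamming window, FFT = next power of two ≥ frame length,
HTK Mel formula), calibrated so a full-scale sinusoid reads 100 dB SPL
(configurable). Hearing loss is simulated by audibility gating: features
are expressed relative to the listener's threshold (a tabulated standard
threshold-of-hearing curve plus the interpolated audiogram) and strictly
sub-threshold cells are replaced by unit-variance Gaussian noise, so the
recognizer cannot use inaudible energy. Ties at threshold are kept. The
default audiogram is a synthetic moderate-to-severe sloping loss standing
in for a bimodal study population's average HA ear.

**Electric (CI side).** The ACE strategy analyses 128-sample Hann frames
(8 ms at 16 kHz) at the 900 pps channel rate (frame advance 16000/900
samples with rounding-based drift compensation, i.e. 6.89 ms overlap),
groups FFT bins 2–63 into 22 quasi-log channels, takes each channel's
envelope as the magnitude of the complex bin sum, selects the 8 largest
(ties toward the lower channel), and maps envelopes log-compressively
(steepness 416.2) from the base (4/256 of full scale) to saturation
(150/256) onto the electrode's THL–MCL current range (defaults 100/200
clinical units; the clinical values of the modelled population are not
published, so these are configuration). Pulses are sequenced base-to-apex
within each cycle at the 7200 pps total rate. A microphone-sensitivity
gain (default 20, i.e. 26 dB) maps conversational input levels onto the
envelope range, as a CI processor's front-end AGC would.

Currents spread along the 35 mm cochlea as `exp(−|x−x_e|/λ)` with
λ = 1 mm (36.8 % one millimetre away); 2200 equidistant cells each run an
event-driven leaky integrate-and-fire membrane (τ = 0.5 ms, threshold 1
drive unit with 1/120 clinical-unit scaling, 0.5 ms absolute refractoriness
followed by an exponentially recovering threshold elevation with τ = 1 ms,
5 % membrane noise, 0.5 ms latency, 50 µs spike jitter). The published
source of this model's parameter table is outside what ships here, so all
are configuration with those defaults. The "internal representation" bins
spikes into 46 spatial groups (see below), smooths each group with a 2 ms
Gaussian FIR and a 10 ms recursive integrator, samples the result on the
10 ms acoustic frame grid, and multiplies by Gaussian noise with mean 1
and variance 0.1 (central degradation). Features are z-scored with
training-set statistics.

**Group-count choice.** The source material is internally inconsistent
about the electric feature dimension (22 groups — one per electrode — vs a
stated dimensionality of 46). We default to 46 groups so the concatenated
acoustic+electric dimension is the printed 77; 22 is available via
`ir_config(n_groups = 22)`.

# Recognition chain and SRT

Whole-word HMMs: 8 emitting states per word (2 in the desk profile), 6 for
silence, 3 each for the start/end models, strictly left-to-right, one
diagonal-covariance Gaussian per state with a variance floor of 1e-3.
Because the synthetic corpus carries exact word boundaries, each word model
is trained on its own segments by Baum-Welch from a flat start (uniform
segmentation) to convergence (relative log-likelihood change < 1e-4, max
20 iterations); embedded re-alignment would add cost without information.
Decoding runs a Viterbi pass over the composed grammar
start · slot1 … slot5 · end with 10 parallel word models per slot —
the closed-set a-priori structure of a matrix test. Scoring is words
correct out of 5 per sentence.

`run_grid()` mixes fresh noise instances per training mixture (8 at full
scale → 960 training sentences per train SNR; 2 at desk scale) and one
held-out instance for testing, over the condition's SNR range in 3 dB
steps (the full-scale ranges per scenario and beamformer are tabulated in
`default_snr_range()`). `extract_srt()` finds, per training row, the first
upward 50 % crossing along the test axis by linear interpolation and
returns the minimum over rows — the "lowest testing SNR with 50 %"
criterion taken literally; whether the original implementation scans rows
or the matrix diagonal is not documented, and the row-minimum reading is
our choice. A matrix whose rows never cross raises an "SRT outside grid"
error, mirroring the range-adjustment workflow.

# SII chain

Because a macroscopic SII model only sees long-term spectra, the speech
input is speech-shaped noise with the corpus spectrum. The scene is mixed,
the beamformer+HA chain applied via phase inversion, and the CI side
auralized: ACE envelopes, mixed across electrodes by the current-spread
function, re-modulate tone carriers at the electrode-mapped frequencies —
a vocoder that deliberately destroys temporal fine structure, which is why
the EC path cannot win on the CI side at high frequencies.

Band analysis uses 30 ERB-spaced 4th-order gammatone bands (146–8000 Hz),
1024-sample short-term windows, profile averaged over windows. The EC
stage grid-searches interaural delay (±10 ms, 0.25 ms steps) and gain
(±40 dB, 2 dB steps) per band using closed-form residual powers from
cross-correlations; EC processing inaccuracies are applied
deterministically as the first-order expected residual — amplitude jitter
of 1.5 dB and time jitter of 105 µs add
`(σ_a² + (2πf σ_δ)²) · (P_L + g²P_R)` to both speech and noise residuals —
rather than by Monte-Carlo draws, keeping the chain deterministic. Band
SNRs are capped at +40 dB. The acoustic side additionally vetoes bands
whose speech level falls below the listener's threshold.

Per band the best of left / right / EC is taken; acoustic and electric
profiles are combined by an electro-acoustic weighting (acoustic full
weight below 1 kHz, electric above, linear crossfade over one octave; a
band whose only audible side carries zero weight falls back to that side
unweighted, and a unit-weight mode exists). SII is the importance-weighted
mean band audibility `clip((SNR+15)/30, 0, 1)` with uniform importance by
default. `find_srt_sii()` bisects a broadband speech gain until the SII
meets the side's reference — 0.26 for acoustic-only listening, 0.42 for
CI listening, the empirical anchors of this model family; for bimodal
listening the reference of the side dominating the combined profile is
used and flagged, since the original combination rule is under-specified.
Band SNRs shift linearly with broadband speech gain for separated signals,
so the bisection operates on the measured profile directly (exact, fast).

# Problem sizes and determinism

The test suite and the acceptance script run a "desk" profile chosen as
the package's standard small-scale configuration: 10 sentences (one
occurrence per word), 2 training mixtures, 2-state word models, 220 nerve
cells, train SNRs {−21, −9} dB and test SNRs −33…−3 dB in 6 dB steps.
These sizes keep a complete two-beamformer recognition experiment in the
minutes range on one core while still exercising every stage at full
fidelity; the `full` profile restores the study-scale numbers (120
sentences, 8 mixtures, 8 states, 2200 cells, 3 dB grids). All generators
and the spiking model are bit-reproducible under a fixed seed (the RNG
state is saved and restored around every stochastic stage, and sub-streams
are derived deterministically from the master seed).

# What the synthetic bench does and does not show

Passing tests demonstrate internal correctness (oracle equivalences,
calibration, balance, reproducibility) and qualitative behaviour: the MVDR
and ADM improve instrumental SNR in lateral-noise scenes, both model
chains predict lower (better) SRTs with the MVDR than without beamforming
in `S0N-90`, and recognition collapses to the 10 % slot-chance level in
pure noise. They do not validate against human data: synthetic tokens are
not intelligible speech, the head model is anechoic, the default audiogram
and CI maps are synthetic stand-ins, and desk-scale SRTs are several dB
from what real corpora yield. Quantitative agreement with patient SRTs
requires the real recordings, measured HRIRs and individual fittings,
which are outside this package by design.

# Known limitations

- Stationary-noise logic throughout: the SII chain has no modulation-domain
  extension, so fluctuating-masker benefits are underestimated.
- The EC inaccuracy model is a first-order expectation, not a draw-level
  simulation; it slightly underestimates degradation for very large
  equalization gains.
- The whole chain is fixed at 16 kHz; inputs at other rates must be
  resampled by the caller.
- `spread_current()` materializes a dense pulses-by-cells matrix and is
  meant for analysis at small scale; the simulation path spreads currents
  internally.
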