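# bimodalsrt

Speech-in-noise modelling for **bimodal cochlear-implant listeners** — people
who wear a cochlear implant (CI) on one ear and a hearing aid (HA) on the
other. The package predicts **speech reception thresholds** (SRT: the SNR at
which a listener scores 50 % of words correct on a matrix sentence test) and
the benefit of hearing-aid **beamformers**, with two independent model
chains plus an instrumental signal metric:

1. **Recognition chain (FADE-style).** A virtual spatial scene (frontal
   matrix-sentence target, lateral or diffuse maskers, a 4-microphone head
   model) is processed by a beamformer (none / adaptive differential
   microphone / binaural MVDR) and by device simulations: multiband
   compression with a CAMFIT-style prescription on the HA side, the ACE
   n-of-m coding strategy plus a stochastic integrate-and-fire
   auditory-nerve population on the CI side. The acoustic features
   (31-band log-Mel spectrogram gated by audibility against the listener's
   audiogram) and electric features (the spatially/temporally integrated
   nerve activity, 46 groups) are concatenated (dimension 77) and fed to a
   whole-word HMM recognizer trained and tested over a train-by-test SNR
   grid; the SRT is the lowest test SNR reaching 50 % words correct.
2. **SII chain (BSIM-style).** Separated speech and noise are pushed
   through the same (adaptive, nonlinear) front end using the
   Hagerman–Olofsson phase-inversion trick, the CI side is auralized by an
   ACE/current-spread vocoder, and per-gammatone-band SNRs of the left,
   right and binaural equalization–cancellation (EC) paths are combined by
   an electro-acoustic weighting into a speech intelligibility index
   (SII = Σᵢ wᵢ · clip((SNRᵢ+15)/30, 0, 1)). The SRT is found by bisecting
   a broadband speech gain until the SII hits the side's reference value
   (0.26 acoustic, 0.42 CI).
3. **Instrumental SNR benefit.** Output-minus-input broadband SNR of a
   beamformer chain, via phase-inversion separation.

All inputs are synthetic and generated by the package itself: a balanced
five-slot matrix corpus (10 alternatives per slot; every word occurs
n/10 times) with deterministic harmonic-complex word tokens, speech-shaped
stationary noise with the corpus long-term spectrum, 20-talker-style
babble, and a parametric head model (Woodworth ITD, frequency-dependent
head shadow, 1 cm front/rear microphone spacing).

## Worked example

A desk-scale run (10 sentences, 220 nerve cells, 2-state word models,
coarse SNR grid) of the recognition chain in the `S0N-90` scene — target in
front, speech-shaped noise at −90° — with and without the binaural MVDR:

```r
library(bimodalsrt)

corp <- generate_corpus(default_vocabulary(10), 10, seed = 1)
cfg  <- pipeline_config(pop = nerve_population(n_cells = 220))
hmm  <- hmm_config(states_word = 2, states_sil = 2, states_edge = 1)
grid <- snr_grid(train_snrs = c(-21, -9), test_snrs = seq(-33, -3, 6),
                 n_train_mixtures = 2)

rm_nobf <- run_grid(corp, "S0N-90", "NoBF", grid, cfg, hmm, seed = 1)
print(rm_nobf)
#> Recognition matrix (S0N-90, NoBF), % words correct:
#>      test
#> train -33 -27 -21 -15 -9 -3
#>   -21  12   4  20  16  8 10
#>   -9    8   4  18  18 78 68
extract_srt(rm_nobf)     # -11.8 dB

rm_mvdr <- run_grid(corp, "S0N-90", "MVDR", grid, cfg, hmm, seed = 1)
extract_srt(rm_mvdr)     # -22.3 dB
srt_benefit(-11.8, -22.3)  # 10.5 dB MVDR benefit
```

Each matrix cell is the percentage of correctly recognized words when an
HMM set trained at the row's SNR decodes sentences mixed at the column's
SNR; performance peaks near the training SNR and collapses toward the
10 % slot-chance level in heavy noise. The MVDR cancels the lateral noise
and shifts the whole psychometric surface to lower SNRs, here by ~10 dB.
The SII chain gives the same ordering in seconds:

```r
bsim_predict(corp, "S0N-90", "NoBF", cfg, seed = 1)  #  -9.8 dB
bsim_predict(corp, "S0N-90", "MVDR", cfg, seed = 1)  # -18.0 dB
```

A thin CLI over the same functions lives in `inst/cli/bimodalsrt.R`
(`corpus`, `fade`, `bsim`, `evaluate`, `validate` verbs).

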