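# Shared fixtures, built once per test run.  Sizes are kept small: the
# tests probe model properties, not study-scale accuracy.

fs <- 16000

# tiny 2-alternative corpus for structural checks
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_corpus(default_vocabulary(2), 4, seed = 7)
    cache
  }
})

# 10-alternative desk corpus shared by the recognition tests
desk_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_corpus(default_vocabulary(10), 10, seed = 1)
    cache
  }
})

desk_pipeline <- function(side_mode = "bimodal") {
  pipeline_config(pop = nerve_population(n_cells = 220),
                  side_mode = side_mode)
}

desk_hmm <- function() hmm_config(states_word = 2, states_sil = 2,
                                  states_edge = 1)

# independent Welch PSD oracle (not the package's internal helper)
oracle_psd <- function(x, nfft = 512) {
  hop <- nfft / 2
  n_frames <- floor((length(x) - nfft) / hop) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1))
  acc <- numeric(nfft / 2 + 1)
  for (m in seq_len(n_frames)) {
    seg <- x[((m - 1) * hop + 1):((m - 1) * hop + nfft)] * w
    acc <- acc + (Mod(fft(seg))^2)[seq_len(nfft / 2 + 1)]
  }
  acc / n_frames
}

# third-octave band levels (dB) of a signal from the oracle PSD
oracle_third_octave <- function(x, f_lo = 200, f_hi = 6000) {
  psd <- oracle_psd(x)
  freqs <- seq(0, 256) * fs / 512
  edges <- 10^(seq(log10(f_lo), log10(f_hi), by = 0.1))
  vapply(seq_len(length(edges) - 1), function(b) {
    sel <- freqs >= edges[b] & freqs < edges[b + 1]
    10 * log10(sum(psd[sel]))
  }, numeric(1))
}
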