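# Maskers: stationary speech-shaped noise with the corpus long-term
# spectrum (the matrix-test "Olnoise" analogue) and multi-talker babble
# built from uncorrelated sentence streams.

# Welch-averaged power spectral density on the rfft grid of length nfft/2+1
welch_psd <- function(x, nfft = 512) {
  hop <- nfft / 2
  frames <- frame_signal(x, nfft, hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1))
  spec <- abs(stats::mvfft(frames * w))^2
  psd <- rowMeans(spec)[seq_len(nfft / 2 + 1)]
  psd / sum(w^2)
}

#' Stationary noise with the corpus long-term average spectrum
#'
#' Gaussian noise spectrally shaped so its long-term spectrum matches that of
#' the concatenated corpus (the usual construction of a matrix-test masking
#' noise).
#'
#' @param corpus a [generate_corpus()] corpus
#' @param duration seconds (> 0)
#' @param seed integer seed (bit-reproducible)
#' @param match_rms match output RMS to the corpus RMS
#' @return mono waveform
#' @export
make_speech_shaped_noise <- function(corpus, duration, seed = 1,
                                     match_rms = TRUE) {
  if (length(corpus$sentences) == 0) stop("corpus is empty")
  if (duration <= 0) stop("duration must be > 0")
  fs <- corpus$fs
  ref <- corpus_concat(corpus)
  nfft <- 512
  mag <- sqrt(welch_psd(ref, nfft))
  freqs <- seq(0, nfft / 2) * fs / nfft
  n <- round(duration * fs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noise <- rnorm(n)
  shaped <- fft_filter(noise, function(f) {
    approx(freqs, mag, pmin(f, fs / 2), rule = 2)$y
  })
  if (match_rms) shaped <- shaped / rms(shaped) * rms(ref)
  shaped
}

#' Multi-talker babble streams
#'
#' Each stream is the sum of `n_talkers_per_stream` independent
#' concatenations of corpus sentences (distinct random sentence permutations
#' with random circular offsets, so streams are mutually uncorrelated).  The
#' default 4 talkers x 5 streams gives a 20-talker diffuse babble when the 5
#' streams are presented from distinct azimuths.
#'
#' @param corpus a corpus
#' @param n_talkers_per_stream talkers summed per stream
#' @param n_streams number of output streams
#' @param duration stream duration in seconds (default: one corpus pass)
#' @param seed integer seed
#' @return list of `n_streams` RMS-equalized mono waveforms
#' @export
make_babble <- function(corpus, n_talkers_per_stream = 4, n_streams = 5,
                        duration = NULL, seed = 1) {
  n_sent <- length(corpus$sentences)
  n_talk <- n_talkers_per_stream * n_streams
  if (n_sent < 2 || n_sent < n_talk / 2)
    stop("corpus too small to draw ", n_talk, " uncorrelated talker streams")
  fs <- corpus$fs
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base_len <- length(corpus_concat(corpus))
  n <- if (is.null(duration)) base_len else round(duration * fs)
  streams <- lapply(seq_len(n_streams), function(st) {
    acc <- numeric(n)
    for (tk in seq_len(n_talkers_per_stream)) {
      perm <- sample(n_sent)            # fresh permutation per talker
      talker <- unlist(lapply(corpus$sentences[perm], `[[`, "waveform"),
                       use.names = FALSE)
      off <- sample(length(talker), 1)  # random circular offset decorrelates
      talker <- c(talker[off:length(talker)], talker[seq_len(off - 1)])
      talker <- rep_len(talker, n)
      acc <- acc + talker
    }
    acc / rms(acc) * 0.05
  })
  streams
}
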