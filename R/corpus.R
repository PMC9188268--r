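# Synthetic matrix-sentence corpus.
#
# A matrix test is a closed-set sentence test with a fixed 5-slot syntax
# (name verb number adjective object) and a small per-slot vocabulary.  The
# original German recordings are licensed material, so every vocabulary word
# is rendered as a deterministic synthetic token: a harmonic complex with a
# word-specific fundamental and formant-like spectral envelope, 300-500 ms
# long.  Tokens are acoustically distinct per word identity (so a recognizer
# can learn them) while sharing a speech-like long-term spectrum.

SLOT_NAMES <- c("name", "verb", "number", "adjective", "object")

#' Default matrix-test vocabulary
#'
#' Five slots with `n_alternatives` word identifiers each, mirroring the
#' structure of matrix sentence tests (10 alternatives per slot by default).
#'
#' @param n_alternatives words per slot
#' @return named list of character vectors, one per slot
#' @export
default_vocabulary <- function(n_alternatives = 10) {
  stats::setNames(
    lapply(seq_along(SLOT_NAMES), function(s)
      paste0(SLOT_NAMES[s], seq_len(n_alternatives))),
    SLOT_NAMES)
}

# deterministic per-word acoustic parameters derived from slot/word indices.
# Small multiplicative constants keep neighbouring words well separated in
# (f0, F1, F2) space.
word_params <- function(slot, word) {
  k <- (slot - 1) * 17 + (word - 1) * 7
  list(
    f0 = 90 + 14 * ((k * 5) %% 13),                 # 90..258 Hz
    f1 = 320 + 95 * ((k * 3) %% 7),                 # 320..890 Hz
    f2 = 1100 + 330 * ((k * 11) %% 9),              # 1.1..3.7 kHz
    f3 = 3200 + 420 * (k %% 5),                     # 3.2..4.9 kHz
    dur = 0.30 + 0.05 * (k %% 5)                    # 300..500 ms
  )
}

# renders one word token.  jitter_f0/jitter_db give utterance-to-utterance
# variability (the corpus analogue of a word being "uttered" several times).
synth_token <- function(slot, word, fs = FS, jitter_f0 = 0, jitter_db = 0) {
  p <- word_params(slot, word)
  n <- round(p$dur * fs)
  t <- seq_len(n) / fs
  f0 <- p$f0 * (1 + jitter_f0)
  n_harm <- floor(7000 / f0)
  h <- seq_len(n_harm)
  fh <- h * f0
  # formant-like spectral envelope: three resonance bumps + gentle rolloff
  amp <- (exp(-0.5 * ((fh - p$f1) / 120)^2) +
          0.7 * exp(-0.5 * ((fh - p$f2) / 180)^2) +
          0.3 * exp(-0.5 * ((fh - p$f3) / 260)^2) +
          0.02) / (1 + (fh / 3000)^2)
  x <- colSums(amp * sin(2 * pi * outer(fh, t)))   # n_harm x n
  # raised-cosine onset/offset (25 ms) plus slow AM so tokens are not steady
  ramp <- rep(1, n)
  nr <- round(0.025 * fs)
  ramp[seq_len(nr)] <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  ramp[n + 1 - seq_len(nr)] <- ramp[seq_len(nr)]
  am <- 1 + 0.3 * sin(2 * pi * 3.5 * t + slot)
  x <- x * ramp * am
  x / sqrt(mean(x^2)) * 0.05 * undb(jitter_db)   # common nominal RMS
}

#' Generate a balanced synthetic matrix-sentence corpus
#'
#' Draws `n_sentences` five-word sentences such that every vocabulary word
#' occurs exactly `n_sentences / n_alternatives` times (e.g. 12 times for the
#' default 120 sentences with 10 alternatives per slot).  Each sentence
#' waveform is the concatenation of the five word tokens with short silent
#' pads at both ends; word boundaries are recorded as sample intervals.
#'
#' @param vocabulary list of 5 character vectors (see [default_vocabulary()])
#' @param n_sentences number of sentences; must be divisible by the number of
#'   alternatives per slot
#' @param seed integer seed; corpora are bit-identical under a fixed seed
#' @param fs sampling rate (Hz)
#' @param pad_s leading/trailing silence per sentence (s)
#' @param utterance_jitter logical; add small per-utterance f0/level jitter
#'   (intrinsic variability between repetitions of the same word)
#' @return object of class `corpus`: list with `sentences` (each with
#'   `slot_words`, `word_idx`, `waveform`, `word_boundaries`), `vocabulary`,
#'   `fs`, `seed`
#' @export
generate_corpus <- function(vocabulary = default_vocabulary(),
                            n_sentences = 120, seed = 1, fs = FS,
                            pad_s = 0.1, utterance_jitter = TRUE) {
  n_alt <- unique(lengths(vocabulary))
  if (length(n_alt) != 1)
    stop("all slots must have the same number of alternatives")
  if (length(vocabulary) != 5) stop("vocabulary must have exactly 5 slots")
  if (n_sentences %% n_alt != 0)
    stop("n_sentences (", n_sentences, ") must be divisible by the number ",
         "of alternatives per slot (", n_alt, ") for a balanced corpus")
  reps <- n_sentences / n_alt
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # per slot: a permuted balanced assignment of words to sentences
  slot_assign <- vapply(seq_len(5), function(s)
    sample(rep(seq_len(n_alt), reps)), integer(n_sentences))
  pad <- numeric(round(pad_s * fs))
  sentences <- lapply(seq_len(n_sentences), function(i) {
    words <- slot_assign[i, ]
    toks <- lapply(seq_len(5), function(s) {
      jf <- if (utterance_jitter) runif(1, -0.03, 0.03) else 0
      jd <- if (utterance_jitter) runif(1, -1, 1) else 0
      synth_token(s, words[s], fs, jf, jd)
    })
    lens <- lengths(toks)
    starts <- length(pad) + cumsum(c(0, head(lens, -1))) + 1
    list(slot_words = vapply(seq_len(5), function(s)
           vocabulary[[s]][words[s]], character(1)),
         word_idx = words,
         waveform = c(pad, unlist(toks), pad),
         word_boundaries = cbind(start = starts, end = starts + lens - 1))
  })
  structure(list(sentences = sentences, vocabulary = vocabulary,
                 fs = fs, seed = seed),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat("Synthetic matrix-sentence corpus:", length(x$sentences),
      "sentences,", length(x$vocabulary[[1]]), "alternatives/slot, fs =",
      x$fs, "Hz\n")
  invisible(x)
}

#' Write a corpus manifest (and optionally per-sentence WAV files)
#'
#' @param corpus a [generate_corpus()] object
#' @param dir output directory
#' @param write_audio write one float32 WAV per sentence
#' @return path of the manifest file (tab-separated: id, 5 word ids, file)
#' @export
write_corpus <- function(corpus, dir, write_audio = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(corpus$sentences), function(i) {
    s <- corpus$sentences[[i]]
    f <- file.path(dir, sprintf("sentence_%03d.wav", i))
    if (write_audio) write_wav(s$waveform, f, corpus$fs)
    c(id = i, s$slot_words, file = f)
  })
  man <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), man, sep = "\t", quote = FALSE,
              row.names = FALSE)
  man
}

# save/restore the global RNG state so generators are pure wrt the session
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Concatenate all corpus waveforms (helper for long-term spectra)
#' @param corpus a corpus
#' @return mono waveform
#' @export
corpus_concat <- function(corpus) {
  unlist(lapply(corpus$sentences, `[[`, "waveform"), use.names = FALSE)
}
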