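# The machine-learning SRT chain: spatial scene -> beamformer -> device
# simulation -> bimodal features -> HMM recognizer over a train-by-test SNR
# grid -> SRT at the 50% word-correct criterion.

#' Train/test SNR grid
#'
#' @param train_snrs,test_snrs dB vectors (3 dB steps by default usage)
#' @param n_train_mixtures noise instances of the corpus used in training
#'   per train SNR (8 by default: 8 x 120 = 960 training sentences)
#' @param n_test_mixtures held-out noise instances used in testing
#' @export
snr_grid <- function(train_snrs, test_snrs = train_snrs,
                     n_train_mixtures = 8, n_test_mixtures = 1) {
  structure(list(train_snrs = sort(train_snrs),
                 test_snrs = sort(test_snrs),
                 n_train_mixtures = n_train_mixtures,
                 n_test_mixtures = n_test_mixtures),
            class = "snr_grid")
}

#' Default SNR ranges per scenario and beamformer
#'
#' The simulated SNR ranges (3 dB steps) per spatial scenario and
#' beamformer condition used for the full-scale experiment.
#'
#' @param scenario scenario id
#' @param beamformer beamformer id
#' @export
default_snr_range <- function(scenario, beamformer) {
  key <- paste(beamformer, scenario)
  r <- switch(key,
    "NoBF S0N-90" = c(-13, 5),  "NoBF S0N0" = c(-9, 6),
    "NoBF S0N+90" = c(-13, 5),  "NoBF S0N20TB" = c(-10, 8),
    "ADM S0N-90" = c(-18, 0),   "ADM S0N0" = c(-9, 6),
    "ADM S0N+90" = c(-18, 0),   "ADM S0N20TB" = c(-16, 2),
    "MVDR S0N-90" = c(-24, -6), "MVDR S0N0" = c(-9, 6),
    "MVDR S0N+90" = c(-21, -3), "MVDR S0N20TB" = c(-18, 0),
    stop("unknown scenario/beamformer combination"))
  seq(r[1], r[2], by = 3)
}

#' Concatenate acoustic and electric feature matrices
#'
#' Column-wise concatenation, acoustic first; no cross-channel processing.
#' With the defaults (31 acoustic + 46 electric) the result is
#' 77-dimensional.
#'
#' @param acoustic frames-by-31 matrix
#' @param electric frames-by-n_groups matrix on the same frame grid
#' @export
concat_features <- function(acoustic, electric) {
  if (nrow(acoustic) != nrow(electric))
    stop("frame count mismatch: ", nrow(acoustic), " vs ", nrow(electric))
  cbind(acoustic, electric)
}

#' Bimodal pipeline configuration bundle
#'
#' Collects the per-stage configurations of the feature pipeline.
#'
#' @param head [head_model()]
#' @param audiogram [audiogram()] of the HA side
#' @param acoustic [acoustic_config()]
#' @param compressor [compressor_config()]
#' @param ace [ace_config()]
#' @param pop [nerve_population()]
#' @param ir [ir_config()]
#' @param side_mode `"bimodal"`, `"acoustic"` or `"ci"`
#' @export
pipeline_config <- function(head = head_model(),
                            audiogram = default_audiogram(),
                            acoustic = acoustic_config(),
                            compressor = compressor_config(),
                            ace = ace_config(), pop = nerve_population(),
                            ir = ir_config(),
                            side_mode = c("bimodal", "acoustic", "ci")) {
  structure(list(head = head, audiogram = audiogram, acoustic = acoustic,
                 compressor = compressor, ace = ace, pop = pop, ir = ir,
                 side_mode = match.arg(side_mode)),
            class = "pipeline_config")
}

# word boundaries (samples) -> frame intervals on the feature grid
bounds_to_frames <- function(word_boundaries, n_frames, acfg) {
  hop <- round(acfg$frame_shift * FS)
  fb <- cbind(pmax(1, floor((word_boundaries[, 1] - 1) / hop) + 1),
              pmin(n_frames, floor((word_boundaries[, 2] - 1) / hop) + 1))
  # guarantee non-empty, ordered intervals
  fb[, 2] <- pmax(fb[, 2], fb[, 1])
  fb
}

# features of one beamformed 2-channel signal
bimodal_features <- function(y2, cfg, seed) {
  ac <- logmel(compress_ha(y2[, 1], cfg$audiogram, cfg$compressor),
               cfg$acoustic)
  if (cfg$side_mode == "acoustic")
    return(apply_audibility(ac, threshold_spl(cfg$audiogram, cfg$acoustic),
                            seed = derive_seed(seed, 21L)))
  el <- electric_features(y2[, 2], cfg$ace, cfg$pop, cfg$ir, cfg$acoustic,
                          seed = seed)
  el <- el[seq_len(min(nrow(ac), nrow(el))), , drop = FALSE]
  ac <- ac[seq_len(nrow(el)), , drop = FALSE]
  if (cfg$side_mode == "ci") return(el)
  gated <- apply_audibility(ac, threshold_spl(cfg$audiogram, cfg$acoustic),
                           seed = derive_seed(seed, 21L))
  concat_features(gated, el)
}

# noise bank: one long masker per (mixture, source); sentences use seeded
# circular slices so every sentence sees a different noise instance
make_noise_bank <- function(corpus, scene, mix_seed, dur_s) {
  ns <- scene$noise_sources
  if (all(ns$type == "babble")) {
    make_babble(corpus, 4, nrow(ns), duration = dur_s, seed = mix_seed)
  } else {
    lapply(seq_len(nrow(ns)), function(i)
      make_speech_shaped_noise(corpus, dur_s,
                               seed = derive_seed(mix_seed, i)))
  }
}

slice_noise <- function(bank, n, offset_seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(offset_seed)
  lapply(bank, function(long) {
    off <- sample(length(long), 1)
    rep_len(c(long[off:length(long)], long[seq_len(off - 1)]), n)
  })
}

# features + labels for the whole corpus at one SNR with one noise mixture
corpus_features <- function(corpus, scenario, snr, beamformer, cfg,
                            mix_seed, mvdr = NULL) {
  scene <- scene_spec(scenario, snr)
  max_len <- max(vapply(corpus$sentences, function(s)
    length(s$waveform), integer(1)))
  bank <- make_noise_bank(corpus, scene, mix_seed, (max_len + FS) / FS)
  lapply(seq_along(corpus$sentences), function(i) {
    s <- corpus$sentences[[i]]
    nz <- slice_noise(bank, length(s$waveform),
                      derive_seed(mix_seed, 100 + i))
    parts <- mix_scene(scene, s$waveform, cfg$head,
                       noise_signals = nz)
    y2 <- beamform(parts$mixture, beamformer, cfg$head, mvdr = mvdr)
    feats <- bimodal_features(y2, cfg, seed = derive_seed(mix_seed, i))
    fb <- bounds_to_frames(s$word_boundaries, nrow(feats), cfg$acoustic)
    list(features = feats, words = s$slot_words, frame_bounds = fb)
  })
}

#' Run the recognition experiment over a train-by-test SNR grid
#'
#' For each training SNR: mixes `n_train_mixtures` noise instances of the
#' corpus, extracts bimodal features, trains the word/silence/edge HMMs;
#' then tests each trained model on held-out noise mixtures over all test
#' SNRs.  Feature normalization statistics are estimated on the training
#' set and applied to the test set.
#'
#' @param corpus a [generate_corpus()] corpus
#' @param scenario scenario id (see [scene_spec()])
#' @param beamformer `"NoBF"`, `"ADM"` or `"MVDR"`
#' @param grid an [snr_grid()]
#' @param cfg a [pipeline_config()]
#' @param hmm an [hmm_config()]
#' @param seed master seed; all noise/model randomness derives from it
#' @param verbose print per-cell progress
#' @return object of class `recognition_matrix`: `rates` (train x test
#'   percent correct) plus provenance metadata
#' @export
run_grid <- function(corpus, scenario, beamformer, grid, cfg,
                     hmm = hmm_config(), seed = 1, verbose = FALSE) {
  mvdr <- if (beamformer == "MVDR") mvdr_design(cfg$head) else NULL
  test_raw <- vector("list", length(grid$test_snrs))   # shared across rows
  rates <- matrix(NA_real_, length(grid$train_snrs),
                  length(grid$test_snrs),
                  dimnames = list(train = grid$train_snrs,
                                  test = grid$test_snrs))
  for (ti in seq_along(grid$train_snrs)) {
    tr_snr <- grid$train_snrs[ti]
    train_data <- tryCatch({
      do.call(c, lapply(seq_len(grid$n_train_mixtures), function(m)
        corpus_features(corpus, scenario, tr_snr, beamformer, cfg,
                        mix_seed = derive_seed(seed, ti * 1000 + m),
                        mvdr = mvdr)))
    }, error = function(e)
      stop("training features failed at train SNR ", tr_snr, " dB: ",
           conditionMessage(e)))
    norm <- normalize_features(lapply(train_data, `[[`, "features"))
    for (i in seq_along(train_data))
      train_data[[i]]$features <- norm[[i]]
    stats <- attr(norm, "stats")
    models <- train_models(train_data, corpus$vocabulary, hmm)
    for (si in seq_along(grid$test_snrs)) {
      te_snr <- grid$test_snrs[si]
      if (is.null(test_raw[[si]]))
        test_raw[[si]] <- tryCatch({
          do.call(c, lapply(seq_len(grid$n_test_mixtures), function(m)
            corpus_features(corpus, scenario, te_snr, beamformer, cfg,
                            mix_seed = derive_seed(seed,
                                                   777000 + si * 100 + m),
                            mvdr = mvdr)))
        }, error = function(e)
          stop("test features failed at test SNR ", te_snr, " dB: ",
               conditionMessage(e)))
      test_data <- test_raw[[si]]
      tf <- normalize_features(lapply(test_data, `[[`, "features"),
                               stats = stats)
      for (i in seq_along(test_data)) test_data[[i]]$features <- tf[[i]]
      rates[ti, si] <- recognize(test_data, models)$rate
      if (verbose)
        message(sprintf("train %g dB / test %g dB -> %.1f%%",
                        tr_snr, te_snr, rates[ti, si]))
    }
  }
  structure(list(rates = rates, scenario = scenario,
                 beamformer = beamformer, grid = grid, seed = seed),
            class = "recognition_matrix")
}

#' @export
print.recognition_matrix <- function(x, ...) {
  cat("Recognition matrix (", x$scenario, ", ", x$beamformer,
      "), % words correct:\n", sep = "")
  print(round(x$rates, 1))
  invisible(x)
}

#' Extract the SRT from a recognition matrix
#'
#' Per training row, the first upward crossing of the criterion along the
#' test-SNR axis is located by linear interpolation; the SRT is the lowest
#' crossing over all training rows.  A row already at or above criterion at
#' the lowest test SNR contributes that SNR (censored crossing); rows never
#' reaching the criterion are skipped.
#'
#' @param matrix a [run_grid()] result (or plain rate matrix with test SNRs
#'   as column names)
#' @param criterion percent correct defining the SRT (50 by default)
#' @return SRT in dB, with attribute `per_row` (crossing per train row)
#' @export
extract_srt <- function(matrix, criterion = 50) {
  rates <- if (inherits(matrix, "recognition_matrix")) matrix$rates
           else matrix
  test_snrs <- as.numeric(colnames(rates))
  crossings <- apply(rates, 1, function(r) {
    if (all(is.na(r))) return(NA_real_)
    if (r[1] >= criterion) return(test_snrs[1])
    idx <- which(r[-1] >= criterion & r[-length(r)] < criterion)
    if (length(idx) == 0) return(NA_real_)
    i <- idx[1]
    test_snrs[i] + (criterion - r[i]) / (r[i + 1] - r[i]) *
      (test_snrs[i + 1] - test_snrs[i])
  })
  if (all(is.na(crossings)))
    stop("SRT outside grid: no training row crosses ", criterion,
         "% -- widen the test SNR range")
  srt <- min(crossings, na.rm = TRUE)
  attr(srt, "per_row") <- crossings
  srt
}
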