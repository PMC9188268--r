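# Parametric 4-microphone head model and spatial scene mixing.
#
# The head model stands in for measured behind-the-ear HRIRs: it reproduces
# the cues the beamformers exploit -- interaural time differences (Woodworth
# type, itd_max at +-90 degrees), an interaural level difference from a
# frequency-dependent head-shadow low-pass on the far ear, and a small
# front/rear microphone spacing per side.  Azimuth convention: 0 = front,
# positive = right, in [-180, 180).

#' Parametric four-microphone head model
#'
#' @param itd_max maximum interaural time difference (s) at +-90 degrees
#' @param shadow_db maximum broadband head-shadow attenuation of the far ear
#'   (dB) at +-90 degrees
#' @param shadow_fc corner frequency (Hz) of the shadow low-pass; attenuation
#'   grows with frequency above it
#' @param mic_spacing front-to-rear microphone distance per side (m)
#' @param ear_distance inter-ear distance (m), used for the diffuse-field
#'   coherence of the MVDR design
#' @param reverb optional list(t60, level_db) adding an exponentially
#'   decaying diffuse tail; `NULL` (default) = anechoic
#' @param hrir optional measured HRIR set: function(azimuth) returning a
#'   4-column impulse-response matrix (overrides the parametric model)
#' @return object of class `head_model`
#' @export
head_model <- function(itd_max = 700e-6, shadow_db = 12, shadow_fc = 800,
                       mic_spacing = 0.01, ear_distance = 0.18,
                       reverb = NULL, hrir = NULL) {
  structure(list(itd_max = itd_max, shadow_db = shadow_db,
                 shadow_fc = shadow_fc, mic_spacing = mic_spacing,
                 ear_distance = ear_distance, reverb = reverb, hrir = hrir,
                 mic_labels = c("left_front", "left_rear",
                                "right_front", "right_rear")),
            class = "head_model")
}

# per-channel complex transfer function at azimuth az (degrees) and
# frequencies f (Hz).  Returns a length(f) x 4 complex matrix.
# A constant base delay keeps all channels causal for rear sources.
head_transfer <- function(head, az, f) {
  theta <- az * pi / 180
  c0 <- 343
  # ear delays: far ear lags; base offset keeps delays non-negative
  d_l <- head$itd_max / 2 * (1 + sin(theta))
  d_r <- head$itd_max / 2 * (1 - sin(theta))
  # rear mics lag the front mics by the projected spacing travel time
  d_fr <- head$mic_spacing / c0 * cos(theta)
  base <- head$mic_spacing / c0   # causality offset
  delays <- c(d_l, d_l + d_fr, d_r, d_r + d_fr) + base
  # head shadow on the far side only; first-order rise above shadow_fc
  shade_amount <- function(side_sign) pmax(0, side_sign * sin(theta))
  hf_weight <- (f / head$shadow_fc) / sqrt(1 + (f / head$shadow_fc)^2)
  att_l <- undb(-head$shadow_db * shade_amount(+1) * hf_weight) # src right
  att_r <- undb(-head$shadow_db * shade_amount(-1) * hf_weight) # src left
  mags <- cbind(att_l, att_l, att_r, att_r)
  mags * exp(-2i * pi * outer(f, delays))
}

#' Spatialize a mono source to the four head microphones
#'
#' Applies the azimuth-dependent per-channel delay and head-shadow filtering
#' of the parametric head model (or convolves with measured HRIRs when the
#' head model carries them).
#'
#' @param x mono waveform
#' @param azimuth source azimuth in degrees, in [-180, 180); 0 = front,
#'   positive = right
#' @param head a [head_model()]
#' @param tail extra output samples for the filter tail
#' @return samples-by-4 matrix (left-front, left-rear, right-front,
#'   right-rear)
#' @export
spatialize <- function(x, azimuth, head = head_model(), tail = 64L) {
  if (azimuth < -180 || azimuth >= 180)
    stop("azimuth must be in [-180, 180)")
  if (!is.null(head$hrir)) {
    h <- head$hrir(azimuth)
    return(vapply(seq_len(4), function(ch)
      signal::conv(x, h[, ch])[seq_len(length(x) + nrow(h) - 1)],
      numeric(length(x) + nrow(h) - 1)))
  }
  n_out <- length(x) + tail
  y <- vapply(seq_len(4), function(ch) {
    fft_filter(x, function(f) head_transfer(head, azimuth, f)[, ch],
               tail = tail)
  }, numeric(n_out))
  if (!is.null(head$reverb)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(1234L, round(azimuth)))
    t60 <- head$reverb$t60
    nrev <- round(t60 * FS / 2)
    env <- exp(-6.908 * seq_len(nrev) / (t60 * FS))
    g <- undb(head$reverb$level_db) * rms(x)
    for (ch in seq_len(4)) {
      tailsig <- signal::conv(x, rnorm(nrev) * env)
      y[, ch] <- y[, ch] + g * tailsig[seq_len(n_out)] / rms(tailsig)
    }
  }
  y
}

SCENARIOS <- c("S0N-90", "S0N0", "S0N+90", "S0N20TB")

#' Define a spatial scenario
#'
#' The four scenarios are frontal target speech with: noise from the left
#' (`S0N-90`), from the front (`S0N0`), from the right (`S0N+90`), or a
#' diffuse 20-talker babble from five surrounding azimuths (`S0N20TB`).
#'
#' @param scenario_id one of `"S0N-90"`, `"S0N0"`, `"S0N+90"`, `"S0N20TB"`
#' @param snr_db broadband SNR (dB) at the front microphones
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(scenario_id, snr_db = 0) {
  scenario_id <- match.arg(scenario_id, SCENARIOS)
  noise_sources <- switch(scenario_id,
    "S0N-90" = data.frame(azimuth = -90, type = "ssn"),
    "S0N0"   = data.frame(azimuth = 0, type = "ssn"),
    "S0N+90" = data.frame(azimuth = 90, type = "ssn"),
    "S0N20TB" = data.frame(azimuth = c(-135, -90, 45, 90, 135),
                           type = "babble"))
  structure(list(scenario_id = scenario_id, target_azimuth = 0,
                 noise_sources = noise_sources, snr_db = snr_db),
            class = "scene_spec")
}

# boolean gate of speech-active samples: front-mix envelope above -40 dB re
# max (80 ms smoothing)
speech_active_gate <- function(speech_front, fs = FS) {
  env <- sqrt(stats::filter(speech_front^2, rep(1 / (0.08 * fs), 0.08 * fs),
                            sides = 2))
  env[is.na(env)] <- 0
  env > max(env) * undb(-40)
}

# broadband SNR (dB) of separated speech/noise averaged over the two front
# channels, restricted to speech-active samples
front_snr_db <- function(speech4, noise4, fs = FS) {
  gate <- speech_active_gate(rowMeans(speech4[, c(1, 3)]), fs)
  s_pow <- mean(c(speech4[gate, 1]^2, speech4[gate, 3]^2))
  n_pow <- mean(c(noise4[gate, 1]^2, noise4[gate, 3]^2))
  10 * log10(s_pow / n_pow)
}

#' Mix a spatial scene at a calibrated SNR
#'
#' Spatializes the target speech frontally and the scenario's noise
#' source(s), then scales the summed noise so the broadband SNR -- measured
#' over speech-active samples, averaged across the two front microphones --
#' equals `scene$snr_db`.  Returns the mixture and the separated parts
#' (mixture = speech_only + noise_only sample-exactly).
#'
#' @param scene a [scene_spec()]
#' @param speech mono target waveform
#' @param head a [head_model()]
#' @param seed integer seed for noise instantiation
#' @param corpus corpus used to build the masker (spectrum for `ssn`,
#'   material for babble)
#' @param noise_signals optional pre-built list of mono noise waveforms, one
#'   per noise source (overrides generation)
#' @return list(mixture, speech_only, noise_only): samples-by-4 matrices
#' @export
mix_scene <- function(scene, speech, head = head_model(), seed = 1,
                      corpus = NULL, noise_signals = NULL) {
  if (max(abs(speech)) == 0) stop("speech is silent")
  ns <- scene$noise_sources
  if (is.null(noise_signals)) {
    if (is.null(corpus)) stop("need a corpus (or noise_signals) for masker")
    dur <- (length(speech) + 1000) / FS
    noise_signals <- if (all(ns$type == "babble")) {
      make_babble(corpus, 4, nrow(ns), duration = dur, seed = seed)
    } else {
      lapply(seq_len(nrow(ns)), function(i)
        make_speech_shaped_noise(corpus, dur, seed = derive_seed(seed, i)))
    }
  }
  if (any(vapply(noise_signals, function(z) max(abs(z)) == 0, logical(1))))
    stop("silent noise source")
  speech4 <- spatialize(speech, scene$target_azimuth, head)
  n_out <- nrow(speech4)
  noise4 <- matrix(0, n_out, 4)
  for (i in seq_len(nrow(ns))) {
    nz <- fix_length(noise_signals[[i]], length(speech))
    noise4 <- noise4 + spatialize(nz, ns$azimuth[i], head)
  }
  # calibrate: scale noise for the requested front-channel SNR
  cur <- front_snr_db(speech4, noise4)
  noise4 <- noise4 * undb(cur - scene$snr_db)
  list(mixture = speech4 + noise4, speech_only = speech4,
       noise_only = noise4)
}
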