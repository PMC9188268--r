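# Hearing-aid simulation: multiband dynamic range compressor with a
# CAMFIT-style prescription modified for bimodal fittings -- amplification
# targets the residual low-frequency hearing (no gain prescribed above
# 5 kHz) and the prescribed gain is capped at the gain of a 90 dB HL loss.

#' Multiband compressor configuration
#'
#' @param n_bands number of frequency bands
#' @param crossover_freqs band edges (Hz); defaults to log spacing
#'   100-8000 Hz
#' @param gain_rule linear insertion gain per dB HL (CAMFIT-style
#'   proportional rule)
#' @param camfit_hl_cap HL cap (dB) for the prescription
#' @param camfit_upper_freq no gain at or above this frequency (Hz)
#' @param knee compression knee (dB SPL input band level)
#' @param ratio compression ratio above the knee
#' @param attack,release level-estimator time constants (ms)
#' @param dbfs_spl calibration: band level of a full-scale sinusoid (dB SPL)
#' @export
compressor_config <- function(n_bands = 9, crossover_freqs = NULL,
                              gain_rule = 0.48, camfit_hl_cap = 90,
                              camfit_upper_freq = 5000, knee = 50,
                              ratio = 2, attack = 20, release = 100,
                              dbfs_spl = 100, gain_table = NULL) {
  if (is.null(crossover_freqs))
    crossover_freqs <- exp(seq(log(100), log(8000),
                               length.out = n_bands + 1))
  centers <- sqrt(crossover_freqs[-1] * crossover_freqs[-(n_bands + 1)])
  structure(list(n_bands = n_bands, crossover_freqs = crossover_freqs,
                 centers = centers, gain_rule = gain_rule,
                 camfit_hl_cap = camfit_hl_cap,
                 camfit_upper_freq = camfit_upper_freq, knee = knee,
                 ratio = ratio, attack = attack, release = release,
                 dbfs_spl = dbfs_spl, gain_table = gain_table),
            class = "compressor_config")
}

#' An audiogram (pure-tone thresholds)
#'
#' @param freqs audiometric frequencies (Hz), strictly increasing
#' @param thresholds hearing levels (dB HL), finite
#' @export
audiogram <- function(freqs, thresholds) {
  if (any(diff(freqs) <= 0)) stop("audiogram freqs must be increasing")
  if (any(!is.finite(thresholds))) stop("audiogram thresholds must be finite")
  structure(list(freqs = freqs, thresholds = thresholds),
            class = "audiogram")
}

#' Synthetic average audiogram of a moderately-to-severely impaired HA ear
#'
#' A synthetic stand-in for a bimodal study population's average
#' contralateral audiogram: mild low-frequency loss sloping to severe loss
#' at high frequencies.
#' @export
default_audiogram <- function() {
  audiogram(c(125, 250, 500, 1000, 2000, 4000, 8000),
            c(30, 35, 45, 55, 70, 85, 95))
}

# interpolate HL at arbitrary frequencies (linear in log-f, clamped)
interp_hl <- function(ag, f) {
  approx(log(ag$freqs), ag$thresholds, log(pmax(f, min(ag$freqs))),
         rule = 2)$y
}

#' CAMFIT-style prescribed linear insertion gains per band
#'
#' Gain proportional to the hearing loss, computed from HL capped at
#' `camfit_hl_cap` (losses beyond the cap get the cap's gain) and zero at or
#' above `camfit_upper_freq`.
#'
#' @param ag an [audiogram()]
#' @param cfg a [compressor_config()]
#' @return numeric vector of per-band gains (dB)
#' @export
camfit_gains <- function(ag, cfg = compressor_config()) {
  hl <- pmin(interp_hl(ag, cfg$centers), cfg$camfit_hl_cap)
  g <- cfg$gain_rule * hl
  g[cfg$centers >= cfg$camfit_upper_freq] <- 0
  g
}

# complementary linear-phase band split: triangular masks in log-frequency
# that sum to exactly 1, applied by FFT filtering -> perfect reconstruction
band_split <- function(x, cfg) {
  edges <- cfg$crossover_freqs
  nb <- cfg$n_bands
  lapply(seq_len(nb), function(b) {
    fft_filter(x, function(f) {
      lo <- edges[b]; hi <- edges[b + 1]
      m <- as.numeric(f >= lo & f < hi)
      if (b == 1) m[f < lo] <- 1
      if (b == nb) m[f >= hi] <- 1
      m
    })
  })
}

#' Multiband dynamic range compression with CAMFIT-style gains
#'
#' Splits the signal into complementary bands, tracks each band's level with
#' attack/release smoothing, applies the prescribed linear gain plus
#' compressive gain reduction above the knee, and sums the bands back.  A
#' flat 0 dB HL audiogram prescribes zero gain and the compressor acts as an
#' identity up to filterbank reconstruction error.
#'
#' @param signal mono input (full scale +-1)
#' @param ag an [audiogram()]
#' @param cfg a [compressor_config()]
#' @return mono output
#' @export
compress_ha <- function(signal, ag = default_audiogram(),
                        cfg = compressor_config()) {
  gains <- if (!is.null(cfg$gain_table)) {
    if (length(cfg$gain_table) != cfg$n_bands)
      stop("gain_table must have one entry per band")
    cfg$gain_table
  } else camfit_gains(ag, cfg)
  bands <- band_split(signal, cfg)
  a_att <- exp(-1 / (cfg$attack * 1e-3 * FS))
  a_rel <- exp(-1 / (cfg$release * 1e-3 * FS))
  out <- numeric(length(signal))
  for (b in seq_len(cfg$n_bands)) {
    xb <- bands[[b]]
    env <- smooth_env_cpp(xb^2, a_att, a_rel)
    lvl <- 10 * log10(pmax(env, 1e-20) / 0.5) + cfg$dbfs_spl
    g <- gains[b] - pmax(lvl - cfg$knee, 0) * (1 - 1 / cfg$ratio) *
      (gains[b] > 0)
    out <- out + xb * undb(g)
  }
  out
}
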