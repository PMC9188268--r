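# SII-based SRT chain: separated speech/noise through the front-end, CI
# auralization (vocoder-style), gammatone band analysis, binaural
# equalization-cancellation, band-wise best-SNR selection, electro-acoustic
# weighting, SII, and an iterative broadband-gain SRT search.

#' BSIM configuration
#'
#' @param n_bands gammatone bands
#' @param f_lo,f_hi band range (Hz), ERB-spaced
#' @param ec_amp_jitter_db amplitude-jitter SD of the EC stage (dB)
#' @param ec_time_jitter time-jitter SD of the EC stage (s)
#' @param ec_max_delay EC delay search range (s)
#' @param ec_delay_step delay grid step (s)
#' @param ec_max_gain_db EC gain search range (dB)
#' @param ec_gain_step_db gain grid step (dB)
#' @param sii_ref_acoustic,sii_ref_ci reference SII values of the two sides
#' @param snr_cap band-SNR ceiling (dB) when noise power vanishes
#' @param window short-term analysis window (samples)
#' @param importance band-importance weights (`"uniform"` or a vector
#'   summing to 1)
#' @param crossover_hz electro-acoustic weighting crossover frequency
#' @export
bsim_config <- function(n_bands = 30, f_lo = 146, f_hi = 8000,
                        ec_amp_jitter_db = 1.5, ec_time_jitter = 105e-6,
                        ec_max_delay = 10e-3, ec_delay_step = 0.25e-3,
                        ec_max_gain_db = 40, ec_gain_step_db = 2,
                        sii_ref_acoustic = 0.26, sii_ref_ci = 0.42,
                        snr_cap = 40, window = 1024,
                        importance = "uniform", crossover_hz = 1000,
                        ea_weighting = c("crossover", "unit")) {
  ea_weighting <- match.arg(ea_weighting)
  if (sii_ref_acoustic <= 0 || sii_ref_acoustic >= 1 ||
      sii_ref_ci <= 0 || sii_ref_ci >= 1)
    stop("SII references must lie in (0, 1)")
  erb <- function(f) 24.7 * (4.37 * f / 1000 + 1)
  erbscale <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
  inv_erbscale <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
  centers <- inv_erbscale(seq(erbscale(f_lo), erbscale(f_hi),
                              length.out = n_bands))
  structure(list(n_bands = n_bands, centers = centers, erb = erb(centers),
                 ec_amp_jitter_db = ec_amp_jitter_db,
                 ec_time_jitter = ec_time_jitter,
                 ec_max_delay = ec_max_delay,
                 ec_delay_step = ec_delay_step,
                 ec_max_gain_db = ec_max_gain_db,
                 ec_gain_step_db = ec_gain_step_db,
                 sii_ref_acoustic = sii_ref_acoustic,
                 sii_ref_ci = sii_ref_ci, snr_cap = snr_cap,
                 window = window, importance = importance,
                 crossover_hz = crossover_hz, ea_weighting = ea_weighting),
            class = "bsim_config")
}

# 4th-order gammatone bandpass (cascade of 4 one-pole complex sections,
# realized by demodulation to baseband + real one-pole cascade)
gammatone_filter <- function(x, cf, bw, fs = FS) {
  r <- exp(-2 * pi * 1.019 * bw / fs)
  ph <- 2 * pi * cf * seq_along(x) / fs
  co <- cos(ph); si <- sin(ph)
  zr <- x * co; zi <- -x * si
  for (k in 1:4) {
    zr <- as.numeric(signal::filter(1 - r, c(1, -r), zr))
    zi <- as.numeric(signal::filter(1 - r, c(1, -r), zi))
  }
  2 * (zr * co - zi * si)
}

# band-filter a signal through the whole filterbank: samples x bands
gammatone_bank <- function(x, cfg, fs = FS) {
  vapply(seq_len(cfg$n_bands), function(b)
    gammatone_filter(x, cfg$centers[b], cfg$erb[b], fs),
    numeric(length(x)))
}

#' CI auralization of separated speech and noise
#'
#' Vocoder-style reconstruction of what the CI transmits: ACE band
#' envelopes are computed per cycle, spread across the electrode array with
#' the exponential current-spread function, and re-modulate tone carriers
#' at the electrode-mapped frequencies.  The temporal fine structure of the
#' input is discarded (only envelopes survive), which is what limits EC
#' binaural processing on the CI side.
#'
#' @param speech,noise equal-length separated mono signals (one ear)
#' @param ace an [ace_config()]
#' @param pop a [nerve_population()] (for the spread constant)
#' @return list(speech_aur, noise_aur)
#' @export
ci_auralize <- function(speech, noise, ace = ace_config(),
                        pop = nerve_population()) {
  stopifnot_same_length(speech, noise)
  n <- length(speech)
  freqs <- ace_channel_freqs(ace)
  # electrode-to-electrode envelope mixing by exponential current spread
  spread <- exp(-abs(outer(pop$electrode_positions,
                           pop$electrode_positions, "-")) /
                  pop$lambda_spread)
  aur_one <- function(x) {
    eg <- ace_encode(x, ace)
    env <- attr(eg, "envelopes")                 # cycles x M
    if (nrow(env) == 0) return(numeric(n))
    env_spread <- env %*% spread
    adv <- ace$fs / ace$channel_rate
    cyc_t <- (round((seq_len(nrow(env)) - 1) * adv) + ace$frame_len / 2)
    t_all <- seq_len(n)
    out <- numeric(n)
    for (m in seq_len(ace$M)) {
      e <- approx(cyc_t, env_spread[, m], t_all, rule = 2)$y
      out <- out + e * sin(2 * pi * freqs[m] * t_all / ace$fs)
    }
    out / (sum(0.5 - 0.5 * cos(2 * pi * (seq_len(ace$frame_len) - 1) /
                                 ace$frame_len)) / 2)
  }
  list(speech_aur = aur_one(speech), noise_aur = aur_one(noise))
}

# cross-correlation <a, shift(b, lag)> for a lag vector, via FFT
xcorr_lags <- function(a, b, lags) {
  n <- length(a)
  nfft <- next_pow2(2 * n)
  A <- fft(fix_length(a, nfft)); B <- fft(fix_length(b, nfft))
  cc <- Re(fft(A * Conj(B), inverse = TRUE)) / nfft
  # cc[k+1] = sum a[i] b[i-k] (circular); negative lags wrap
  idx <- ifelse(lags >= 0, lags + 1, nfft + lags + 1)
  cc[idx]
}

#' Per-band SNRs of the left, right and EC paths
#'
#' For each gammatone band: left/right SNRs from band powers; the EC SNR
#' from jointly equalizing interaural delay and level (grid search over
#' `+-ec_max_delay` and `+-ec_max_gain_db`) and cancelling, degraded by the
#' configured EC processing inaccuracies (deterministic first-order
#' expectation of amplitude and time jitter).  Short-term analysis in
#' `window`-sample segments, profile averaged over segments.
#'
#' @param speech_l,noise_l,speech_r,noise_r separated band-limited inputs
#'   (equal length)
#' @param cfg a [bsim_config()]
#' @param ec enable the EC path
#' @return object of class `band_snr_profile`: data.frame with per-band
#'   `snr_left`, `snr_right`, `snr_ec`, `snr_best` (dB) and `path`
#' @export
band_snrs <- function(speech_l, noise_l, speech_r, noise_r,
                      cfg = bsim_config(), ec = TRUE) {
  n <- length(speech_l)
  stopifnot(length(noise_l) == n, length(speech_r) == n,
            length(noise_r) == n)
  sl <- gammatone_bank(speech_l, cfg); nl <- gammatone_bank(noise_l, cfg)
  sr <- gammatone_bank(speech_r, cfg); nr <- gammatone_bank(noise_r, cfg)
  lags <- round(seq(-cfg$ec_max_delay, cfg$ec_max_delay,
                    by = cfg$ec_delay_step) * FS)
  gains <- undb(seq(-cfg$ec_max_gain_db, cfg$ec_max_gain_db,
                    by = cfg$ec_gain_step_db))
  win <- min(cfg$window, n)
  starts <- seq(1, n - win + 1, by = win)
  cap_lin <- 10^(cfg$snr_cap / 10)
  res <- vapply(seq_len(cfg$n_bands), function(b) {
    sig2 <- (2 * pi * cfg$centers[b] * cfg$ec_time_jitter)^2 +
      (log(10) / 20 * cfg$ec_amp_jitter_db)^2
    acc <- c(0, 0, 0)
    lag_first <- NA_real_
    for (st in starts) {
      i <- st:(st + win - 1)
      psl <- mean(sl[i, b]^2); pnl <- mean(nl[i, b]^2)
      psr <- mean(sr[i, b]^2); pnr <- mean(nr[i, b]^2)
      snr_l <- min(psl / max(pnl, psl / cap_lin), cap_lin)
      snr_r <- min(psr / max(pnr, psr / cap_lin), cap_lin)
      snr_e <- 0
      if (ec) {
        cn <- xcorr_lags(nl[i, b], nr[i, b], lags) / win
        cs <- xcorr_lags(sl[i, b], sr[i, b], lags) / win
        # residual powers over the (delay, gain) grid, closed form
        en <- outer(cn, gains, function(c_, g) pnl + g^2 * pnr - 2 * g * c_)
        es <- outer(cs, gains, function(c_, g) psl + g^2 * psr - 2 * g * c_)
        g2 <- matrix(gains^2, length(lags), length(gains), byrow = TRUE)
        en <- en + sig2 * (pnl + g2 * pnr)        # EC inaccuracy floor
        es <- es + sig2 * (psl + g2 * psr)
        snr_grid_vals <- es / pmax(en, es / cap_lin)
        best <- which.max(snr_grid_vals)
        snr_e <- min(snr_grid_vals[best], cap_lin)
        if (is.na(lag_first))
          lag_first <- lags[(best - 1) %% length(lags) + 1] / FS
      }
      acc <- acc + c(10 * log10(max(snr_l, 1e-10)),
                     10 * log10(max(snr_r, 1e-10)),
                     if (ec) 10 * log10(max(snr_e, 1e-10)) else -Inf)
    }
    c(acc / length(starts), lag_first)
  }, numeric(4))
  prof <- data.frame(freq = cfg$centers, snr_left = res[1, ],
                     snr_right = res[2, ],
                     snr_ec = if (ec) res[3, ] else -Inf,
                     ec_lag = res[4, ])
  prof$snr_best <- pmax(prof$snr_left, prof$snr_right, prof$snr_ec)
  prof$path <- c("left", "right", "ec")[
    max.col(cbind(prof$snr_left, prof$snr_right, prof$snr_ec),
            ties.method = "first")]
  class(prof) <- c("band_snr_profile", "data.frame")
  prof
}

#' Electro-acoustic weighting of two band-SNR profiles
#'
#' Combines the acoustic-side and electric-side band SNRs per band:
#' acoustic SNR carries full weight below the crossover, electric above,
#' with a linear crossfade over one octave centred on the crossover; the
#' combined SNR is the maximum of the two weighted, shifted profiles.
#'
#' @param acoustic_profile,electric_profile [band_snrs()] profiles on the
#'   same band grid
#' @param cfg a [bsim_config()]
#' @param shift_acoustic_db,shift_electric_db per-side SNR offsets
#' @return data.frame with `freq`, `snr` (dB), `side` per band
#' @export
ea_weight <- function(acoustic_profile, electric_profile,
                      cfg = bsim_config(), shift_acoustic_db = 0,
                      shift_electric_db = 0) {
  if (nrow(acoustic_profile) != nrow(electric_profile) ||
      any(abs(acoustic_profile$freq - electric_profile$freq) > 1e-6))
    stop("band-grid mismatch between profiles")
  f <- acoustic_profile$freq
  if (cfg$ea_weighting == "unit") {
    w_a <- rep(1, length(f)); w_e <- rep(1, length(f))
  } else {
    # acoustic weight 1 below crossover/sqrt2, 0 above crossover*sqrt2
    lo <- cfg$crossover_hz / sqrt(2); hi <- cfg$crossover_hz * sqrt(2)
    w_a <- pmin(pmax((log2(hi) - log2(f)) / (log2(hi) - log2(lo)), 0), 1)
    w_e <- 1 - w_a
  }
  sa0 <- acoustic_profile$snr_best + shift_acoustic_db
  se0 <- electric_profile$snr_best + shift_electric_db
  sa <- ifelse(w_a > 0 & is.finite(sa0), w_a * sa0, -Inf)
  se <- ifelse(w_e > 0 & is.finite(se0), w_e * se0, -Inf)
  # a band where the only audible path carries zero weight falls back to
  # that path unweighted (the crossfade cannot veto the sole side)
  fb <- !is.finite(pmax(sa, se))
  ca <- ifelse(fb & is.finite(sa0), sa0, sa)
  ce <- ifelse(fb & is.finite(se0), se0, se)
  data.frame(freq = f, snr = pmax(ca, ce),
             side = ifelse(ca >= ce, "acoustic", "electric"))
}

#' Speech intelligibility index from band SNRs
#'
#' Band audibility `clip((SNR + 15) / 30, 0, 1)` weighted by normalized
#' band-importance weights.
#'
#' @param band_snrs_db numeric vector of band SNRs (dB)
#' @param importance `"uniform"` or a weight vector (normalized to sum 1)
#' @return SII in [0, 1]
#' @export
sii <- function(band_snrs_db, importance = "uniform") {
  w <- if (identical(importance, "uniform")) {
    rep(1 / length(band_snrs_db), length(band_snrs_db))
  } else {
    if (abs(sum(importance) - 1) > 1e-6) importance <- importance /
        sum(importance)
    importance
  }
  aud <- pmin(pmax((band_snrs_db + 15) / 30, 0), 1)
  sum(w * aud)
}

#' Iterative SRT search by broadband speech gain
#'
#' Bisects on a broadband gain applied to the speech until the SII matches
#' the side's reference value; the SRT is the scene's base SNR plus the
#' converged gain.  `sii_fun(gain_db)` must be non-decreasing in the gain.
#'
#' @param sii_fun function mapping broadband speech gain (dB) to SII
#' @param reference target SII (0.26 acoustic / 0.42 CI by default usage)
#' @param base_snr_db the scene's nominal SNR (dB)
#' @param bounds gain search bracket (dB)
#' @param tol SII convergence tolerance
#' @param max_iter iteration cap
#' @return SRT (dB) with attribute `sii` (converged value)
#' @export
find_srt_sii <- function(sii_fun, reference, base_snr_db = 0,
                         bounds = c(-40, 40), tol = 1e-3, max_iter = 50) {
  lo <- bounds[1]; hi <- bounds[2]
  s_lo <- sii_fun(lo); s_hi <- sii_fun(hi)
  if (s_lo > reference || s_hi < reference)
    stop("reference SII not bracketed by the gain bounds; widen bounds")
  mid <- (lo + hi) / 2
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s <- sii_fun(mid)
    if (abs(s - reference) < tol) break
    if (s < reference) lo <- mid else hi <- mid
  }
  out <- base_snr_db + mid
  attr(out, "sii") <- sii_fun(mid)
  out
}

#' BSIM SRT prediction for one scenario/beamformer condition
#'
#' Builds the full SII chain: speech-shaped surrogate speech and scenario
#' noise are spatialized, the beamformer+HA chain is applied via
#' phase-inversion separation, the CI side is auralized, band SNRs with EC
#' are computed per side, combined by the electro-acoustic weighting, and
#' the SRT found by the iterative gain search.  Because separated speech
#' and noise shift band SNRs linearly with broadband speech gain, the gain
#' search shifts the measured profile.
#'
#' @param corpus corpus defining the speech long-term spectrum
#' @param scenario scenario id
#' @param beamformer `"NoBF"`, `"ADM"` or `"MVDR"`
#' @param cfg a [pipeline_config()]
#' @param bcfg a [bsim_config()]
#' @param side_mode `"bimodal"`, `"acoustic"` (HA side only) or `"ci"`
#' @param duration analysis duration (s)
#' @param base_snr_db nominal scene SNR (dB)
#' @param seed integer seed
#' @return SRT (dB); attributes carry the band profiles, the selected
#'   reference and the dominant side
#' @export
bsim_predict <- function(corpus, scenario, beamformer = "NoBF",
                         cfg = pipeline_config(), bcfg = bsim_config(),
                         side_mode = c("bimodal", "acoustic", "ci"),
                         duration = 2, base_snr_db = 0, seed = 1) {
  side_mode <- match.arg(side_mode)
  # surrogate speech: stationary noise with the corpus long-term spectrum
  speech <- make_speech_shaped_noise(corpus, duration,
                                     seed = derive_seed(seed, 1))
  scene <- scene_spec(scenario, base_snr_db)
  bank <- make_noise_bank(corpus, scene, derive_seed(seed, 2),
                          duration + 0.2)
  nz <- lapply(bank, fix_length, n = length(speech))
  parts <- mix_scene(scene, speech, cfg$head, noise_signals = nz)
  mvdr <- if (beamformer == "MVDR") mvdr_design(cfg$head) else NULL
  chain <- function(x4) {
    y2 <- beamform(x4, beamformer, cfg$head, mvdr = mvdr)
    y2[, 1] <- compress_ha(y2[, 1], cfg$audiogram, cfg$compressor)
    y2
  }
  sep <- hagerman_separate(chain, parts$speech_only, parts$noise_only)
  s2 <- sep$speech_hat; n2 <- sep$noise_hat
  # acoustic side: left ear, with audibility veto of sub-threshold bands
  ac_prof <- band_snrs(s2[, 1], n2[, 1], s2[, 1], n2[, 1], bcfg,
                       ec = FALSE)
  thr <- approx(log(mel_centers(cfg$acoustic)),
                threshold_spl(cfg$audiogram, cfg$acoustic),
                log(bcfg$centers), rule = 2)$y
  lvl <- vapply(seq_len(bcfg$n_bands), function(b) {
    xb <- gammatone_filter(s2[, 1], bcfg$centers[b], bcfg$erb[b])
    10 * log10(max(mean(xb^2), 1e-20) / 0.5) + cfg$acoustic$dbfs_spl
  }, numeric(1))
  ac_prof$snr_best[lvl < thr] <- -Inf            # inaudible bands
  # CI side: right ear auralized through the ACE/spread vocoder
  aur <- ci_auralize(s2[, 2], n2[, 2], cfg$ace, cfg$pop)
  ci_prof <- band_snrs(aur$speech_aur, aur$noise_aur,
                       aur$speech_aur, aur$noise_aur, bcfg, ec = FALSE)
  # binaural EC path across the two (device-processed) ear signals
  ec_prof <- if (side_mode == "bimodal") {
    band_snrs(s2[, 1], n2[, 1], aur$speech_aur, aur$noise_aur, bcfg,
              ec = TRUE)
  } else NULL
  profile <- switch(side_mode,
    acoustic = ac_prof$snr_best,
    ci = ci_prof$snr_best,
    bimodal = {
      comb <- ea_weight(ac_prof, ci_prof, bcfg)
      pmax(comb$snr, ec_prof$snr_ec)
    })
  side_dom <- switch(side_mode,
    acoustic = "acoustic", ci = "ci",
    bimodal = {
      comb <- ea_weight(ac_prof, ci_prof, bcfg)
      if (mean(comb$side == "acoustic") >= 0.5) "acoustic" else "ci"
    })
  reference <- if (side_dom == "acoustic") bcfg$sii_ref_acoustic
               else bcfg$sii_ref_ci
  srt <- find_srt_sii(function(g) sii(profile + g, bcfg$importance),
                      reference, base_snr_db = base_snr_db)
  attr(srt, "profile") <- profile
  attr(srt, "reference") <- reference
  attr(srt, "dominant_side") <- side_dom
  srt
}
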