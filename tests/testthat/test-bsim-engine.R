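test_that("SII bounds, hand computation and monotonicity", {
  expect_equal(sii(rep(20, 30)), 1.0)
  expect_equal(sii(rep(-20, 30)), 0.0)
  # two equal-importance bands at 0 and +15 dB: (0.5 + 1)/2
  expect_equal(sii(c(0, 15)), 0.75)
  # monotone non-decreasing in every band SNR
  set.seed(41)
  base <- runif(30, -20, 20)
  s0 <- sii(base)
  for (b in sample(30, 5)) {
    up <- base; up[b] <- up[b] + 5
    expect_gte(sii(up), s0)
  }
  # custom importance is normalized
  expect_equal(sii(c(15, -15), importance = c(2, 2)), 0.5)
})

test_that("bisection SRT search matches an exhaustive fine-grid oracle", {
  # synthetic monotone SII curve with a known crossing
  curve <- function(g) 1 / (1 + exp(-(g + 7.3) / 2.1))
  ref <- 0.26
  srt <- find_srt_sii(curve, ref, base_snr_db = -3)
  gains <- seq(-40, 40, by = 0.001)
  oracle <- gains[which.min(abs(curve(gains) - ref))]
  expect_lt(abs(as.numeric(srt) - (-3 + oracle)), 0.05)
  # invariant to the starting bracket when it contains the crossing
  srt2 <- find_srt_sii(curve, ref, base_snr_db = -3, bounds = c(-20, 10))
  expect_lt(abs(as.numeric(srt) - as.numeric(srt2)), 0.05)
  # fixed point: reference equal to the SII at zero gain
  srt3 <- find_srt_sii(curve, curve(0), base_snr_db = 5)
  expect_lt(abs(as.numeric(srt3) - 5), 0.05)
  expect_error(find_srt_sii(curve, 0.9999, bounds = c(-5, 5)),
               "not bracketed")
  # default references of the two sides
  cfg <- bsim_config()
  expect_equal(cfg$sii_ref_acoustic, 0.26)
  expect_equal(cfg$sii_ref_ci, 0.42)
  expect_error(bsim_config(sii_ref_ci = 1.5), "references")
})

test_that("band SNRs implement better-ear selection", {
  set.seed(42)
  n <- 8192
  sp <- rnorm(n) * 0.1
  nz <- rnorm(n)
  # left SNR 5 dB, right 0 dB, EC disabled
  cfg <- bsim_config()
  prof <- band_snrs(sp, nz * 0.1 * 10^(-5 / 20), sp, nz * 0.1, cfg,
                    ec = FALSE)
  expect_true(all(abs(prof$snr_best - prof$snr_left) < 1e-9))
  expect_true(all(prof$snr_left - prof$snr_right > 3))
  expect_true(all(prof$path %in% c("left", "right")))
})

test_that("EC cancels identical noise and recovers interaural delay", {
  set.seed(43)
  n <- 8192
  nz <- rnorm(n)
  sp <- rnorm(n) * 0.5
  cfg <- bsim_config(ec_amp_jitter_db = 0, ec_time_jitter = 0)
  # identical noise in both ears, speech in the left ear only:
  # cancellation removes the noise up to the SNR cap
  prof <- band_snrs(sp, nz, numeric(n), nz, cfg)
  expect_true(all(prof$snr_ec >= cfg$snr_cap - 1e-6))
  # EC can only help when processing errors are off
  set.seed(44)
  prof2 <- band_snrs(rnorm(n) * 0.3, rnorm(n), rnorm(n) * 0.3, rnorm(n),
                     cfg)
  expect_true(all(prof2$snr_ec >=
                    pmax(prof2$snr_left, prof2$snr_right) - 0.75))
  # known interaural noise delay of 0.5 ms is recovered within one step
  lagn <- round(0.0005 * fs)
  nzr <- c(numeric(lagn), nz[1:(n - lagn)])
  prof3 <- band_snrs(sp, nz, sp * 0, nzr, cfg)
  mid <- which.min(abs(cfg$centers - 1000))
  expect_lt(abs(abs(prof3$ec_lag[mid]) - 0.0005), cfg$ec_delay_step + 1e-9)
  # exhaustive-search oracle at that band: best lag over the same grid
  bl <- bimodalsrt:::gammatone_filter(nz, cfg$centers[mid], cfg$erb[mid])
  br <- bimodalsrt:::gammatone_filter(nzr, cfg$centers[mid], cfg$erb[mid])
  lags <- round(seq(-cfg$ec_max_delay, cfg$ec_max_delay,
                    by = cfg$ec_delay_step) * fs)
  resid <- vapply(lags, function(l) {
    bshift <- if (l >= 0) c(numeric(l), br[1:(1024 - l)])
              else br[(1 - l):1024]
    g <- sum(bl[1:length(bshift)] * bshift) / max(sum(bshift^2), 1e-12)
    sum((bl[1:length(bshift)] - g * bshift)^2)
  }, numeric(1))
  oracle_lag <- lags[which.min(resid)] / fs
  expect_lt(abs(abs(prof3$ec_lag[mid]) - abs(oracle_lag)),
            cfg$ec_delay_step + 1e-9)
})

test_that("EC processing inaccuracies limit cancellation", {
  set.seed(45)
  n <- 8192
  nz <- rnorm(n)
  sp <- rnorm(n) * 0.5
  cfg_err <- bsim_config()                      # default jitter on
  prof <- band_snrs(sp, nz, numeric(n), nz, cfg_err)
  # perfect-cancellation SNR cap is no longer reached in any band
  expect_true(all(prof$snr_ec < cfg_err$snr_cap - 1))
  # degradation grows with frequency (time jitter dominates at HF)
  expect_gt(prof$snr_ec[2], prof$snr_ec[30])
})

test_that("electro-acoustic weighting combines profiles band-wise", {
  cfg <- bsim_config(ea_weighting = "unit")
  f <- cfg$centers
  mk <- function(snr) {
    p <- data.frame(freq = f, snr_left = snr, snr_right = snr,
                    snr_ec = -Inf, snr_best = snr, path = "left")
    class(p) <- c("band_snr_profile", "data.frame"); p
  }
  ac <- mk(ifelse(f < 1000, 10, -5))            # acoustic better low
  el <- mk(ifelse(f < 1000, -5, 8))             # electric better high
  comb <- ea_weight(ac, el, cfg)
  expect_equal(comb$snr, pmax(ac$snr_best, el$snr_best))
  expect_true(all(comb$side[f < 1000] == "acoustic"))
  expect_true(all(comb$side[f >= 1000] == "electric"))
  # electric at -Inf everywhere: output equals the acoustic profile,
  # under unit and under crossover weighting
  el_off <- mk(-Inf)
  expect_equal(ea_weight(ac, el_off, cfg)$snr, ac$snr_best)
  cfg_x <- bsim_config()
  expect_equal(ea_weight(ac, el_off, cfg_x)$snr[f < 600],
               ac$snr_best[f < 600])
  expect_equal(ea_weight(ac, el_off, cfg_x)$snr[f > 2000],
               ac$snr_best[f > 2000])
  # identical profiles with unit weights: output equals either profile
  expect_equal(ea_weight(ac, ac, cfg)$snr, ac$snr_best)
  bad <- mk(0); bad$freq <- bad$freq * 2
  expect_error(ea_weight(ac, bad, cfg), "band-grid")
})

test_that("CI auralization concentrates energy in the mapped band", {
  ace <- ace_config()
  pop <- nerve_population(n_cells = 110)
  # silence in, silence out
  aur0 <- ci_auralize(numeric(4000), numeric(4000), ace, pop)
  expect_equal(aur0$speech_aur, numeric(4000))
  # a tone exciting one channel: auralized energy peaks at that band
  freqs <- bimodalsrt:::ace_channel_freqs(ace)
  target_ch <- 12
  t <- (1:8000) / fs
  tone <- sin(2 * pi * freqs[target_ch] * t) * 0.05
  aur <- ci_auralize(tone, numeric(8000), ace, pop)
  cfg <- bsim_config()
  pows <- vapply(seq_len(cfg$n_bands), function(b)
    mean(bimodalsrt:::gammatone_filter(aur$speech_aur, cfg$centers[b],
                                       cfg$erb[b])[2000:8000]^2),
    numeric(1))
  peak_f <- cfg$centers[which.max(pows)]
  expect_lt(abs(log2(peak_f / freqs[target_ch])), 0.5)
  # envelope grows monotonically with sub-saturation input level
  lv <- vapply(c(0.01, 0.03, 0.06), function(a) {
    au <- ci_auralize(tone / 0.05 * a, numeric(8000), ace, pop)
    rms(au$speech_aur)
  }, numeric(1))
  expect_true(all(diff(lv) > 0))
})

test_that("BSIM predicts a beamformer benefit in a lateral-noise scene", {
  corp <- desk_corpus()
  cfg <- pipeline_config(pop = nerve_population(n_cells = 110))
  s_nobf <- bsim_predict(corp, "S0N-90", "NoBF", cfg, duration = 1,
                         seed = 3)
  s_mvdr <- bsim_predict(corp, "S0N-90", "MVDR", cfg, duration = 1,
                         seed = 3)
  expect_lte(as.numeric(s_mvdr), as.numeric(s_nobf))
  expect_true(attr(s_nobf, "reference") %in% c(0.26, 0.42))
})
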