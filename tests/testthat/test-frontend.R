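test_that("ADM implements the front-minus-scaled-back beam combination", {
  set.seed(3)
  n4 <- spatialize(rnorm(8000) * 0.05, 150)      # rear-half-plane source
  beams <- bimodalsrt:::adm_beams(n4[, 1], n4[, 2], 0.01)
  # beta frozen at 0: output is exactly the front beam
  y0 <- adm_process(n4[, 1], n4[, 2], adm_state(beta = 0, adapt = FALSE))
  expect_equal(as.numeric(y0), beams$cf, tolerance = 1e-12)
  # beta frozen at 0.5: output is cF - 0.5 cB
  y5 <- adm_process(n4[, 1], n4[, 2], adm_state(beta = 0.5, adapt = FALSE))
  expect_equal(as.numeric(y5), beams$cf - 0.5 * beams$cb,
               tolerance = 1e-12)
  expect_error(adm_process(rnorm(10), rnorm(9)), "length")
})

test_that("adapted ADM beta reaches the grid-search energy optimum", {
  set.seed(4)
  n4 <- spatialize(rnorm(32000) * 0.05, 150)
  y <- adm_process(n4[, 1], n4[, 2], adm_state())
  beta_hat <- attr(y, "beta_final")
  beams <- bimodalsrt:::adm_beams(n4[, 1], n4[, 2], 0.01)
  betas <- seq(0, 1, by = 0.001)
  energies <- vapply(betas, function(b)
    sum((beams$cf - b * beams$cb)^2), numeric(1))
  beta_star <- betas[which.min(energies)]
  expect_lt(abs(beta_hat - beta_star), 0.05)
  # adapted output energy is no worse than the beta = 0 output and within
  # 1% of the grid minimum on the final half of the signal
  tailidx <- 16001:32000
  e_adapt <- sum((beams$cf[tailidx] - beta_hat * beams$cb[tailidx])^2)
  e_zero <- sum(beams$cf[tailidx]^2)
  e_star <- min(vapply(betas, function(b)
    sum((beams$cf[tailidx] - b * beams$cb[tailidx])^2), numeric(1)))
  expect_lte(e_adapt, e_zero * (1 + 1e-9))
  expect_lt(e_adapt, e_star * 1.01)
})

test_that("MVDR weights match the closed form and keep the constraint", {
  # 2-mic toy against the hand-computed closed form
  Sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  d <- c(1, 1)
  w <- mvdr_weights(Sigma, d)
  expect_equal(Re(w), c(0.5, 0.5), tolerance = 1e-12)
  # independent matrix-inversion oracle
  oracle <- solve(Sigma) %*% d / as.numeric(t(d) %*% solve(Sigma) %*% d)
  expect_equal(as.complex(w), as.complex(oracle), tolerance = 1e-12)
  # identity coherence, d = e1: pass-through of the reference mic
  w2 <- mvdr_weights(diag(4), c(1, 0, 0, 0))
  expect_equal(as.complex(w2), as.complex(c(1, 0, 0, 0)))
  # full design: distortionless constraint per bin for both outputs
  filt <- mvdr_design()
  for (side in 1:2) {
    resid <- vapply(seq_along(filt$freqs), function(k) {
      d <- filt$d[k, ] / filt$d[k, c(1, 3)[side]]
      Mod(sum(Conj(filt$w[k, , side]) * d) - 1)
    }, numeric(1))
    expect_lt(max(resid), 1e-6)
  }
  expect_error(mvdr_weights(matrix(1, 2, 2), c(1, 1)), "singular")
})

test_that("MVDR processing passes frontal targets and reduces diffuse noise", {
  filt <- mvdr_design()
  set.seed(5)
  # band-limited target (real audio has no energy at Nyquist; the STFT
  # realization of the fractional steering delay is inexact there)
  x <- bimodalsrt:::fft_filter(rnorm(8000) * 0.05, function(f)
    as.numeric(f < 7000))
  sp4 <- spatialize(x, 0)
  out <- mvdr_process(sp4, filt)
  resid_db <- 20 * log10(rms(out[, 1] - sp4[, 1]) / rms(sp4[, 1]))
  expect_lt(resid_db, -40)
  # synthetic isotropic field: sum of independent sources all around
  iso <- matrix(0, 8000 + 64, 4)
  for (az in seq(-180, 170, by = 30))
    iso <- iso + spatialize(rnorm(8000) * 0.02, az)
  y <- mvdr_process(iso, filt)
  expect_lte(mean(y[, 1]^2), mean(iso[, 1]^2))
  expect_lte(mean(y[, 2]^2), mean(iso[, 3]^2))
  expect_equal(mvdr_process(matrix(0, 1000, 4), filt),
               matrix(0, 1000, 2))
  expect_error(mvdr_process(matrix(0, 100, 3), filt), "samples-by-4")
})

test_that("compressor prescription follows the capped CAMFIT-style rule", {
  cfg <- compressor_config()
  # 0 dB HL: no gain, identity up to reconstruction error
  ag0 <- audiogram(c(125, 8000), c(0, 0))
  expect_true(all(camfit_gains(ag0, cfg) == 0))
  set.seed(6)
  x <- rnorm(8000) * 0.03
  y <- compress_ha(x, ag0, cfg)
  expect_lt(20 * log10(rms(y - x) / rms(x)), -40)
  # silence maps to silence
  expect_equal(compress_ha(numeric(1000), default_audiogram(), cfg),
               numeric(1000))
  # HL cap: 95 dB HL prescribes the same gain as 90 dB HL
  g95 <- camfit_gains(audiogram(c(125, 8000), c(95, 95)), cfg)
  g90 <- camfit_gains(audiogram(c(125, 8000), c(90, 90)), cfg)
  expect_equal(g95, g90)
  # no gain at/above the 5 kHz upper frequency limit
  ghi <- camfit_gains(audiogram(c(125, 8000), c(60, 60)), cfg)
  expect_true(all(ghi[cfg$centers >= 5000] == 0))
  expect_true(all(ghi[cfg$centers < 5000] > 0))
})

test_that("steady-state compressor gain matches the static table", {
  # linear region (ratio 1): band output level = input level + table gain
  cfg <- compressor_config(ratio = 1,
                           gain_table = c(0, 0, 0, 6, 0, 0, 0, 0, 0))
  f0 <- cfg$centers[4]
  t <- (1:16000) / fs
  x <- sin(2 * pi * f0 * t) * 0.01
  y <- compress_ha(x, default_audiogram(), cfg)
  gain_db <- 20 * log10(rms(y[8000:16000]) / rms(x[8000:16000]))
  expect_lt(abs(gain_db - 6), 0.5)
})

test_that("phase-inversion separation is exact for linear chains", {
  set.seed(7)
  s <- rnorm(4000) * 0.05; n <- rnorm(4000) * 0.05
  # identity
  sep <- hagerman_separate(identity, s, n)
  expect_equal(sep$speech_hat, s, tolerance = 1e-14)
  expect_equal(sep$noise_hat, n, tolerance = 1e-14)
  # static gain
  sep <- hagerman_separate(function(x) 0.3 * x, s, n)
  expect_equal(sep$speech_hat, 0.3 * s, tolerance = 1e-14)
  # nonlinear memoryless compressor: re-addition identity holds exactly,
  # nonlinear error vs direct processing is finite and reported
  soft <- function(x) tanh(3 * x)
  sep <- hagerman_separate(soft, s, n)
  expect_lt(max(abs(sep$speech_hat + sep$noise_hat - soft(s + n))), 1e-14)
  nl_err <- rms(sep$speech_hat - soft(s)) / rms(soft(s))
  expect_true(is.finite(nl_err) && nl_err > 0)
  expect_error(hagerman_separate(identity, s, n[1:10]), "shape")
})

test_that("full linear front-end chain separates below -60 dB error", {
  corp <- tiny_corpus()
  sp <- corp$sentences[[1]]$waveform
  mx <- mix_scene(scene_spec("S0N-90", 0), sp, corpus = corp, seed = 9)
  filt <- mvdr_design()
  chain <- function(x4) mvdr_process(x4, filt)     # linear chain
  sep <- hagerman_separate(chain, mx$speech_only, mx$noise_only)
  direct_s <- chain(mx$speech_only)
  rel <- rms(sep$speech_hat - direct_s) / rms(direct_s)
  expect_lt(20 * log10(max(rel)), -60)
})
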