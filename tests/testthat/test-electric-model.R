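test_that("ACE selects the N largest envelopes and orders base-to-apex", {
  set.seed(21)
  x <- rnorm(8000) * 0.05
  cfg <- ace_config()
  eg <- ace_encode(x, cfg)
  env <- attr(eg, "envelopes")
  adv <- cfg$fs / cfg$channel_rate
  base <- cfg$base_frac *
    (sum(0.5 - 0.5 * cos(2 * pi * (0:127) / 128)) / 2)
  starts <- round((seq_len(attr(eg, "n_cycles")) - 1) * adv)
  cycle_of <- findInterval(eg$time * cfg$fs + 1e-6, starts)
  for (k in unique(cycle_of)[1:40]) {
    sel <- eg$electrode[cycle_of == k]
    # brute-force top-N oracle on the recorded envelopes (ties: lower ch)
    oracle <- order(-env[k, ], seq_len(cfg$M))[seq_len(cfg$N)]
    oracle <- oracle[env[k, oracle] > base]
    expect_setequal(sel, oracle)
    # base-to-apex: descending center frequency within the cycle
    expect_true(all(diff(sel) < 0))
    tt <- eg$time[cycle_of == k]
    expect_true(all(diff(tt) > 0))
  }
  expect_lte(max(table(cycle_of)), cfg$N)
  expect_error(ace_encode(x, cfg, fs = 8000), "mismatch")
})

test_that("stimulation rates respect the channel and total rate limits", {
  cfg <- ace_config()
  # per-channel rate never exceeds the channel rate
  set.seed(22)
  x <- rnorm(fs) * 0.05
  eg <- ace_encode(x, cfg)
  dur <- attr(eg, "duration")
  per_ch <- table(factor(eg$electrode, levels = 1:22)) / dur
  expect_true(all(per_ch <= cfg$channel_rate * 1.001))
  # loud broadband input drives all N maxima: total rate ~ N x 900
  loud <- x / max(abs(x))
  eg2 <- ace_encode(loud, cfg)
  total_rate <- nrow(eg2) / attr(eg2, "duration")
  expect_lt(abs(total_rate - 7200) / 7200, 0.02)
})

test_that("current spread follows the double-sided exponential", {
  pop <- nerve_population(n_cells = 141, cochlea_len = 35)
  eg <- structure(data.frame(time = 0, electrode = 11L, amplitude = 120),
                  class = c("electrodogram", "data.frame"))
  sc <- spread_current(eg, pop)
  d <- abs(pop$cell_positions - pop$electrode_positions[11])
  expect_equal(as.numeric(sc$stim), 120 * exp(-d / 1), tolerance = 1e-12)
  # printed anchors: 36.8% at 1 mm, e^-2 at 2 mm; symmetry in distance
  sm <- bimodalsrt:::spread_matrix(nerve_population(n_cells = 2200))
  expect_equal(exp(-1), 0.368, tolerance = 5e-4)
  i <- which.min(abs(nerve_population(n_cells = 2200)$cell_positions -
                       (pop$electrode_positions[11] + 1)))
  expect_equal(sm[11, i], exp(-1), tolerance = 1e-2)
  expect_equal(exp(-2), 0.1353, tolerance = 5e-4)
})

test_that("integrate-and-fire dynamics match the closed-form ISI", {
  dt <- 1 / 7200
  pop <- nerve_population(n_cells = 1, noise_sd = 0, jitter_sd = 0,
                          rel_amp = 0, current_scale = 1)
  # zero stimulus, noise off: no spikes
  stim0 <- list(times = (0:199) * dt, stim = matrix(0, 200, 1))
  expect_equal(nrow(simulate_population(stim0, pop, seed = 1)), 0)
  # sustained suprathreshold drive: periodic firing at the closed-form ISI
  s <- 0.4                                      # threshold = 1
  stim <- list(times = (0:599) * dt, stim = matrix(s, 600, 1))
  sp <- simulate_population(stim, pop, seed = 1)
  isi <- diff(sp$time)
  expect_gt(nrow(sp), 5)
  expect_lt(diff(range(isi)), 1e-12)            # strictly periodic
  a <- exp(-dt / pop$tau_m)
  k_blocked <- sum((1:100) * dt < pop$t_abs)    # events lost to refractory
  m_star <- ceiling(log(1 - (1 - a) / s) / log(a))
  isi_oracle <- (k_blocked + m_star) * dt
  expect_lt(abs(isi[1] - isi_oracle), dt + 1e-12)
  # two pulses closer than the absolute refractory period: <= 1 spike
  stim2 <- list(times = c(0, 2e-4), stim = matrix(5, 2, 1))
  expect_lte(nrow(simulate_population(stim2, pop, seed = 1)), 1)
  expect_error(simulate_population(
    list(times = 0, stim = matrix(NaN, 1, 1)), pop), "non-finite")
})

test_that("spike probability per pulse is monotone in amplitude", {
  pop <- nerve_population(n_cells = 1, noise_sd = 0.3, jitter_sd = 0,
                          rel_amp = 0, current_scale = 1)
  p_fire <- function(amp) {
    hits <- vapply(1:1000, function(sd_)
      nrow(simulate_population(list(times = 0, stim = matrix(amp, 1, 1)),
                               pop, seed = sd_)), numeric(1))
    mean(hits > 0)
  }
  p <- vapply(c(0.4, 0.8, 1.2), p_fire, numeric(1))
  expect_true(all(diff(p) > 0))
  expect_gt(p[3], 0.7)
  expect_lt(p[1], 0.3)
})

test_that("internal representation integrates spikes as configured", {
  pop <- nerve_population(n_cells = 46)
  cfg <- ir_config(noise_var = 0)
  # a single spike: output trace equals Gaussian kernel (x) integrator
  spikes <- data.frame(time = 0.1, cell = 23L)
  ir <- internal_representation(spikes, pop, cfg, n_frames = 40, seed = 1)
  g <- which(ir[20, ] > 0 | ir[15, ] > 0)
  expect_length(g, 1)
  # direct-convolution oracle on the fine grid
  dt <- cfg$dt
  n_bins <- ceiling((40 * 0.010 + 0.05) / dt)
  imp <- numeric(n_bins); imp[floor(0.1 / dt) + 1] <- 1
  half <- ceiling(4 * cfg$gauss_sd / dt)
  kern <- exp(-0.5 * ((-half:half) * dt / cfg$gauss_sd)^2)
  kern <- kern / sum(kern)
  smooth <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    js <- max(1, i - half):min(n_bins, i + half)
    smooth[i] <- sum(imp[js] * kern[half + 1 + (i - js)])
  }
  a <- exp(-dt / cfg$integrator_tau)
  y <- numeric(n_bins)
  for (i in seq_len(n_bins)) y[i] <- (if (i > 1) a * y[i - 1] else 0) +
    (1 - a) * smooth[i]
  frame_bins <- round(((1:40) - 1) * 0.010 / dt + 0.010 / 2 / dt) + 1
  expect_equal(ir[, g], y[frame_bins], tolerance = 1e-9)
  # multiplicative noise has mean 1, variance 0.1 at defaults
  cfg2 <- ir_config()
  expect_equal(cfg2$noise_var, 0.1)
  expect_error(internal_representation(spikes, pop, ir_config(n_groups = 0),
                                       n_frames = 10), "group")
})

test_that("feature normalization yields zero mean and unit variance", {
  set.seed(23)
  feats <- lapply(1:5, function(i) matrix(rnorm(200, 3, 2), 20, 10))
  norm <- normalize_features(feats)
  all_ <- do.call(rbind, norm)
  expect_lt(max(abs(colMeans(all_))), 1e-6)
  expect_lt(max(abs(apply(all_, 2, var) - 1)), 1e-6)
  # training stats applied to held-out data reuse the same transform
  st <- attr(norm, "stats")
  test_norm <- normalize_features(feats[1], stats = st)
  expect_equal(test_norm[[1]], norm[[1]])
})

test_that("electric pathway is bit-reproducible under a fixed seed", {
  corp <- tiny_corpus()
  w <- corp$sentences[[1]]$waveform[1:8000]
  pop <- nerve_population(n_cells = 110)
  f1 <- electric_features(w, pop = pop, seed = 4)
  f2 <- electric_features(w, pop = pop, seed = 4)
  expect_identical(f1, f2)
  f3 <- electric_features(w, pop = pop, seed = 5)
  expect_false(identical(f1, f3))
})
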