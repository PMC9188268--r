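# Electric (CI side) pathway: ACE n-of-m coding, exponential current spread
# along the cochlea, a stochastic leaky integrate-and-fire auditory-nerve
# population, and the spatially/temporally integrated "internal
# representation" used as electric features.

#' ACE coding strategy configuration
#'
#' The ACE strategy analyses 128-sample (8 ms at 16 kHz) Hann-windowed
#' frames at the per-channel stimulation rate, groups FFT bins into M = 22
#' band envelopes, selects the N = 8 largest per cycle and maps them
#' log-compressively onto the electrode's threshold/comfort current range.
#'
#' @param M analysis channels (electrodes)
#' @param N maxima selected per cycle
#' @param channel_rate per-channel stimulation rate (pulses/s)
#' @param frame_len analysis frame (samples)
#' @param fs sampling rate (Hz)
#' @param thl,mcl threshold / most-comfortable current levels (clinical
#'   units), recycled to M electrodes
#' @param base_frac,sat_frac envelope base and saturation levels as
#'   fractions of the full-scale envelope
#' @param rho log-compression steepness
#' @param sensitivity input gain (linear) of the processor's microphone
#'   sensitivity stage, mapping conversational-level input onto the
#'   base-to-saturation envelope range
#' @export
ace_config <- function(M = 22L, N = 8L, channel_rate = 900,
                       frame_len = 128L, fs = FS, thl = 100, mcl = 200,
                       base_frac = 4 / 256, sat_frac = 150 / 256,
                       rho = 416.2, sensitivity = 20) {
  if (N > M) stop("N must not exceed M")
  structure(list(M = M, N = N, channel_rate = channel_rate,
                 frame_len = frame_len, fs = fs,
                 thl = rep_len(thl, M), mcl = rep_len(mcl, M),
                 base_frac = base_frac, sat_frac = sat_frac, rho = rho,
                 sensitivity = sensitivity),
            class = "ace_config")
}

# quasi-logarithmic FFT-bin grouping: 22 contiguous groups covering bin
# edges 187.5-7937.5 Hz (bins 2..63, 0-based) with log-spaced boundaries
# snapped to bins (>= 1 bin per group)
ace_bin_groups <- function(cfg) {
  bin_hz <- cfg$fs / cfg$frame_len
  lo_bin <- 2L; hi_bin <- as.integer(cfg$frame_len / 2 - 1)  # 2..63
  n_bins <- hi_bin - lo_bin + 1L
  edges_hz <- exp(seq(log((lo_bin - 0.5) * bin_hz),
                      log((hi_bin + 0.5) * bin_hz),
                      length.out = cfg$M + 1))
  edges <- round(edges_hz / bin_hz - 0.5) + 0.5
  # enforce >= 1 bin per group and exact coverage
  edges[1] <- lo_bin - 0.5; edges[cfg$M + 1] <- hi_bin + 0.5
  for (i in 2:cfg$M) edges[i] <- max(edges[i], edges[i - 1] + 1)
  for (i in cfg$M:2) edges[i] <- min(edges[i], edges[i + 1] - 1)
  lapply(seq_len(cfg$M), function(g)
    seq(ceiling(edges[g]), floor(edges[g + 1])))   # 0-based bin indices
}

# channel center frequencies (Hz), channel 1 = lowest (most apical)
ace_channel_freqs <- function(cfg) {
  bin_hz <- cfg$fs / cfg$frame_len
  vapply(ace_bin_groups(cfg), function(b) mean(b) * bin_hz, numeric(1))
}

#' Encode a signal into a CI electrodogram with the ACE strategy
#'
#' @param signal mono waveform at `cfg$fs`
#' @param cfg an [ace_config()]
#' @param fs sampling rate of `signal`; must equal `cfg$fs`
#' @return object of class `electrodogram`: data.frame with `time` (s),
#'   `electrode` (1 = apical .. M = basal), `amplitude` (clinical units),
#'   pulses within each cycle in base-to-apex order; attributes `cfg`,
#'   `duration`, `n_cycles`, `envelopes` (cycles x M matrix)
#' @export
ace_encode <- function(signal, cfg = ace_config(), fs = FS) {
  if (fs != cfg$fs) stop("sampling rate mismatch: signal must be at cfg$fs")
  flen <- cfg$frame_len
  advance <- cfg$fs / cfg$channel_rate        # fractional; drift-compensated
  n <- length(signal)
  n_cycles <- max(0L, floor((n - flen) / advance) + 1L)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / flen)
  groups <- ace_bin_groups(cfg)
  env_fs <- sum(w) / 2                        # full-scale tone envelope
  base <- cfg$base_frac * env_fs
  sat <- cfg$sat_frac * env_fs
  total_rate <- cfg$channel_rate * cfg$N
  env_mat <- matrix(0, n_cycles, cfg$M)
  out <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    start <- round((k - 1) * advance)         # 0-based start sample
    frame <- signal[(start + 1):(start + flen)] * w * cfg$sensitivity
    X <- fft(frame)
    env <- vapply(groups, function(b) Mod(sum(X[b + 1])), numeric(1))
    env_mat[k, ] <- env
    # N largest envelopes; ties broken toward the lower channel index
    sel <- order(-env, seq_len(cfg$M))[seq_len(cfg$N)]
    sel <- sel[env[sel] > base]               # sub-base: no pulse emitted
    if (length(sel) == 0) next
    # base-to-apex: highest center frequency (channel M) first
    sel <- sort(sel, decreasing = TRUE)
    v <- pmin((env[sel] - base) / (sat - base), 1)
    amp <- cfg$thl[sel] + (cfg$mcl[sel] - cfg$thl[sel]) *
      log(1 + cfg$rho * v) / log(1 + cfg$rho)
    t0 <- start / cfg$fs
    out[[k]] <- data.frame(time = t0 + (seq_along(sel) - 1) / total_rate,
                           electrode = sel, amplitude = amp)
  }
  eg <- do.call(rbind, out)
  if (is.null(eg))
    eg <- data.frame(time = numeric(0), electrode = integer(0),
                     amplitude = numeric(0))
  structure(eg, cfg = cfg, duration = n / cfg$fs, n_cycles = n_cycles,
            envelopes = env_mat, class = c("electrodogram", "data.frame"))
}

#' Auditory-nerve population geometry and membrane parameters
#'
#' @param n_cells nerve cells, equidistant over the cochlear length
#' @param cochlea_len cochlear duct length (mm)
#' @param electrode_positions electrode positions from the apex (mm)
#' @param lambda_spread exponential current-spread constant (mm)
#' @param threshold membrane threshold (drive units)
#' @param tau_m membrane time constant (s)
#' @param t_abs absolute refractory period (s)
#' @param tau_rel relative-refractory recovery time constant (s)
#' @param rel_amp relative-refractory threshold elevation at onset
#'   (fraction of threshold)
#' @param noise_sd membrane noise SD as a fraction of threshold
#' @param latency spike latency (s)
#' @param jitter_sd spike-time jitter SD (s)
#' @param current_scale clinical-units-to-membrane-drive factor
#' @export
nerve_population <- function(n_cells = 2200, cochlea_len = 35,
                             electrode_positions = seq(8.125, 23.875,
                                                       by = 0.75),
                             lambda_spread = 1, threshold = 1,
                             tau_m = 0.5e-3, t_abs = 0.5e-3,
                             tau_rel = 1e-3, rel_amp = 1,
                             noise_sd = 0.05, latency = 0.5e-3,
                             jitter_sd = 50e-6, current_scale = 1 / 120) {
  cell_positions <- seq(0, cochlea_len,
                        length.out = n_cells + 2)[2:(n_cells + 1)]
  structure(list(n_cells = n_cells, cochlea_len = cochlea_len,
                 electrode_positions = electrode_positions,
                 cell_positions = cell_positions,
                 lambda_spread = lambda_spread, threshold = threshold,
                 tau_m = tau_m, t_abs = t_abs, tau_rel = tau_rel,
                 rel_amp = rel_amp, noise_sd = noise_sd, latency = latency,
                 jitter_sd = jitter_sd, current_scale = current_scale),
            class = "nerve_population")
}

# n_electrodes x n_cells exponential spread attenuation matrix
spread_matrix <- function(pop) {
  exp(-abs(outer(pop$electrode_positions, pop$cell_positions, "-")) /
        pop$lambda_spread)
}

#' Spread electrode currents onto the nerve-cell array
#'
#' Each pulse stimulates every cell with its amplitude attenuated by
#' `exp(-distance / lambda)` (a 36.8% drop 1 mm away at the default
#' `lambda = 1` mm).
#'
#' @param electrodogram an [ace_encode()] electrodogram
#' @param pop a [nerve_population()]
#' @return list with `times` (s) and `stim`, a pulses-by-cells matrix of
#'   per-cell stimulus amplitudes (dense; intended for short signals)
#' @export
spread_current <- function(electrodogram, pop) {
  sm <- spread_matrix(pop)
  list(times = electrodogram$time,
       stim = electrodogram$amplitude *
         sm[electrodogram$electrode, , drop = FALSE])
}

#' Simulate the integrate-and-fire nerve population
#'
#' Event-driven leaky integrate-and-fire dynamics per cell: the membrane
#' integrates pulse-grid input with exponential leak, spikes on threshold
#' crossing, is absolutely then relatively refractory, receives additive
#' Gaussian membrane noise per pulse, and emits each spike at the crossing
#' time plus latency plus Gaussian jitter.  Bit-reproducible under a seed.
#'
#' @param stimuli either an [ace_encode()] electrodogram (currents spread
#'   internally, memory-efficient) or a [spread_current()] list of per-cell
#'   stimulus time series
#' @param pop a [nerve_population()]
#' @param seed integer seed
#' @return data.frame of spike events (`time` s, `cell` index), time-sorted
#' @export
simulate_population <- function(stimuli, pop, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (inherits(stimuli, "electrodogram")) {
    if (any(!is.finite(stimuli$amplitude))) stop("non-finite stimulus")
    res <- lif_population_cpp(
      stimuli$time, as.integer(stimuli$electrode),
      stimuli$amplitude * pop$current_scale, spread_matrix(pop),
      pop$tau_m, pop$threshold, pop$t_abs, pop$tau_rel, pop$rel_amp,
      pop$noise_sd * pop$threshold, pop$latency, pop$jitter_sd)
  } else {
    if (any(!is.finite(stimuli$stim))) stop("non-finite stimulus")
    res <- lif_population_dense_cpp(
      stimuli$times, stimuli$stim * pop$current_scale,
      pop$tau_m, pop$threshold, pop$t_abs, pop$tau_rel, pop$rel_amp,
      pop$noise_sd * pop$threshold, pop$latency, pop$jitter_sd)
  }
  sp <- data.frame(time = res$time, cell = res$cell)
  sp[order(sp$time), , drop = FALSE]
}

#' Internal-representation configuration
#'
#' @param n_groups spatial groups (46 by default so the concatenated
#'   electric+acoustic feature dimension is 77; 22 = one group per
#'   electrode is available via config)
#' @param gauss_sd Gaussian temporal-smoothing SD (s)
#' @param integrator_tau recursive leaky-integrator time constant (s)
#' @param noise_var variance of the multiplicative (mean 1) Gaussian noise
#' @param dt internal binning step (s)
#' @export
ir_config <- function(n_groups = 46, gauss_sd = 2e-3,
                      integrator_tau = 10e-3, noise_var = 0.1,
                      dt = 1e-3) {
  structure(list(n_groups = n_groups, gauss_sd = gauss_sd,
                 integrator_tau = integrator_tau, noise_var = noise_var,
                 dt = dt),
            class = "ir_config")
}

# spatial group centers (mm from apex)
ir_group_centers <- function(pop, n_groups) {
  if (n_groups == length(pop$electrode_positions))
    return(pop$electrode_positions)
  seq(min(pop$electrode_positions), max(pop$electrode_positions),
      length.out = n_groups)
}

#' Internal representation: integrated auditory-nerve activity
#'
#' Bins spikes into spatial groups (cells assigned to the nearest group
#' center, boundaries at midpoints), smooths each group's spike-count time
#' series with a Gaussian FIR followed by a first-order recursive
#' integrator, samples the result on the acoustic feature frame grid, and
#' multiplies by white Gaussian noise with mean 1 (central degradation).
#' Use [normalize_features()] to z-score features over a corpus.
#'
#' @param spikes data.frame from [simulate_population()]
#' @param pop the [nerve_population()] that produced the spikes
#' @param cfg an [ir_config()]
#' @param n_frames number of output frames
#' @param frame_shift frame hop (s), matching the acoustic features
#' @param seed integer seed for the multiplicative noise
#' @return frames-by-`n_groups` matrix
#' @export
internal_representation <- function(spikes, pop, cfg = ir_config(),
                                    n_frames, frame_shift = 0.010,
                                    seed = 1) {
  if (cfg$n_groups < 1) stop("empty group axis")
  centers <- ir_group_centers(pop, cfg$n_groups)
  dur <- n_frames * frame_shift + 0.05
  n_bins <- ceiling(dur / cfg$dt)
  act <- matrix(0, n_bins, cfg$n_groups)
  if (nrow(spikes) > 0) {
    cell_group <- vapply(pop$cell_positions, function(p)
      which.min(abs(centers - p)), integer(1))
    g <- cell_group[spikes$cell]
    b <- pmin(pmax(floor(spikes$time / cfg$dt) + 1, 1), n_bins)
    for (i in seq_along(g)) act[b[i], g[i]] <- act[b[i], g[i]] + 1
  }
  # Gaussian FIR (temporal resolution reduction) then recursive integrator
  half <- max(1L, ceiling(4 * cfg$gauss_sd / cfg$dt))
  kern <- exp(-0.5 * ((-half:half) * cfg$dt / cfg$gauss_sd)^2)
  kern <- kern / sum(kern)
  a <- exp(-cfg$dt / cfg$integrator_tau)
  sm <- apply(act, 2, function(col) {
    col <- as.numeric(stats::filter(c(numeric(half), col, numeric(half)),
                                    kern, sides = 2))[(half + 1):(half + n_bins)]
    col[is.na(col)] <- 0
    as.numeric(stats::filter(col * (1 - a), a, method = "recursive"))
  })
  # sample on the feature frame grid (frame centers)
  frame_bins <- pmin(pmax(round(((seq_len(n_frames) - 1) * frame_shift +
                                   frame_shift / 2) / cfg$dt) + 1, 1), n_bins)
  ir <- sm[frame_bins, , drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ir * matrix(rnorm(length(ir), 1, sqrt(cfg$noise_var)), nrow(ir))
}

#' Z-score a list of feature matrices with pooled per-column statistics
#'
#' @param feats list of frames-by-dim matrices (same dim)
#' @param stats optional precomputed list(mean, sd) to apply (e.g. training
#'   statistics applied to test data)
#' @return list of normalized matrices; attribute `stats` carries the
#'   pooled mean/sd used
#' @export
normalize_features <- function(feats, stats = NULL) {
  all <- do.call(rbind, feats)
  if (is.null(stats)) {
    m <- colMeans(all)
    s <- apply(all, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    stats <- list(mean = m, sd = s)
  }
  out <- lapply(feats, function(f)
    sweep(sweep(f, 2, stats$mean), 2, stats$sd, "/"))
  attr(out, "stats") <- stats
  out
}

#' Full electric feature pathway for one signal
#'
#' ACE encoding, current spread, integrate-and-fire population and internal
#' representation, on the acoustic feature frame grid.
#'
#' @param signal mono waveform
#' @param ace an [ace_config()]
#' @param pop a [nerve_population()]
#' @param ir an [ir_config()]
#' @param acfg the [acoustic_config()] defining the frame grid
#' @param seed integer seed (population and IR noise derive from it)
#' @return frames-by-`n_groups` matrix (unnormalized)
#' @export
electric_features <- function(signal, ace = ace_config(),
                              pop = nerve_population(), ir = ir_config(),
                              acfg = acoustic_config(), seed = 1) {
  n_frames <- floor((length(signal) - round(acfg$frame_len * FS)) /
                      round(acfg$frame_shift * FS)) + 1
  eg <- ace_encode(signal, ace)
  sp <- simulate_population(eg, pop, seed = derive_seed(seed, 11L))
  internal_representation(sp, pop, ir, n_frames,
                          frame_shift = acfg$frame_shift,
                          seed = derive_seed(seed, 12L))
}

#' Write / read an electrodogram as delimited text
#' @param eg an electrodogram
#' @param path file path
#' @export
write_electrodogram <- function(eg, path) {
  write.table(as.data.frame(eg)[, c("time", "electrode", "amplitude")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_electrodogram
#' @export
read_electrodogram <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  structure(tab, class = c("electrodogram", "data.frame"))
}
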