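# Acoustic (hearing-aid side) feature pathway: log-Mel spectrogram in dB
# SPL, then audibility gating against the listener's hearing threshold --
# sub-threshold cells are replaced by unit-variance Gaussian noise so the
# recognizer cannot exploit inaudible energy.

#' Acoustic feature configuration
#'
#' @param sample_rate Hz (the chain runs at 16 kHz)
#' @param frame_len analysis frame (s)
#' @param frame_shift hop (s)
#' @param n_mel Mel bands
#' @param dbfs_spl calibration: level of a full-scale sinusoid (dB SPL)
#' @export
acoustic_config <- function(sample_rate = FS, frame_len = 0.025,
                            frame_shift = 0.010, n_mel = 31,
                            dbfs_spl = 100) {
  if (frame_len <= frame_shift) stop("frame_len must exceed frame_shift")
  if (n_mel < 1) stop("n_mel must be >= 1")
  structure(list(sample_rate = sample_rate, frame_len = frame_len,
                 frame_shift = frame_shift, n_mel = n_mel,
                 dbfs_spl = dbfs_spl),
            class = "acoustic_config")
}

hz2mel <- function(f) 2595 * log10(1 + f / 700)
mel2hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular Mel filterbank matrix (n_bins x n_mel) on the rfft grid
mel_filterbank <- function(n_fft, n_mel, fs) {
  n_bins <- n_fft / 2 + 1
  freqs <- seq(0, n_fft / 2) * fs / n_fft
  mels <- seq(hz2mel(0), hz2mel(fs / 2), length.out = n_mel + 2)
  cf <- mel2hz(mels)
  fb <- matrix(0, n_bins, n_mel)
  for (m in seq_len(n_mel)) {
    lo <- cf[m]; mid <- cf[m + 1]; hi <- cf[m + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

# Mel band center frequencies for a config
mel_centers <- function(cfg) {
  mels <- seq(hz2mel(0), hz2mel(cfg$sample_rate / 2),
              length.out = cfg$n_mel + 2)
  mel2hz(mels[2:(cfg$n_mel + 1)])
}

#' Log-Mel spectrogram in dB SPL
#'
#' Frames the signal (25 ms / 10 ms default), applies a normalized Hamming
#' window, takes the FFT magnitude (FFT size: next power of two at or above
#' the frame length), weights and sums with a triangular Mel filterbank and
#' takes the base-10 logarithm.  Values are calibrated so a full-scale
#' sinusoid reads `dbfs_spl` dB SPL in its band.
#'
#' @param signal mono waveform
#' @param cfg an [acoustic_config()]
#' @return frames-by-`n_mel` matrix (dB SPL) with attribute `frame_times`
#'   (frame start times, s)
#' @export
logmel <- function(signal, cfg = acoustic_config()) {
  fs <- cfg$sample_rate
  flen <- round(cfg$frame_len * fs)
  hop <- round(cfg$frame_shift * fs)
  if (length(signal) < flen) stop("signal shorter than one frame")
  frames <- frame_signal(signal, flen, hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  w <- w / sqrt(mean(w^2))                      # normalized window
  n_fft <- next_pow2(flen)
  padded <- rbind(frames * w, matrix(0, n_fft - flen, ncol(frames)))
  spec <- abs(stats::mvfft(padded))[seq_len(n_fft / 2 + 1), , drop = FALSE]^2
  fb <- mel_filterbank(n_fft, cfg$n_mel, fs)
  melspec <- t(spec) %*% fb                     # frames x n_mel
  # full-scale sine at a bin center: peak bin power (sum(w)/2)^2
  p_ref <- (sum(w) / 2)^2
  out <- 10 * log10(pmax(melspec, 1e-30) / p_ref) + cfg$dbfs_spl
  attr(out, "frame_times") <- (seq_len(nrow(out)) - 1) * cfg$frame_shift
  out
}

# ISO 226:2003 threshold-of-hearing curve (dB SPL), tabulated
ISO226_FREQ <- c(20, 25, 31.5, 40, 50, 63, 80, 100, 125, 160, 200, 250,
                 315, 400, 500, 630, 800, 1000, 1250, 1600, 2000, 2500,
                 3150, 4000, 5000, 6300, 8000)
ISO226_THR <- c(78.5, 68.7, 59.5, 51.1, 44.0, 37.5, 31.5, 26.5, 22.1,
                17.9, 14.4, 11.4, 8.6, 6.2, 4.4, 3.0, 2.2, 2.4, 3.5,
                1.7, -1.3, -4.2, -6.0, -5.4, -1.5, 6.0, 12.6)

#' Hearing threshold in dB SPL at the Mel band centers
#'
#' The standard threshold-of-hearing curve (log-frequency interpolated to
#' the band centers) plus the interpolated audiometric hearing loss; band
#' centers outside the tabulated support are clamped with a warning.
#'
#' @param ag an [audiogram()]
#' @param cfg an [acoustic_config()]
#' @return numeric vector of length `n_mel` (dB SPL)
#' @export
threshold_spl <- function(ag, cfg = acoustic_config()) {
  cf <- mel_centers(cfg)
  if (any(cf < min(ISO226_FREQ) | cf > max(ISO226_FREQ)))
    warning("band centers outside the threshold table support; clamped")
  iso <- approx(log(ISO226_FREQ), ISO226_THR,
                log(pmin(pmax(cf, min(ISO226_FREQ)), max(ISO226_FREQ))))$y
  iso + interp_hl(ag, cf)
}

#' Apply audibility gating to a feature matrix
#'
#' Expresses features relative to the hearing threshold (sensation level)
#' and replaces strictly sub-threshold entries by draws from a standard
#' normal distribution, modelling loss of audibility.  Entries exactly at
#' threshold are kept.
#'
#' @param features frames-by-bands matrix (dB SPL)
#' @param thresholds per-band thresholds (dB SPL), length = band count
#' @param seed integer seed for the Gaussian fill
#' @return gated matrix with attribute `replaced` (logical mask)
#' @export
apply_audibility <- function(features, thresholds, seed = 1) {
  if (ncol(features) != length(thresholds))
    stop("band count mismatch between features and thresholds")
  rel <- sweep(features, 2, thresholds)
  mask <- rel < 0
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rel[mask] <- rnorm(sum(mask))
  attr(rel, "replaced") <- mask
  rel
}

#' Read an audiogram from a two-column delimited text file (Hz, dB HL)
#' @param path file path
#' @export
read_audiogram <- function(path) {
  tab <- read.table(path, header = FALSE)
  audiogram(tab[[1]], tab[[2]])
}
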