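#' @useDynLib bimodalsrt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft sd var approx convolve cor pt
#' @importFrom utils head tail read.table write.table
NULL

# package-wide sampling rate: the whole chain runs at 16 kHz
FS <- 16000L

db <- function(x) 20 * log10(x)
undb <- function(x) 10^(x / 20)

#' Root-mean-square of a signal
#' @param x numeric vector or matrix (columns are channels)
#' @return scalar RMS (vector input) or per-column RMS (matrix input)
#' @export
rms <- function(x) {
  if (is.matrix(x)) return(sqrt(colMeans(x^2)))
  sqrt(mean(x^2))
}

rms_db <- function(x) 20 * log10(pmax(rms(x), .Machine$double.xmin))

#' Broadband level difference between two signals in dB
#' @keywords internal
level_diff_db <- function(a, b) rms_db(a) - rms_db(b)

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))

# zero-pad x to length n (or truncate)
fix_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

# linear-phase FFT filtering of a real signal with a frequency response
# sampled on the non-negative rfft grid of length nfft/2+1.
# Returns a signal of length length(x) + tail.
fft_filter <- function(x, resp, tail = 0L) {
  n_out <- length(x) + tail
  nfft <- next_pow2(n_out)
  h_half <- resp(seq(0, nfft / 2) * FS / nfft)   # complex response at >=0 freqs
  h_full <- c(h_half, Conj(rev(h_half[2:(nfft / 2)])))
  X <- fft(fix_length(x, nfft))
  y <- Re(fft(X * h_full, inverse = TRUE)) / nfft
  y[seq_len(n_out)]
}

# fractional delay of tau seconds via FFT phase ramp (exact for band-limited x)
frac_delay <- function(x, tau, tail = 0L) {
  fft_filter(x, function(f) exp(-2i * pi * f * tau), tail = tail)
}

# frames x of a signal as columns of a matrix; no padding (last partial frame
# dropped)
frame_signal <- function(x, frame_len, hop) {
  n_frames <- floor((length(x) - frame_len) / hop) + 1
  if (n_frames < 1) stop("signal shorter than one frame")
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, "+")
  matrix(x[idx], nrow = frame_len)
}

# mixes a seed with a stream label so sub-generators are decorrelated but
# reproducible; keeps the result a valid 32-bit integer seed
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

stopifnot_same_length <- function(a, b) {
  if (length(a) != length(b)) stop("signals must have the same length")
}
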