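# Beamformers: monaural adaptive differential microphone (ADM) per side and
# a fixed binaural MVDR designed against a spherically isotropic diffuse
# field.  Both consume the 4-channel head-microphone signal; outputs are the
# 2-channel (left, right) ear signals of the device chain.  The NoBF control
# condition simply passes the two front microphones.

#' ADM state/configuration
#'
#' The adaptive differential microphone forms fixed front- and rear-pointing
#' cardioid beams from a closely spaced microphone pair (delay-and-subtract)
#' and outputs `y(t) = cF(t) - beta * cB(t)`, with the scalar blocking-beam
#' coefficient `beta` adapted by a normalized gradient step to minimize
#' output energy, clamped to [0, 1] so the null stays in the rear
#' half-plane.
#'
#' @param beta initial blocking coefficient
#' @param step_size normalized LMS step
#' @param beta_bounds clamp interval
#' @param block_len adaptation block (samples; 128 = 8 ms at 16 kHz)
#' @param mic_spacing front/rear spacing (m) defining the cardioid delay
#' @param adapt logical; `FALSE` freezes `beta`
#' @export
adm_state <- function(beta = 0, step_size = 0.1, beta_bounds = c(0, 1),
                      block_len = 128L, mic_spacing = 0.01, adapt = TRUE) {
  structure(list(beta = beta, step_size = step_size,
                 beta_bounds = beta_bounds, block_len = block_len,
                 mic_spacing = mic_spacing, adapt = adapt),
            class = "adm_state")
}

# fixed cardioid beams from a front/rear pair: delay-and-subtract with the
# acoustic travel-time delay of the spacing
adm_beams <- function(front, rear, mic_spacing) {
  tau <- mic_spacing / 343
  cf <- front - frac_delay(rear, tau)[seq_along(front)]
  cb <- rear - frac_delay(front, tau)[seq_along(front)]
  list(cf = cf, cb = cb)
}

#' Process a microphone pair with the ADM
#'
#' @param front_mic,rear_mic equal-length mono signals of one side's
#'   front/rear microphones
#' @param state an [adm_state()]
#' @return mono output with attributes `beta_trace` (per-block beta) and
#'   `beta_final`
#' @export
adm_process <- function(front_mic, rear_mic, state = adm_state()) {
  stopifnot_same_length(front_mic, rear_mic)
  b <- adm_beams(front_mic, rear_mic, state$mic_spacing)
  cf <- b$cf; cb <- b$cb
  n <- length(cf)
  blk <- state$block_len
  beta <- state$beta
  n_blocks <- ceiling(n / blk)
  y <- numeric(n)
  trace <- numeric(n_blocks)
  for (k in seq_len(n_blocks)) {
    idx <- ((k - 1) * blk + 1):min(k * blk, n)
    yk <- cf[idx] - beta * cb[idx]
    y[idx] <- yk
    if (state$adapt) {
      p <- sum(cb[idx]^2) + 1e-12
      beta <- beta + state$step_size * sum(yk * cb[idx]) / p
      beta <- min(max(beta, state$beta_bounds[1]), state$beta_bounds[2])
    }
    trace[k] <- beta
  }
  attr(y, "beta_trace") <- trace
  attr(y, "beta_final") <- beta
  y
}

# microphone positions (m) in the horizontal plane, x to the right,
# y to the front, order: LF, LR, RF, RR
mic_positions <- function(head) {
  e <- head$ear_distance / 2; s <- head$mic_spacing
  rbind(c(-e, s / 2), c(-e, -s / 2), c(e, s / 2), c(e, -s / 2))
}

#' Design a binaural MVDR beamformer
#'
#' Per FFT bin `w = Sigma^-1 d / (d^H Sigma^-1 d)` with the steering vector
#' `d` taken from the head model's frontal (0 degree) transfer function and
#' `Sigma` the spherically isotropic diffuse-field coherence
#' `sinc(2 pi f d_ij / c)` of the microphone geometry, diagonally loaded.
#' Two filters are produced, referenced to the left-front and right-front
#' microphones, so each output preserves the respective ear's frontal target
#' response (distortionless constraint `w^H d = 1` per bin).
#'
#' @param head a [head_model()]
#' @param n_fft STFT size (hop is `n_fft/2`, sqrt-Hann analysis/synthesis)
#' @param diffuse_model `"spherical"` (isotropic sinc coherence) or
#'   `"identity"` (uncorrelated noise)
#' @param loading diagonal loading as a fraction of `trace(Sigma)/n_mics`
#' @return object of class `mvdr_filter` with `w` (bins x 4 x 2 complex)
#' @export
#' @rdname mvdr_design
#' @param Sigma noise spatial covariance/coherence matrix
#' @param d steering vector
#' @param loading diagonal loading fraction (of `trace/n`)
mvdr_weights <- function(Sigma, d, loading = 0) {
  n <- nrow(Sigma)
  Sigma <- Sigma + loading * (sum(diag(Sigma)) / n) * diag(n)
  sol <- tryCatch(solve(Sigma, d),
                  error = function(e)
                    stop("singular coherence matrix; ",
                         "increase diagonal loading"))
  sol / sum(Conj(d) * sol)
}

#' @export
mvdr_design <- function(head = head_model(), n_fft = 256L,
                        diffuse_model = c("spherical", "identity"),
                        loading = 1e-3) {
  diffuse_model <- match.arg(diffuse_model)
  pos <- mic_positions(head)
  dist <- as.matrix(stats::dist(pos))
  freqs <- seq(0, n_fft / 2) * FS / n_fft
  n_bins <- length(freqs)
  w <- array(0i, c(n_bins, 4, 2))
  d_all <- head_transfer(head, 0, freqs)     # bins x 4
  for (k in seq_len(n_bins)) {
    f <- freqs[k]
    Sigma <- if (diffuse_model == "spherical") {
      arg <- 2 * pi * f * dist / 343
      S <- ifelse(arg == 0, 1, sin(arg) / arg)
      S
    } else diag(4)
    for (out in 1:2) {
      ref <- c(1, 3)[out]
      d <- d_all[k, ] / d_all[k, ref]        # reference-mic normalization
      w[k, , out] <- mvdr_weights(Sigma, d, loading)
    }
  }
  structure(list(w = w, d = d_all, n_fft = n_fft, freqs = freqs,
                 diffuse_model = diffuse_model, loading = loading),
            class = "mvdr_filter")
}

# STFT helpers (sqrt-Hann analysis and synthesis, 50% overlap: COLA exact)
stft_frames <- function(x, n_fft) {
  hop <- n_fft / 2
  x <- c(numeric(hop), x, numeric(n_fft))
  n_frames <- floor((length(x) - n_fft) / hop) + 1
  w <- sqrt(0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / n_fft))
  list(spec = stats::mvfft(frame_signal(x, n_fft, hop) * w),
       n_frames = n_frames, hop = hop, w = w)
}
istft_frames <- function(spec, n_fft, n_out) {
  hop <- n_fft / 2
  w <- sqrt(0.5 - 0.5 * cos(2 * pi * (seq_len(n_fft) - 1) / n_fft))
  frames <- Re(stats::mvfft(spec, inverse = TRUE)) / n_fft * w
  y <- numeric((ncol(spec) - 1) * hop + n_fft)
  for (m in seq_len(ncol(spec))) {
    idx <- ((m - 1) * hop + 1):((m - 1) * hop + n_fft)
    y[idx] <- y[idx] + frames[, m]
  }
  y[(hop + 1):(hop + n_out)]
}

#' Apply an MVDR beamformer to a 4-channel signal
#'
#' @param x samples-by-4 matrix (LF, LR, RF, RR)
#' @param filt an [mvdr_design()] filter
#' @return samples-by-2 matrix (left, right ear outputs)
#' @export
mvdr_process <- function(x, filt) {
  if (!is.matrix(x) || ncol(x) != 4)
    stop("x must be a samples-by-4 matrix")
  n_fft <- filt$n_fft
  n <- nrow(x)
  S <- lapply(seq_len(4), function(ch) stft_frames(x[, ch], n_fft))
  n_bins <- n_fft / 2 + 1
  out <- matrix(0, n, 2)
  for (side in 1:2) {
    Y <- matrix(0i, n_fft, ncol(S[[1]]$spec))
    for (ch in seq_len(4)) {
      wk <- Conj(filt$w[, ch, side])                  # y = w^H x
      wk_full <- c(wk, Conj(rev(wk[2:(n_bins - 1)])))
      Y <- Y + S[[ch]]$spec * wk_full
    }
    out[, side] <- istft_frames(Y, n_fft, n)
  }
  out
}

#' Run a beamformer over a 4-channel scene signal
#'
#' Convenience front-end dispatcher: `"NoBF"` passes the two front
#' microphones, `"ADM"` runs one adaptive differential microphone per side,
#' `"MVDR"` applies the binaural MVDR design.
#'
#' @param x samples-by-4 matrix
#' @param method `"NoBF"`, `"ADM"` or `"MVDR"`
#' @param head head model (for MVDR design / ADM spacing)
#' @param mvdr optional precomputed [mvdr_design()]
#' @return samples-by-2 matrix (left, right)
#' @export
beamform <- function(x, method = c("NoBF", "ADM", "MVDR"),
                     head = head_model(), mvdr = NULL) {
  method <- match.arg(method)
  switch(method,
    NoBF = x[, c(1, 3)],
    ADM = cbind(
      adm_process(x[, 1], x[, 2],
                  adm_state(mic_spacing = head$mic_spacing)),
      adm_process(x[, 3], x[, 4],
                  adm_state(mic_spacing = head$mic_spacing))),
    MVDR = {
      if (is.null(mvdr)) mvdr <- mvdr_design(head)
      mvdr_process(x, mvdr)
    })
}
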