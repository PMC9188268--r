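# Instrumental SNR benefit, SRT benefit, and model-vs-reference agreement
# statistics.

#' Instrumental SNR improvement of a beamformer chain
#'
#' The input SNR is measured at the side's front microphone; the output SNR
#' on the separated outputs obtained by processing speech+noise and
#' speech-noise through the chain (phase inversion), so adaptive and
#' nonlinear chains are handled.  Improvement = output - input.  SNRs are
#' broadband, over speech-active samples.
#'
#' @param speech_4ch,noise_4ch separated scene signals (samples x 4)
#' @param beamformer `"NoBF"`, `"ADM"` or `"MVDR"`
#' @param side `"left"` or `"right"`
#' @param head a [head_model()]
#' @param mvdr optional precomputed [mvdr_design()]
#' @param chain optional custom processing function (samples x 4 ->
#'   samples x 2), overriding `beamformer`
#' @return list(input_snr, output_snr, improvement) in dB
#' @export
instrumental_snr <- function(speech_4ch, noise_4ch, beamformer = "NoBF",
                             side = c("left", "right"),
                             head = head_model(), mvdr = NULL,
                             chain = NULL) {
  side <- match.arg(side)
  ch_in <- if (side == "left") 1L else 3L
  ch_out <- if (side == "left") 1L else 2L
  gate <- speech_active_gate(speech_4ch[, ch_in])
  input_snr <- 10 * log10(mean(speech_4ch[gate, ch_in]^2) /
                            mean(noise_4ch[gate, ch_in]^2))
  proc <- if (is.null(chain)) {
    function(x4) beamform(x4, beamformer, head, mvdr = mvdr)
  } else chain
  sep <- hagerman_separate(proc, speech_4ch, noise_4ch)
  s_out <- sep$speech_hat[, ch_out]; n_out <- sep$noise_hat[, ch_out]
  gate_o <- speech_active_gate(s_out)
  output_snr <- 10 * log10(mean(s_out[gate_o]^2) / mean(n_out[gate_o]^2))
  list(input_snr = input_snr, output_snr = output_snr,
       improvement = output_snr - input_snr)
}

#' SRT benefit of an algorithm over the no-beamformer condition
#'
#' Positive values mean the algorithm lowered (improved) the SRT.
#'
#' @param srt_nobf,srt_alg SRTs (dB) from the same scenario and model
#' @return benefit in dB
#' @export
srt_benefit <- function(srt_nobf, srt_alg) {
  as.numeric(srt_nobf) - as.numeric(srt_alg)
}

#' Agreement between predicted and reference values
#'
#' Pearson correlation (with a two-sided t-based p value) and RMS error.
#'
#' @param predicted,reference equal-length numeric vectors (n >= 3 for r)
#' @return list(pearson_r, p_value, rmse)
#' @export
agreement <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("vectors must have equal length")
  if (length(predicted) < 3)
    stop("need at least 3 pairs for a correlation")
  r <- cor(predicted, reference)
  n <- length(predicted)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  if (abs(r) == 1) p <- 0
  list(pearson_r = r, p_value = p,
       rmse = sqrt(mean((predicted - reference)^2)))
}
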