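# Phase-inversion (Hagerman-Olofsson) separation: recovers separately
# processed speech and noise from a possibly nonlinear, adaptive processing
# chain by processing the sum and the difference of the two inputs.

#' Separate processed speech and noise by phase inversion
#'
#' Processes `speech + noise` and `speech - noise` through `process` and
#' forms `speech_hat = (P(s+n) + P(s-n))/2`,
#' `noise_hat = (P(s+n) - P(s-n))/2`.  For a linear chain the recovery is
#' exact; for nonlinear chains the re-addition identity
#' `speech_hat + noise_hat == P(s+n)` still holds to numerical precision.
#' `process` must be deterministic (any adaptation state is reset per call).
#'
#' @param process function mapping a waveform (vector or matrix) to a
#'   waveform; applied twice with identical internal state
#' @param speech,noise equal-length waveforms (vectors or equal-shape
#'   matrices)
#' @return list(speech_hat, noise_hat)
#' @export
hagerman_separate <- function(process, speech, noise) {
  if (is.matrix(speech) != is.matrix(noise) ||
      !identical(dim(speech), dim(noise)) ||
      length(speech) != length(noise))
    stop("speech and noise must have identical shape")
  p1 <- process(speech + noise)
  p2 <- process(speech - noise)
  if (length(p1) != length(p2))
    stop("process must be deterministic (outputs differ in length)")
  list(speech_hat = (p1 + p2) / 2, noise_hat = (p1 - p2) / 2)
}
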