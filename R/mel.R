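#' Convert frequency between hertz and mels
#'
#' The analysis expresses all formant values on the mel scale, a perceptual
#' frequency scale that is approximately linear below 1 kHz and logarithmic
#' above. The conversion used is the O'Shaughnessy form
#' \deqn{m = k \log_{10}(1 + f / c)}
#' with \eqn{k = 2595} and corner frequency \eqn{c = 700} Hz, the convention
#' of the real-time formant-perturbation software ecosystem. Both constants
#' can be overridden for compatibility with other conventions.
#'
#' @param f_hz Frequency in hertz (vector, all values >= 0).
#' @param m_mel Frequency in mels (vector, all values >= 0).
#' @param k,corner_hz Scale constant and corner frequency of the mel map.
#'
#' @return `hz_to_mel()` returns mels; `mel_to_hz()` returns hertz. The two
#'   are exact inverses on `[0, Inf)`.
#'
#' @examples
#' hz_to_mel(700) # 2595 * log10(2)
#' mel_to_hz(hz_to_mel(550))
#' @export
hz_to_mel <- function(f_hz, k = 2595, corner_hz = 700) {
  if (any(!is.finite(f_hz)) || any(f_hz < 0)) {
    abort("`f_hz` must be finite and >= 0.")
  }
  k * log10(1 + f_hz / corner_hz)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m_mel, k = 2595, corner_hz = 700) {
  if (any(!is.finite(m_mel)) || any(m_mel < 0)) {
    abort("`m_mel` must be finite and >= 0.")
  }
  corner_hz * (10^(m_mel / k) - 1)
}
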