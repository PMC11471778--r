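#' Compressed acoustic envelope of a speech waveform
#'
#' Mimics early auditory processing: the waveform is half-wave rectified,
#' low-pass filtered with a type I (even-order, linear-phase) FIR filter
#' designed by the Kaiser method (cutoff \code{fc}, transition bandwidth
#' \code{transitionBw}, stop-band attenuation \code{stopAttenDb} dB,
#' pass-band ripple about 1e-3 relative to peak), compressed by a cube root,
#' and resampled to \code{targetFs}. Filtering is applied zero-phase; small
#' negative excursions from filter ringing are clipped at 0 before the
#' compression.
#'
#' @param waveform numeric audio samples.
#' @param audioFs audio sampling rate in Hz (> 40).
#' @param targetFs output sampling rate in Hz.
#' @param fc low-pass cutoff in Hz.
#' @param transitionBw transition bandwidth in Hz.
#' @param stopAttenDb stop-band attenuation in dB.
#' @param exponent compression exponent (default 1/3).
#' @return numeric envelope sampled at \code{targetFs}, non-negative.
#' @export
computeEnvelope <- function(waveform, audioFs, targetFs, fc = 20,
                            transitionBw = 10, stopAttenDb = 60,
                            exponent = 1 / 3) {
  if (audioFs <= 40) stop("'audioFs' must exceed 40 Hz")
  if (any(!is.finite(waveform))) stop("waveform must be finite")
  h <- .firLowpassKaiser(audioFs, fc, transitionBw, stopAttenDb)
  if (length(waveform) < length(h))
    stop("waveform (", length(waveform),
         " samples) is shorter than the filter (", length(h), " taps)")
  rect <- pmax(waveform, 0)
  lp <- .filterZeroPhase(h, rect)
  env <- pmax(lp, 0)^exponent
  n <- length(env)
  tIn <- (seq_len(n) - 1) / audioFs
  m <- floor(n * targetFs / audioFs)
  tOut <- (seq_len(m) - 1) / targetFs
  stats::approx(tIn, env, xout = tOut, rule = 2)$y
}
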