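#' Band-limited analytic signal
#'
#' Band-pass filters each channel with a linear-phase windowed-sinc FIR
#' filter (transition width 25% of the lower edge, floored at 1 Hz) and
#' forms the analytic signal by quadrature (imaginary part = Hilbert
#' transform), so that \code{Mod(z)} is the instantaneous amplitude and
#' \code{Arg(z)} the instantaneous phase. By default filtering is zero-phase
#' (the symmetric FIR applied with its group delay compensated); with
#' \code{causal = TRUE} the filter runs forward only and delays the signal by
#' its group delay, which avoids pre-stimulus leakage at the cost of a phase
#' lag.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param band a \linkS4class{BandSpec} within (0, fs/2).
#' @param causal use forward-only filtering (default FALSE = zero-phase).
#' @return An \linkS4class{AnalyticBundle} of kind \code{"amp_weighted"}
#'   carrying the band's own amplitude and phase.
#' @export
bandpassAnalytic <- function(rec, band, causal = FALSE) {
  fs <- rec@fs
  if (band@fHi >= fs / 2)
    stop("band edge ", band@fHi, " Hz is at or above Nyquist (", fs / 2,
         " Hz)")
  h <- .firBandpass(fs, band@fLo, band@fHi)
  filt <- if (causal) .filterCausal else .filterZeroPhase
  z <- t(apply(rec@signal, 1, function(x) .analytic(filt(h, x))))
  if (nrow(rec@signal) == 1) z <- matrix(z, nrow = 1)
  new("AnalyticBundle", z = z, kind = "amp_weighted", fs = fs,
      phaseBand = band, ampBand = band, stories = rec@stories,
      nZeroAmp = 0L)
}

#' Unit-modulus phase signal
#'
#' Normalises an analytic signal to unit modulus, \code{z / |z|}, keeping
#' only the instantaneous phase. Zero-amplitude samples (where phase is
#' undefined) are set to 0 and counted in the \code{nZeroAmp} slot.
#'
#' @param a an \linkS4class{AnalyticBundle}.
#' @return A unit-phase \linkS4class{AnalyticBundle}; idempotent.
#' @export
unitPhase <- function(a) {
  m <- Mod(a@z)
  zero <- m == 0
  m[zero] <- 1
  z <- a@z / m
  z[zero] <- 0 + 0i
  new("AnalyticBundle", z = z, kind = "unit_phase", fs = a@fs,
      phaseBand = a@phaseBand, ampBand = a@ampBand, stories = a@stories,
      nZeroAmp = a@nZeroAmp + sum(zero))
}

#' Cross-band amplitude-weighted carrier
#'
#' Combines the amplitude of a high-frequency analytic signal with the phase
#' of a low-frequency one into the complex carrier
#' \code{r_high(t) * exp(i * phi_low(t))}, the quantity whose event-locked
#' mean vector length (or complex-TRF coefficients) measures phase-amplitude
#' coupling.
#'
#' @param phaseSig analytic bundle providing the phase (low band).
#' @param ampSig analytic bundle providing the amplitude (high band).
#' @return An \linkS4class{AnalyticBundle} of kind \code{"amp_weighted"}
#'   with the phase band of \code{phaseSig} and the amplitude band of
#'   \code{ampSig}. Overlapping bands trigger a warning, not an error.
#' @export
pacCarrier <- function(phaseSig, ampSig) {
  if (!identical(dim(phaseSig@z), dim(ampSig@z)) ||
      !isTRUE(all.equal(phaseSig@fs, ampSig@fs)))
    stop("phase and amplitude bundles must share channels, length and fs")
  if (phaseSig@phaseBand@fHi >= ampSig@ampBand@fLo)
    warning("phase band upper edge (", phaseSig@phaseBand@fHi,
            " Hz) reaches into the amplitude band")
  m <- Mod(phaseSig@z)
  m[m == 0] <- 1
  z <- Mod(ampSig@z) * (phaseSig@z / m)
  new("AnalyticBundle", z = z, kind = "amp_weighted", fs = phaseSig@fs,
      phaseBand = phaseSig@phaseBand, ampBand = ampSig@ampBand,
      stories = phaseSig@stories, nZeroAmp = phaseSig@nZeroAmp)
}

#' Epoch a recording or analytic signal around events
#'
#' Cuts equal-length windows around each onset (no baseline applied). Events
#' whose window falls outside the recording are dropped and counted. Windows
#' may overlap freely, as words in naturalistic speech do.
#'
#' @param x a \linkS4class{ContinuousRecording} or
#'   \linkS4class{AnalyticBundle}.
#' @param events an \linkS4class{OnsetTrain} (onsets are taken relative to
#'   the start of the story whose id matches, or to the recording start when
#'   no story matches) or a numeric vector of onset seconds relative to the
#'   recording start.
#' @param pre,post window extent in seconds before and after each onset
#'   (both >= 0); the time axis runs from \code{-pre} to \code{post} and
#'   includes 0.
#' @return An \linkS4class{EpochSet} (complex when \code{x} is analytic).
#' @export
epochData <- function(x, events, pre = 0.2, post = 0.6) {
  sig <- signalData(x)
  fs <- samplingRate(x)
  st <- stories(x)
  if (is(events, "OnsetTrain")) {
    offset <- 0
    hit <- match(events@storyId, st$story_id)
    if (!is.na(hit)) offset <- (st$start[hit] - 1) / fs
    onsets <- events@onsets + offset
  } else onsets <- as.numeric(events)
  n <- ncol(sig)
  ctr <- .onsetToSample(onsets, fs)
  preS <- as.integer(round(pre * fs)); postS <- as.integer(round(post * fs))
  ok <- ctr - preS >= 1L & ctr + postS <= n
  nDropped <- sum(!ok)
  if (nDropped) message(nDropped, " event(s) fell outside the recording and were dropped")
  ctr <- ctr[ok]
  if (!length(ctr)) stop("no events fall inside the recording")
  rel <- -preS:postS
  cplx <- is.complex(sig)
  data <- array(if (cplx) as.complex(0) else 0,
                c(length(ctr), nrow(sig), length(rel)))
  for (k in seq_along(ctr)) data[k, , ] <- sig[, ctr[k] + rel, drop = FALSE]
  new("EpochSet", data = data, times = rel / fs, fs = fs,
      nDropped = as.integer(nDropped))
}

#' Morlet wavelet time-frequency decomposition of epochs
#'
#' Convolves each epoch with complex Morlet wavelets on a frequency grid
#' (default: 32 log-spaced frequencies from 3 to 80 Hz) whose number of
#' cycles interpolates linearly across the grid (default 2 to 7 cycles).
#' Coefficients are scaled so a unit-amplitude sinusoid at a grid frequency
#' yields |coefficient| of about 1; power is \code{Mod(.)^2}. Normalising
#' the coefficients by their modulus before averaging across trials gives the
#' inter-trial phase clustering input.
#'
#' @param epochs a real \linkS4class{EpochSet}.
#' @param freqs frequency grid in Hz.
#' @param nCycles scalar, per-frequency vector, or length-2 range
#'   interpolated linearly across the grid.
#' @return complex array trials x channels x freqs x samples, with the grid
#'   attached as attributes \code{freqs} and \code{times}.
#' @export
morletTfr <- function(epochs,
                      freqs = exp(seq(log(3), log(80), length.out = 32)),
                      nCycles = c(2, 7)) {
  nf <- length(freqs)
  cyc <- if (length(nCycles) == 1) rep(nCycles, nf)
         else if (length(nCycles) == 2) seq(nCycles[1], nCycles[2],
                                            length.out = nf)
         else nCycles
  if (length(cyc) != nf) stop("'nCycles' must be scalar, length 2, or per-frequency")
  d <- dim(epochs@data)
  fs <- epochs@fs
  wavelets <- lapply(seq_len(nf), function(i)
    .morletWavelet(freqs[i], cyc[i], fs))
  maxLen <- max(vapply(wavelets, length, integer(1)))
  if (d[3] < maxLen)
    stop("epochs (", d[3], " samples) are shorter than the longest wavelet (",
         maxLen, " samples); lengthen the window or raise the lowest frequency")
  out <- array(as.complex(0), c(d[1], d[2], nf, d[3]))
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2])) {
      x <- Re(epochs@data[tr, ch, ])
      for (i in seq_len(nf))
        out[tr, ch, i, ] <- .convSameComplex(x, wavelets[[i]])
    }
  attr(out, "freqs") <- freqs
  attr(out, "times") <- epochs@times
  out
}

#' Cerebro-acoustic coherence
#'
#' Welch-style magnitude-squared coherence between each recording channel and
#' the speech envelope: cross- and auto-spectra are averaged over tapered,
#' overlapping segments and combined as \code{|Sxy|^2 / (Sxx * Syy)}, which
#' lies in [0, 1].
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param envelope numeric series of the same length as the recording.
#' @param segment segment length in seconds (default 4).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return channels x frequencies matrix with the frequency axis (Hz) as
#'   attribute \code{freqs}.
#' @export
envCoherence <- function(rec, envelope, segment = 4, overlap = 0.5) {
  fs <- rec@fs
  n <- ncol(rec@signal)
  if (length(envelope) != n)
    stop("envelope length must match the recording")
  L <- as.integer(round(segment * fs))
  if (L > n) stop("segment longer than the recording")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  if (length(starts) < 2) stop("need at least two segments; shorten 'segment'")
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hann
  nf <- L %/% 2 + 1
  fIdx <- seq_len(nf)
  nc <- nrow(rec@signal)
  Sxx <- matrix(0, nc, nf); Syy <- numeric(nf)
  Sxy <- matrix(as.complex(0), nc, nf)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    Ye <- stats::fft(win * (envelope[idx] - mean(envelope[idx])))[fIdx]
    Syy <- Syy + Mod(Ye)^2
    for (ch in seq_len(nc)) {
      Xe <- stats::fft(win * (rec@signal[ch, idx] -
                              mean(rec@signal[ch, idx])))[fIdx]
      Sxx[ch, ] <- Sxx[ch, ] + Mod(Xe)^2
      Sxy[ch, ] <- Sxy[ch, ] + Xe * Conj(Ye)
    }
  }
  coh <- Mod(Sxy)^2 / (Sxx * matrix(Syy, nc, nf, byrow = TRUE))
  coh[!is.finite(coh)] <- 0
  attr(coh, "freqs") <- (fIdx - 1) * fs / L
  coh
}
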