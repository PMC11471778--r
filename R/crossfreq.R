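#' Trial-based inter-trial phase clustering
#'
#' The modulus of the trial-mean unit phasor at each channel and time point:
#' \code{ITPC(t) = |mean over trials of exp(i phi(t))|}, in [0, 1]; 1 means
#' perfect phase alignment across events, 0 uniform phases.
#'
#' @param epochs a complex \linkS4class{EpochSet} built from a unit-phase
#'   analytic signal (moduli must be 1, or 0 at nulled samples).
#' @return channels x samples numeric matrix with the epoch time axis as
#'   attribute \code{times}.
#' @export
itpcTrial <- function(epochs) {
  d <- dim(epochs@data)
  if (d[1] == 0) stop("no trials")
  m <- Mod(epochs@data)
  if (any(abs(m[m != 0] - 1) > 1e-6))
    stop("itpcTrial expects unit-modulus epochs; apply unitPhase() first")
  out <- Mod(apply(epochs@data, c(2, 3), mean))
  if (is.null(dim(out))) out <- matrix(out, nrow = d[2])
  attr(out, "times") <- epochs@times
  out
}

#' Trial-based phase-amplitude coupling (mean vector length)
#'
#' The event-locked mean vector length of the amplitude-weighted carrier:
#' \code{PAC(t) = |mean over trials of r(t) exp(i phi(t))|}, where r is the
#' high-band amplitude and phi the low-band phase.
#'
#' @param epochs a complex \linkS4class{EpochSet} built from
#'   \code{\link{pacCarrier}} output.
#' @return channels x samples numeric matrix with attribute \code{times}.
#' @export
pacTrial <- function(epochs) {
  d <- dim(epochs@data)
  if (d[1] == 0) stop("no trials")
  out <- Mod(apply(epochs@data, c(2, 3), mean))
  if (is.null(dim(out))) out <- matrix(out, nrow = d[2])
  attr(out, "times") <- epochs@times
  out
}

#' Stimulus-wide phase-amplitude coupling with surrogate z-scoring
#'
#' Scans a grid of phase and amplitude frequencies. For each pair the
#' modulation index is the time-averaged mean vector length
#' \code{|mean over t of r_amp(t) exp(i phi_phase(t))|}, with phase and
#' amplitude extracted by Morlet wavelets (7 cycles). The index is z-scored
#' against surrogates in which the amplitude series is cut at a random point
#' and its two segments swapped (destroying the phase-amplitude alignment
#' while preserving the amplitude autocorrelation). Cut points are drawn
#' from the middle 80% of the series: a cut near either edge yields a
#' surrogate nearly identical to the original and biases the null toward
#' the observed index.
#'
#' @param rec a \linkS4class{ContinuousRecording}, at least 10 cycles of the
#'   slowest phase frequency long.
#' @param phaseFreqs,ampFreqs frequency grids in Hz (defaults 1-8 Hz in 1 Hz
#'   steps and 15-80 Hz in 5 Hz steps).
#' @param nSurrogates number of amplitude-swap surrogates (>= 100).
#' @param nCycles Morlet cycles (default 7).
#' @param seed integer seed for the surrogate cut points.
#' @return A \linkS4class{PACMap}.
#' @export
globalPac <- function(rec, phaseFreqs = 1:8, ampFreqs = seq(15, 80, 5),
                      nSurrogates = 200, nCycles = 7, seed = NULL) {
  if (nSurrogates < 100) stop("'nSurrogates' must be >= 100")
  fs <- rec@fs
  n <- ncol(rec@signal)
  if (n / fs < 10 / min(phaseFreqs))
    stop("recording must span at least 10 cycles of the slowest phase frequency")
  if (max(ampFreqs) >= fs / 2) stop("amplitude grid reaches Nyquist")
  nc <- nrow(rec@signal)
  np <- length(phaseFreqs); na <- length(ampFreqs)
  dims <- c(np, na, nc)
  raw <- array(0, dims); sMean <- array(0, dims); sSd <- array(0, dims)
  lo <- max(2L, ceiling(0.1 * n))
  hi <- min(n - 1L, floor(0.9 * n))
  cuts <- .withSeed(seed,
    sample.int(hi - lo + 1L, nSurrogates, replace = TRUE) + lo - 1L)
  for (ch in seq_len(nc)) {
    x <- rec@signal[ch, ]
    phasors <- matrix(as.complex(0), n, np)
    for (i in seq_len(np)) {
      w <- .convSameComplex(x, .morletWavelet(phaseFreqs[i], nCycles, fs))
      m <- Mod(w); m[m == 0] <- 1
      phasors[, i] <- w / m
    }
    for (j in seq_len(na)) {
      r <- Mod(.convSameComplex(x, .morletWavelet(ampFreqs[j], nCycles, fs)))
      raw[, j, ch] <- Mod(crossprod(phasors, r)) / n
      surr <- matrix(0, np, nSurrogates)
      for (s in seq_len(nSurrogates)) {
        rs <- c(r[(cuts[s] + 1L):n], r[1:cuts[s]])
        surr[, s] <- Mod(crossprod(phasors, rs)) / n
      }
      sMean[, j, ch] <- rowMeans(surr)
      sSd[, j, ch] <- apply(surr, 1, stats::sd)
    }
  }
  new("PACMap", raw = raw, surrMean = sMean, surrSd = sSd,
      z = (raw - sMean) / sSd, phaseFreqs = as.numeric(phaseFreqs),
      ampFreqs = as.numeric(ampFreqs),
      nSurrogates = as.integer(nSurrogates))
}

#' Feature-resolved ITPC via a complex TRF
#'
#' Fits a complex-valued TRF of the continuous unit-phase signal
#' \code{exp(i phi(t))} on the lagged stimulus design. The coefficient
#' magnitude |beta| per feature, lag and channel measures how strongly that
#' feature clusters the phase at that lag. With an onset-only comb design,
#' non-overlapping events and \code{lambda = 0}, |beta| over lags equals the
#' trial-based ITPC exactly; valued feature columns extend the estimate to
#' feature-specific contributions that the trial-based average cannot
#' resolve.
#'
#' @param stim a \linkS4class{StimulusMatrix} of comb features.
#' @param phaseSig a unit-phase \linkS4class{AnalyticBundle}.
#' @param tauMin,tauMax,lagsSamples lag grid, as in
#'   \code{\link{buildLaggedDesign}}.
#' @param lambda ridge mode, as in \code{\link{fitTrf}}.
#' @return A \linkS4class{ComplexTRFResult} of kind \code{"itpc"}.
#' @export
trfItpc <- function(stim, phaseSig, tauMin = -0.2, tauMax = 0.6,
                    lagsSamples = NULL, lambda = 0) {
  if (phaseSig@kind != "unit_phase")
    stop("'phaseSig' must be a unit-phase bundle; apply unitPhase()")
  design <- buildLaggedDesign(stim, tauMin, tauMax, lagsSamples)
  kernel <- fitTrf(design, phaseSig, lambda)
  kernel@channelNames <- paste0("ch", seq_len(nrow(phaseSig@z)))
  new("ComplexTRFResult", kernel = kernel, kind = "itpc")
}

#' Feature-resolved PAC via a complex TRF
#'
#' Fits a complex-valued TRF of the amplitude-weighted carrier
#' \code{r_high(t) exp(i phi_low(t))} on the lagged stimulus design. The
#' coefficient magnitudes |beta| are feature-resolved phase-amplitude
#' coupling estimates: they recover which feature drives the coupling and at
#' what latency, which the event-locked mean vector length cannot
#' disentangle. Summarise over channels with \code{\link{gfp}}.
#'
#' @param stim a \linkS4class{StimulusMatrix}; may combine an onset comb
#'   with valued feature combs.
#' @param carrier an amp-weighted \linkS4class{AnalyticBundle} from
#'   \code{\link{pacCarrier}}.
#' @param tauMin,tauMax,lagsSamples lag grid.
#' @param lambda ridge mode, as in \code{\link{fitTrf}}.
#' @param normalizeAmp divide each channel's carrier by its time-mean
#'   amplitude so |beta| reads as relative modulation (default TRUE).
#' @return A \linkS4class{ComplexTRFResult} of kind \code{"pac"}.
#' @export
trfPac <- function(stim, carrier, tauMin = -0.2, tauMax = 0.6,
                   lagsSamples = NULL, lambda = "eigenMean",
                   normalizeAmp = TRUE) {
  if (carrier@kind != "amp_weighted")
    stop("'carrier' must be an amp_weighted bundle from pacCarrier()")
  z <- carrier@z
  if (normalizeAmp) {
    mu <- rowMeans(Mod(z))
    mu[mu == 0] <- 1
    z <- z / mu
  }
  design <- buildLaggedDesign(stim, tauMin, tauMax, lagsSamples)
  Y <- t(z)
  kernel <- fitTrf(design, Y, lambda)
  kernel@channelNames <- paste0("ch", seq_len(nrow(z)))
  new("ComplexTRFResult", kernel = kernel, kind = "pac")
}
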