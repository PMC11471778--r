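#' Generate a quasi-rhythmic word-onset train
#'
#' Emulates naturalistic word onsets: inter-onset intervals are drawn from a
#' Gaussian centred on \code{1/meanRate} with standard deviation
#' \code{jitterSd}, floored at a 50 ms refractory interval so onsets remain
#' strictly increasing, and the train is truncated to \code{[0, duration)}.
#' With \code{jitterSd = 0} the train is exactly periodic starting at 0.
#'
#' @param duration story duration in seconds (> 0).
#' @param meanRate mean word rate in Hz (> 0).
#' @param jitterSd standard deviation of the inter-onset interval jitter in
#'   seconds (>= 0).
#' @param seed integer seed; identical calls produce identical trains.
#' @param storyId story identifier.
#' @param refractory minimum inter-onset interval in seconds.
#' @return An \linkS4class{OnsetTrain}.
#' @export
genOnsets <- function(duration, meanRate, jitterSd = 0, seed = NULL,
                      storyId = "story1", refractory = 0.05) {
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive, got ", duration)
  if (!is.numeric(meanRate) || meanRate <= 0)
    stop("'meanRate' must be positive, got ", meanRate)
  if (jitterSd < 0) stop("'jitterSd' must be >= 0")
  n <- ceiling(duration * meanRate * 1.5) + 10
  intervals <- .withSeed(seed, {
    if (jitterSd == 0) rep(1 / meanRate, n)
    else pmax(refractory, stats::rnorm(n, 1 / meanRate, jitterSd))
  })
  onsets <- cumsum(c(0, intervals))
  onsets <- onsets[onsets < duration]
  OnsetTrain(onsets, duration, storyId)
}

#' Generate word-level feature value sequences
#'
#' Draws correlated per-word feature columns via a Gaussian construction:
#' standard-normal columns are mixed through the matrix square root of the
#' requested correlation matrix, then scaled to the requested marginal mean
#' and standard deviation. Columns of type \code{"integer"} (depth/close
#' stand-ins) are rounded and floored at \code{mins}; the requested
#' correlation then holds only approximately for those columns.
#'
#' @param nWords number of words (>= 1).
#' @param means,sds marginal moments, one per feature.
#' @param corr correlation matrix (positive semi-definite), a single
#'   off-diagonal value for all pairs, or NULL for independence.
#' @param types per-feature type, "real" or "integer".
#' @param mins per-feature lower bound applied to integer columns (e.g. 1 for
#'   depth, 0 for close).
#' @param names feature names.
#' @param seed integer seed.
#' @return data.frame of \code{nWords} rows, one column per feature.
#' @export
genFeatureValues <- function(nWords, means, sds, corr = NULL,
                             types = NULL, mins = NULL, names = NULL,
                             seed = NULL) {
  if (nWords < 1) stop("'nWords' must be >= 1")
  p <- length(means)
  if (length(sds) != p) stop("'means' and 'sds' must have equal length")
  if (is.null(types)) types <- rep("real", p)
  if (is.null(mins)) mins <- rep(-Inf, p)
  if (is.null(names)) names <- paste0("feat", seq_len(p))
  if (is.null(corr)) corr <- diag(p)
  if (length(corr) == 1 && p > 1) {
    r <- corr; corr <- matrix(r, p, p); diag(corr) <- 1
  }
  corr <- as.matrix(corr)
  ev <- eigen(corr, symmetric = TRUE)
  if (any(ev$values < -1e-8))
    stop("correlation matrix is not positive semi-definite")
  rootC <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Z <- .withSeed(seed, matrix(stats::rnorm(nWords * p), nWords, p))
  X <- Z %*% rootC
  out <- lapply(seq_len(p), function(j) {
    v <- means[j] + sds[j] * X[, j]
    if (types[j] == "integer") v <- pmax(mins[j], round(v))
    v
  })
  stats::setNames(as.data.frame(out), names)
}

#' Simulate a phase-amplitude-coupled recording
#'
#' Builds a signal containing a slow oscillation at \code{fPhase} plus a fast
#' oscillation at \code{fAmp} whose instantaneous amplitude is modulated by
#' the slow phase, plus Gaussian noise. Three coupling mechanisms are
#' available:
#' \describe{
#'   \item{global}{the fast amplitude follows
#'     \code{1 + coupling * (1 + cos(phi_slow))/2} everywhere (peak at slow
#'     phase 0), with no reference to events;}
#'   \item{onset_locked}{phase modulation of the fast amplitude occurs only
#'     inside Gaussian windows (FWHM \code{burstWidth}) centred
#'     \code{latency} seconds after each event;}
#'   \item{feature_scaled}{as onset_locked, with each event's burst gain
#'     multiplied by that word's feature value.}
#' }
#'
#' @param scenario "global", "onset_locked" or "feature_scaled".
#' @param fs sampling rate in Hz (> 2 * fAmp).
#' @param duration recording duration in seconds.
#' @param fPhase,fAmp slow (phase) and fast (amplitude) frequencies in Hz.
#' @param coupling dimensionless coupling strength (>= 0); 0 removes all
#'   phase dependence of the fast amplitude.
#' @param events \linkS4class{OnsetTrain}; required for the event-locked
#'   scenarios.
#' @param featureValues per-word gains for "feature_scaled"; same length as
#'   the events.
#' @param latency burst delay after onset in seconds.
#' @param burstWidth full width at half maximum of the burst window (s).
#' @param phaseDrift Brownian drift of the slow oscillator's phase, in
#'   radians per square-root second. Neural rhythms are quasi-periodic, not
#'   stationary sinusoids; the drift decorrelates the slow phase over tens
#'   of seconds, which also keeps segment-swap surrogate schemes meaningful
#'   (a strictly periodic signal is invariant to circular amplitude shifts).
#'   Set 0 for an exactly periodic oscillator.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param nChannels number of channels (independent noise per channel).
#' @param seed integer seed.
#' @return A \linkS4class{ContinuousRecording} whose provenance records the
#'   generator parameters.
#' @export
genPacRecording <- function(scenario = c("global", "onset_locked",
                                         "feature_scaled"),
                            fs = 200, duration = 60, fPhase = 2, fAmp = 40,
                            coupling = 1, events = NULL,
                            featureValues = NULL, latency = 0.15,
                            burstWidth = 0.15, phaseDrift = 0.5,
                            noiseSd = 0.1, nChannels = 1, seed = NULL) {
  scenario <- match.arg(scenario)
  if (fs <= 2 * fAmp) stop("fs must exceed 2 * fAmp")
  if (fPhase <= 0 || fAmp <= fPhase) stop("need 0 < fPhase < fAmp")
  if (coupling < 0) stop("'coupling' must be >= 0")
  if (scenario != "global") {
    if (is.null(events) || length(events@onsets) == 0)
      stop("event-locked scenarios require a non-empty onset train")
  }
  if (scenario == "feature_scaled") {
    if (is.null(featureValues) ||
        length(featureValues) != length(events@onsets))
      stop("'featureValues' must match the number of events (",
           length(events@onsets), ")")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  draws <- .withSeed(seed, list(
    drift = if (phaseDrift > 0)
      cumsum(stats::rnorm(n, 0, phaseDrift / sqrt(fs))) else numeric(n),
    noise = matrix(stats::rnorm(nChannels * n, 0, noiseSd),
                   nrow = nChannels)))
  phi <- 2 * pi * fPhase * t + draws$drift
  phaseMod <- (1 + cos(phi)) / 2

  if (scenario == "global") {
    r <- 1 + coupling * phaseMod
  } else {
    sigma <- burstWidth / (2 * sqrt(2 * log(2)))
    gains <- if (scenario == "feature_scaled") featureValues
             else rep(1, length(events@onsets))
    burst <- numeric(n)
    for (k in seq_along(events@onsets)) {
      c0 <- events@onsets[k] + latency
      lo <- max(1L, floor((c0 - 4 * sigma) * fs) + 1L)
      hi <- min(n, ceiling((c0 + 4 * sigma) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      burst[idx] <- burst[idx] +
        gains[k] * exp(-((t[idx] - c0)^2) / (2 * sigma^2))
    }
    r <- 1 + coupling * burst * phaseMod
  }

  clean <- cos(phi) + r * cos(2 * pi * fAmp * t)
  sig <- matrix(rep(clean, each = nChannels), nrow = nChannels) +
    draws$noise
  ContinuousRecording(sig, fs,
    provenance = list(generator = "genPacRecording", scenario = scenario,
                      fPhase = fPhase, fAmp = fAmp, coupling = coupling,
                      latency = latency, burstWidth = burstWidth,
                      phaseDrift = phaseDrift, noiseSd = noiseSd,
                      seed = seed))
}

#' Simulate a recording as stimulus convolved with a known kernel
#'
#' The response at each channel is the discrete convolution of the stimulus
#' columns with the kernel's per-feature, per-lag coefficients (the forward
#' model the TRF estimator inverts), plus i.i.d. Gaussian noise. With
#' \code{noiseSd = 0} the output is exactly reproducible.
#'
#' @param kernel a real \linkS4class{TRFKernel} holding the ground-truth
#'   coefficients.
#' @param stim a \linkS4class{StimulusMatrix} sampled at the kernel's rate.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return A \linkS4class{ContinuousRecording} (channels x samples).
#' @export
genTrfRecording <- function(kernel, stim, noiseSd = 0, seed = NULL) {
  if (!isTRUE(all.equal(kernel@fs, stim@fs)))
    stop("sampling-rate mismatch: kernel at ", kernel@fs, " Hz, stimulus at ",
         stim@fs, " Hz")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (dim(kernel@beta)[1] != ncol(stim@values))
    stop("kernel feature count does not match stimulus")
  design <- buildLaggedDesign(stim,
    lagsSamples = as.integer(round(kernel@lagsSeconds * kernel@fs)))
  clean <- predictTrf(design, kernel)
  n <- nrow(clean); nc <- ncol(clean)
  noise <- if (noiseSd > 0)
    .withSeed(seed, matrix(stats::rnorm(n * nc, 0, noiseSd), n, nc))
  else matrix(0, n, nc)
  ContinuousRecording(t(clean + noise), stim@fs,
    channelNames = kernel@channelNames, stories = stim@stories,
    provenance = list(generator = "genTrfRecording", noiseSd = noiseSd,
                      seed = seed, lambda = kernel@lambda))
}
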