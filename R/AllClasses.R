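#' @import methods
NULL

.checkStories <- function(stories, nSamples) {
  msgs <- character(0)
  req <- c("story_id", "start", "end")
  if (!is.data.frame(stories) || !all(req %in% names(stories)))
    return("'stories' must be a data.frame with columns story_id, start, end")
  if (anyDuplicated(stories$story_id))
    msgs <- c(msgs, "duplicated story ids")
  if (nrow(stories)) {
    o <- order(stories$start)
    s <- stories[o, , drop = FALSE]
    if (s$start[1] != 1L || s$end[nrow(s)] != nSamples ||
        any(s$start > s$end) ||
        (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)] + 1L)))
      msgs <- c(msgs, "story segments must tile 1..nSamples contiguously")
  }
  msgs
}

.singleStory <- function(nSamples, storyId = "story1") {
  data.frame(story_id = storyId, start = 1L, end = as.integer(nSamples),
             stringsAsFactors = FALSE)
}

#' Continuous multichannel recording
#'
#' Container for a channels-by-samples real signal with its sampling rate and
#' story segmentation. Stories are contiguous, non-overlapping segments of the
#' sample axis; all convolutional operations in the package respect story
#' boundaries (no wraparound across stories).
#'
#' @slot signal numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one per channel.
#' @slot stories data.frame with columns \code{story_id}, \code{start},
#'   \code{end} (1-based sample indices, inclusive).
#' @slot provenance free-form list describing how the recording was produced
#'   (generator parameters or source file).
#' @export
setClass("ContinuousRecording",
  representation(signal = "matrix", fs = "numeric",
                 channelNames = "character", stories = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    msgs <- character(0)
    if (!is.numeric(object@signal)) msgs <- c(msgs, "signal must be numeric")
    if (length(object@fs) != 1 || object@fs <= 0)
      msgs <- c(msgs, "fs must be a single positive number")
    if (length(object@channelNames) != nrow(object@signal))
      msgs <- c(msgs, "channelNames length must equal channel count")
    if (anyDuplicated(object@channelNames))
      msgs <- c(msgs, "channel names must be unique")
    msgs <- c(msgs, .checkStories(object@stories, ncol(object@signal)))
    if (length(msgs)) msgs else TRUE
  })

#' Construct a ContinuousRecording
#'
#' @param signal channels x samples numeric matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate (Hz).
#' @param channelNames optional channel labels; defaults to \code{ch1, ch2, ...}.
#' @param stories optional story segmentation data.frame (\code{story_id},
#'   \code{start}, \code{end}); defaults to a single story spanning the
#'   recording.
#' @param provenance optional list recording generator parameters or source.
#' @return A \linkS4class{ContinuousRecording}.
#' @export
ContinuousRecording <- function(signal, fs, channelNames = NULL,
                                stories = NULL, provenance = list()) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(signal)))
  if (is.null(stories)) stories <- .singleStory(ncol(signal))
  stories$start <- as.integer(stories$start)
  stories$end <- as.integer(stories$end)
  new("ContinuousRecording", signal = signal, fs = fs,
      channelNames = channelNames, stories = stories, provenance = provenance)
}

#' Word-onset train for one story
#'
#' @slot storyId story identifier.
#' @slot onsets onset times in seconds, strictly increasing, within
#'   \code{[0, duration)}.
#' @slot duration story duration in seconds.
#' @export
setClass("OnsetTrain",
  representation(storyId = "character", onsets = "numeric",
                 duration = "numeric"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@duration) != 1 || object@duration <= 0)
      msgs <- c(msgs, "duration must be a single positive number")
    if (length(object@onsets)) {
      if (any(object@onsets < 0) || any(object@onsets >= object@duration))
        msgs <- c(msgs, "onsets must lie in [0, duration)")
      if (any(diff(object@onsets) <= 0))
        msgs <- c(msgs, "onsets must be strictly increasing")
    }
    if (length(msgs)) msgs else TRUE
  })

#' @rdname OnsetTrain-class
#' @param onsets,duration,storyId see slots.
#' @return An \linkS4class{OnsetTrain}.
#' @export
OnsetTrain <- function(onsets, duration, storyId = "story1")
  new("OnsetTrain", storyId = storyId, onsets = as.numeric(onsets),
      duration = duration)

#' Frequency band specification
#'
#' @slot name band label (e.g. "delta").
#' @slot fLo,fHi band edges in Hz, \code{0 < fLo < fHi}.
#' @export
setClass("BandSpec",
  representation(name = "character", fLo = "numeric", fHi = "numeric"),
  validity = function(object) {
    if (object@fLo <= 0 || object@fHi <= object@fLo)
      "band edges must satisfy 0 < fLo < fHi" else TRUE
  })

#' @rdname BandSpec-class
#' @param name,fLo,fHi see slots.
#' @export
bandSpec <- function(name, fLo, fHi)
  new("BandSpec", name = name, fLo = fLo, fHi = fHi)

#' Canonical frequency bands
#'
#' The four bands used throughout the analyses: delta (0.5-4 Hz), theta
#' (4-8 Hz), beta (15-25 Hz) and gamma (30-80 Hz).
#'
#' @return Named list of \linkS4class{BandSpec} objects.
#' @export
defaultBands <- function()
  list(delta = bandSpec("delta", 0.5, 4), theta = bandSpec("theta", 4, 8),
       beta = bandSpec("beta", 15, 25), gamma = bandSpec("gamma", 30, 80))

#' Stimulus representation matrix
#'
#' Samples-by-features matrix holding the word-level stimulus representation:
#' comb columns (zero except at word-onset samples, where they carry the word's
#' feature value, or ones for the onset regressor) and dense columns such as
#' the acoustic envelope.
#'
#' @slot values samples x features numeric matrix with feature names as
#'   column names.
#' @slot fs sampling rate in Hz.
#' @slot stories story segmentation (as in
#'   \linkS4class{ContinuousRecording}).
#' @export
setClass("StimulusMatrix",
  representation(values = "matrix", fs = "numeric", stories = "data.frame"),
  validity = function(object) {
    msgs <- character(0)
    if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
    if (ncol(object@values) > 0 && is.null(colnames(object@values)))
      msgs <- c(msgs, "feature columns must be named")
    if (length(object@fs) != 1 || object@fs <= 0)
      msgs <- c(msgs, "fs must be a single positive number")
    msgs <- c(msgs, .checkStories(object@stories, nrow(object@values)))
    if (length(msgs)) msgs else TRUE
  })

#' Lagged design matrix
#'
#' Design matrix X whose columns are lagged copies of the stimulus columns:
#' the column for feature j at lag tau holds x_j(t - tau), zero-padded at
#' story edges (no wraparound). Columns are grouped by feature, lags varying
#' fastest.
#'
#' @slot X samples x (features * lags) numeric matrix.
#' @slot lagsSamples integer lags in samples (positive = stimulus precedes
#'   response).
#' @slot fs sampling rate in Hz.
#' @slot featureNames source feature names.
#' @slot stories story segmentation.
#' @export
setClass("LaggedDesign",
  representation(X = "matrix", lagsSamples = "integer", fs = "numeric",
                 featureNames = "character", stories = "data.frame"),
  validity = function(object) {
    msgs <- character(0)
    if (ncol(object@X) !=
        length(object@featureNames) * length(object@lagsSamples))
      msgs <- c(msgs, "column count must equal n_features * n_lags")
    msgs <- c(msgs, .checkStories(object@stories, nrow(object@X)))
    if (length(msgs)) msgs else TRUE
  })

#' Temporal response function kernel
#'
#' Per-feature, per-lag, per-channel regression coefficients. Coefficients are
#' real for ordinary encoding models and complex when the response is an
#' analytic signal (the ITPC/PAC extension).
#'
#' @slot beta features x lags x channels array (numeric or complex).
#' @slot lagsSeconds lag axis in seconds.
#' @slot fs sampling rate in Hz.
#' @slot lambda ridge penalty actually used in the fit.
#' @slot lambdaMode how lambda was chosen ("zero", "eigenMean" or "fixed").
#' @slot featureNames,channelNames axis labels.
#' @export
setClass("TRFKernel",
  representation(beta = "array", lagsSeconds = "numeric", fs = "numeric",
                 lambda = "numeric", lambdaMode = "character",
                 featureNames = "character", channelNames = "character"),
  validity = function(object) {
    msgs <- character(0)
    d <- dim(object@beta)
    if (length(d) != 3) msgs <- c(msgs, "beta must be a 3-d array")
    else {
      if (d[1] != length(object@featureNames))
        msgs <- c(msgs, "beta dim 1 must match featureNames")
      if (d[2] != length(object@lagsSeconds))
        msgs <- c(msgs, "beta dim 2 must match lag axis")
      if (d[3] != length(object@channelNames))
        msgs <- c(msgs, "beta dim 3 must match channelNames")
    }
    if (any(!is.finite(Mod(object@beta))))
      msgs <- c(msgs, "beta must be finite")
    if (length(msgs)) msgs else TRUE
  })

#' @rdname TRFKernel-class
#' @param beta,lagsSeconds,fs,lambda,lambdaMode,featureNames,channelNames see
#'   slots; defaults label axes generically.
#' @export
TRFKernel <- function(beta, lagsSeconds, fs, lambda = 0,
                      lambdaMode = "fixed", featureNames = NULL,
                      channelNames = NULL) {
  d <- dim(beta)
  if (is.null(featureNames)) featureNames <- paste0("feat", seq_len(d[1]))
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(d[3]))
  new("TRFKernel", beta = beta, lagsSeconds = as.numeric(lagsSeconds),
      fs = fs, lambda = lambda, lambdaMode = lambdaMode,
      featureNames = featureNames, channelNames = channelNames)
}

#' Analytic-signal bundle
#'
#' Complex per-channel series: either a unit-modulus phase signal
#' exp(i*phi_low(t)) or an amplitude-weighted carrier
#' r_high(t) * exp(i*phi_low(t)) combining the amplitude of a high-frequency
#' band with the phase of a low-frequency band.
#'
#' @slot z channels x samples complex matrix.
#' @slot kind "amp_weighted" or "unit_phase".
#' @slot fs sampling rate in Hz.
#' @slot phaseBand band providing the phase.
#' @slot ampBand band providing the amplitude.
#' @slot stories story segmentation.
#' @slot nZeroAmp number of zero-amplitude samples nulled by
#'   \code{unitPhase()}.
#' @export
setClass("AnalyticBundle",
  representation(z = "matrix", kind = "character", fs = "numeric",
                 phaseBand = "BandSpec", ampBand = "BandSpec",
                 stories = "data.frame", nZeroAmp = "integer"),
  validity = function(object) {
    msgs <- character(0)
    if (!is.complex(object@z)) msgs <- c(msgs, "z must be complex")
    if (!object@kind %in% c("amp_weighted", "unit_phase"))
      msgs <- c(msgs, "kind must be amp_weighted or unit_phase")
    if (object@kind == "unit_phase") {
      m <- Mod(object@z)
      if (any(abs(m[m != 0] - 1) > 1e-9))
        msgs <- c(msgs, "unit_phase bundle must have |z| = 1 (or 0 at nulled samples)")
    }
    msgs <- c(msgs, .checkStories(object@stories, ncol(object@z)))
    if (length(msgs)) msgs else TRUE
  })

#' Epoched data
#'
#' Equal-length windows around word onsets, with no baseline applied. The data
#' may be real (raw signal) or complex (analytic signal).
#'
#' @slot data trials x channels x samples array.
#' @slot times time axis in seconds relative to onset (includes 0).
#' @slot fs sampling rate in Hz.
#' @slot nDropped number of events dropped for falling outside the recording.
#' @export
setClass("EpochSet",
  representation(data = "array", times = "numeric", fs = "numeric",
                 nDropped = "integer"),
  validity = function(object) {
    msgs <- character(0)
    d <- dim(object@data)
    if (length(d) != 3) msgs <- c(msgs, "data must be trials x channels x samples")
    else if (d[3] != length(object@times))
      msgs <- c(msgs, "time axis must match sample dimension")
    if (length(object@times) && !any(abs(object@times) < 0.5 / object@fs))
      msgs <- c(msgs, "time axis must include 0")
    if (length(msgs)) msgs else TRUE
  })

#' Cross-validated model scores
#'
#' Per-fold (held-out story), per-channel Pearson correlations between
#' predicted and observed responses.
#'
#' @slot model model name.
#' @slot band frequency-band label.
#' @slot table data.frame with columns \code{fold} (story id), \code{channel},
#'   \code{r}.
#' @export
setClass("ScoreTable",
  representation(model = "character", band = "character",
                 table = "data.frame"),
  validity = function(object) {
    msgs <- character(0)
    if (!all(c("fold", "channel", "r") %in% names(object@table)))
      msgs <- c(msgs, "table needs columns fold, channel, r")
    else if (any(abs(object@table$r) > 1 + 1e-12, na.rm = TRUE))
      msgs <- c(msgs, "Pearson r must lie in [-1, 1]")
    if (length(msgs)) msgs else TRUE
  })

#' Stimulus-wide phase-amplitude coupling map
#'
#' Raw modulation index (time-averaged mean vector length), surrogate moments
#' and the z-scored map over a grid of phase and amplitude frequencies.
#'
#' @slot raw,surrMean,surrSd,z arrays of dimension phase-freqs x amp-freqs x
#'   channels.
#' @slot phaseFreqs,ampFreqs frequency grids in Hz.
#' @slot nSurrogates number of amplitude-segment-swap surrogates.
#' @export
setClass("PACMap",
  representation(raw = "array", surrMean = "array", surrSd = "array",
                 z = "array", phaseFreqs = "numeric", ampFreqs = "numeric",
                 nSurrogates = "integer"),
  validity = function(object) {
    msgs <- character(0)
    d <- dim(object@raw)
    if (d[1] != length(object@phaseFreqs) || d[2] != length(object@ampFreqs))
      msgs <- c(msgs, "map dimensions must match frequency grids")
    if (any(object@surrSd <= 0))
      msgs <- c(msgs, "surrogate sd must be positive")
    if (max(abs(object@z - (object@raw - object@surrMean) / object@surrSd)) >
        1e-8)
      msgs <- c(msgs, "z must equal (raw - surrMean)/surrSd")
    if (length(msgs)) msgs else TRUE
  })

#' Complex TRF result (feature-resolved ITPC / PAC)
#'
#' A complex-valued TRF kernel whose coefficient magnitudes |beta| are the
#' feature-resolved phase-clustering (ITPC) or phase-amplitude-coupling
#' estimates, per feature, lag and channel.
#'
#' @slot kernel the underlying complex \linkS4class{TRFKernel}.
#' @slot kind "itpc" (unit-phase response) or "pac" (amplitude-weighted
#'   carrier response).
#' @export
setClass("ComplexTRFResult",
  representation(kernel = "TRFKernel", kind = "character"),
  validity = function(object) {
    if (!object@kind %in% c("itpc", "pac"))
      "kind must be itpc or pac" else TRUE
  })

#' Cluster-based permutation test result
#'
#' @slot clusters list of integer vectors of contiguous sample indices.
#' @slot masses summed t statistic per cluster (signed).
#' @slot pValues permutation p-value per cluster.
#' @slot tObserved observed t statistic per sample.
#' @slot threshold cluster-forming threshold on |t|.
#' @slot nPerm number of permutations.
#' @export
setClass("ClusterSet",
  representation(clusters = "list", masses = "numeric", pValues = "numeric",
                 tObserved = "numeric", threshold = "numeric",
                 nPerm = "integer"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@clusters) != length(object@masses) ||
        length(object@clusters) != length(object@pValues))
      msgs <- c(msgs, "clusters, masses and pValues must align")
    if (length(object@pValues) &&
        any(object@pValues < 1 / (object@nPerm + 1) - 1e-12))
      msgs <- c(msgs, "p-values cannot undercut 1/(nPerm+1)")
    if (length(object@clusters) > 1) {
      all_idx <- unlist(object@clusters)
      if (anyDuplicated(all_idx)) msgs <- c(msgs, "clusters must be disjoint")
    }
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channel(s) x %d samples @ %g Hz (%.1f s), %d story(ies)\n",
              nrow(object@signal), ncol(object@signal), object@fs,
              ncol(object@signal) / object@fs, nrow(object@stories)))
})

setMethod("show", "StimulusMatrix", function(object) {
  cat(sprintf("StimulusMatrix: %d samples x %d feature(s) @ %g Hz [%s]\n",
              nrow(object@values), ncol(object@values), object@fs,
              paste(colnames(object@values), collapse = ", ")))
})

setMethod("show", "TRFKernel", function(object) {
  cat(sprintf("TRFKernel (%s): %d feature(s) x %d lag(s) x %d channel(s), lags %.3f..%.3f s, lambda = %.4g (%s)\n",
              if (is.complex(object@beta)) "complex" else "real",
              dim(object@beta)[1], dim(object@beta)[2], dim(object@beta)[3],
              min(object@lagsSeconds), max(object@lagsSeconds),
              object@lambda, object@lambdaMode))
})

setMethod("show", "AnalyticBundle", function(object) {
  cat(sprintf("AnalyticBundle (%s): %d channel(s) x %d samples @ %g Hz, phase %s [%g-%g Hz], amp %s [%g-%g Hz]\n",
              object@kind, nrow(object@z), ncol(object@z), object@fs,
              object@phaseBand@name, object@phaseBand@fLo, object@phaseBand@fHi,
              object@ampBand@name, object@ampBand@fLo, object@ampBand@fHi))
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable '%s' (band %s): %d fold(s) x %d channel(s), mean r = %.4f\n",
              object@model, object@band, length(unique(object@table$fold)),
              length(unique(object@table$channel)), mean(object@table$r)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d cluster(s), threshold |t| > %.3f, %d permutations\n",
              length(object@clusters), object@threshold, object@nPerm))
  if (length(object@clusters))
    for (k in seq_along(object@clusters))
      cat(sprintf("  cluster %d: samples %d-%d, mass %.2f, p = %.4g\n", k,
                  min(object@clusters[[k]]), max(object@clusters[[k]]),
                  object@masses[k], object@pValues[k]))
})

setMethod("show", "PACMap", function(object) {
  cat(sprintf("PACMap: %d phase x %d amp frequency bins x %d channel(s), %d surrogates, max z = %.2f\n",
              length(object@phaseFreqs), length(object@ampFreqs),
              dim(object@raw)[3], object@nSurrogates, max(object@z)))
})

setMethod("show", "ComplexTRFResult", function(object) {
  cat(sprintf("ComplexTRFResult (%s):\n  ", object@kind))
  show(object@kernel)
})
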