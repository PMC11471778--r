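#' Sampling rate accessor
#' @param x an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ContinuousRecording", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "StimulusMatrix", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "AnalyticBundle", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TRFKernel", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' Number of samples
#' @param x an object with a sample axis.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "ContinuousRecording", function(x) ncol(x@signal))
#' @rdname nSamples
#' @export
setMethod("nSamples", "StimulusMatrix", function(x) nrow(x@values))
#' @rdname nSamples
#' @export
setMethod("nSamples", "AnalyticBundle", function(x) ncol(x@z))

#' Number of channels
#' @param x an object with channels.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "ContinuousRecording", function(x) nrow(x@signal))
#' @rdname nChannels
#' @export
setMethod("nChannels", "AnalyticBundle", function(x) nrow(x@z))

#' Channel labels
#' @param x an object with channels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "ContinuousRecording", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "TRFKernel", function(x) x@channelNames)

#' Feature labels
#' @param x an object with a feature axis.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname featureNames
#' @export
setMethod("featureNames", "StimulusMatrix", function(x) colnames(x@values))
#' @rdname featureNames
#' @export
setMethod("featureNames", "LaggedDesign", function(x) x@featureNames)
#' @rdname featureNames
#' @export
setMethod("featureNames", "TRFKernel", function(x) x@featureNames)
#' @rdname featureNames
#' @export
setMethod("featureNames", "ComplexTRFResult", function(x)
  x@kernel@featureNames)

#' Story segmentation accessor
#' @param x an object segmented into stories.
#' @return data.frame with columns story_id, start, end.
#' @export
setGeneric("stories", function(x) standardGeneric("stories"))

#' @rdname stories
#' @export
setMethod("stories", "ContinuousRecording", function(x) x@stories)
#' @rdname stories
#' @export
setMethod("stories", "StimulusMatrix", function(x) x@stories)
#' @rdname stories
#' @export
setMethod("stories", "AnalyticBundle", function(x) x@stories)

#' Raw signal matrix accessor
#' @param x a \linkS4class{ContinuousRecording} or
#'   \linkS4class{AnalyticBundle}.
#' @return channels x samples matrix (complex for analytic bundles).
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname signalData
#' @export
setMethod("signalData", "ContinuousRecording", function(x) x@signal)
#' @rdname signalData
#' @export
setMethod("signalData", "AnalyticBundle", function(x) x@z)

#' Kernel coefficient accessor
#' @param x a \linkS4class{TRFKernel} or \linkS4class{ComplexTRFResult}.
#' @return features x lags x channels array.
#' @export
setGeneric("coefArray", function(x) standardGeneric("coefArray"))

#' @rdname coefArray
#' @export
setMethod("coefArray", "TRFKernel", function(x) x@beta)
#' @rdname coefArray
#' @export
setMethod("coefArray", "ComplexTRFResult", function(x) x@kernel@beta)

#' Lag axis in seconds
#' @param x an object with a lag axis.
#' @export
setGeneric("lagAxis", function(x) standardGeneric("lagAxis"))

#' @rdname lagAxis
#' @export
setMethod("lagAxis", "TRFKernel", function(x) x@lagsSeconds)
#' @rdname lagAxis
#' @export
setMethod("lagAxis", "LaggedDesign", function(x) x@lagsSamples / x@fs)
#' @rdname lagAxis
#' @export
setMethod("lagAxis", "ComplexTRFResult", function(x) x@kernel@lagsSeconds)

#' Score table accessor
#' @param x a \linkS4class{ScoreTable}.
#' @return long data.frame of per-fold, per-channel Pearson r.
#' @export
setGeneric("scoreFrame", function(x) standardGeneric("scoreFrame"))

#' @rdname scoreFrame
#' @export
setMethod("scoreFrame", "ScoreTable", function(x) x@table)

#' Mean cross-validated score
#' @param x a \linkS4class{ScoreTable}.
#' @return mean Pearson r over folds and channels.
#' @export
setGeneric("meanScore", function(x) standardGeneric("meanScore"))

#' @rdname meanScore
#' @export
setMethod("meanScore", "ScoreTable", function(x) mean(x@table$r))

#' Global field power of a complex TRF
#'
#' Mean over channels of the squared coefficient magnitude, per feature and
#' lag: the channel-summary curve used to read feature-resolved ITPC/PAC time
#' courses.
#'
#' @param x a \linkS4class{ComplexTRFResult} (or \linkS4class{TRFKernel}).
#' @return features x lags numeric matrix.
#' @export
setGeneric("gfp", function(x) standardGeneric("gfp"))

#' @rdname gfp
#' @export
setMethod("gfp", "TRFKernel", function(x) {
  m <- Mod(x@beta)^2
  out <- apply(m, c(1, 2), mean)
  dimnames(out) <- list(x@featureNames, NULL)
  out
})

#' @rdname gfp
#' @export
setMethod("gfp", "ComplexTRFResult", function(x) gfp(x@kernel))
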