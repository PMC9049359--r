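#' @name accessors
#' @title Accessors for ssvepDS containers
#' @description Slot accessors for the package's S4 containers. Use these in
#'   preference to direct slot access.
#' @param object a package object.
#' @param i indices of trials to keep.
#' @param x,j,...,drop subsetting arguments.
NULL

#' @describeIn accessors channels x samples data matrix of a Recording.
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @export
setMethod("eegData", "Recording", function(object) object@data)

#' @describeIn accessors sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @export
setMethod("sampleRate", "Recording", function(object) object@fs)
#' @export
setMethod("sampleRate", "TrialSet", function(object) object@fs)

#' @describeIn accessors channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @export
setMethod("channelNames", "Recording", function(object) object@channels)
#' @export
setMethod("channelNames", "TrialSet", function(object) object@channels)

#' @describeIn accessors number of channels.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @export
setMethod("nChannels", "Recording", function(object) nrow(object@data))
#' @export
setMethod("nChannels", "TrialSet", function(object)
  if (length(object@trials)) nrow(object@trials[[1]]) else 0L)

#' @describeIn accessors number of samples.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @export
setMethod("nSamples", "Recording", function(object) ncol(object@data))
#' @export
setMethod("nSamples", "TrialSet", function(object)
  if (length(object@trials)) ncol(object@trials[[1]]) else 0L)

#' @describeIn accessors list of trial matrices.
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))
#' @export
setMethod("trials", "TrialSet", function(object) object@trials)

#' @describeIn accessors integer class labels.
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))
#' @export
setMethod("trialLabels", "TrialSet", function(object) object@labels)

#' @describeIn accessors number of classes C.
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))
#' @export
setMethod("nClasses", "TrialSet", function(object) object@nClasses)
#' @export
setMethod("nClasses", "Topographies", function(object) ncol(object@weights))
#' @export
setMethod("nClasses", "CCAFilterBank", function(object) length(object@A))
#' @export
setMethod("nClasses", "LDAModel", function(object) nrow(object@means))

#' @describeIn accessors number of trials in a TrialSet.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @export
setMethod("nTrials", "TrialSet", function(object) length(object@trials))

#' @describeIn accessors topography weight matrix (L x C, unit columns).
#' @export
setGeneric("topographyWeights",
           function(object) standardGeneric("topographyWeights"))
#' @export
setMethod("topographyWeights", "Topographies", function(object) object@weights)

#' @describeIn accessors trained window length of a filter bank (samples).
#' @export
setGeneric("trainedWindow", function(object) standardGeneric("trainedWindow"))
#' @export
setMethod("trainedWindow", "CCAFilterBank", function(object) object@windowLen)

#' @describeIn accessors canonical correlations per class.
#' @export
setGeneric("canonicalCors", function(object) standardGeneric("canonicalCors"))
#' @export
setMethod("canonicalCors", "CCAFilterBank", function(object) object@cors)

#' @describeIn accessors class centroid matrix of an LDA model.
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))
#' @export
setMethod("classMeans", "LDAModel", function(object) object@means)

#' @describeIn accessors pooled within-class covariance of an LDA model.
#' @export
setGeneric("pooledCovariance",
           function(object) standardGeneric("pooledCovariance"))
#' @export
setMethod("pooledCovariance", "LDAModel", function(object) object@covariance)

#' @describeIn accessors class priors of an LDA model.
#' @export
setGeneric("classPriors", function(object) standardGeneric("classPriors"))
#' @export
setMethod("classPriors", "LDAModel", function(object) object@priors)

#' @describeIn accessors cached window lengths of a ModelCache (samples).
#' @export
setGeneric("cachedWindows", function(object) standardGeneric("cachedWindows"))
#' @export
setMethod("cachedWindows", "ModelCache", function(object) object@windows)

#' @describeIn accessors predicted class of a Decision.
#' @export
setGeneric("decisionLabel", function(object) standardGeneric("decisionLabel"))
#' @export
setMethod("decisionLabel", "Decision", function(object) object@label)

#' @describeIn accessors stopping time of a Decision, seconds.
#' @export
setGeneric("stopTime", function(object) standardGeneric("stopTime"))
#' @export
setMethod("stopTime", "Decision", function(object) object@stopTime)

#' @describeIn accessors per-chunk trace of a Decision.
#' @export
setGeneric("decisionTrace", function(object) standardGeneric("decisionTrace"))
#' @export
setMethod("decisionTrace", "Decision", function(object) object@trace)

#' @describeIn accessors estimated narrow-band SNR (linear ratio).
#' @export
setGeneric("snrValue", function(object) standardGeneric("snrValue"))
#' @export
setMethod("snrValue", "SNREstimate", function(object) object@snr)

#' @rdname accessors
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  new("TrialSet", trials = x@trials[i], labels = x@labels[i], fs = x@fs,
      nClasses = x@nClasses, channels = x@channels)
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trials (%d classes), %d channels x %d samples @ %g Hz\n",
              nTrials(object), object@nClasses, nChannels(object),
              nSamples(object), object@fs))
  if (nTrials(object))
    print(table(class = object@labels))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: L=%d C=%d fStim=%g Hz fs=%g Hz snr=%g alpha=%g\n",
    object@nChannels, object@nClasses, object@fStim, object@fSample,
    object@snr, object@noiseExponent))
})

setMethod("show", "Topographies", function(object) {
  w <- object@weights
  cat(sprintf("Topographies: %d channels x %d classes", nrow(w), ncol(w)))
  if (ncol(w) >= 2) {
    cc <- abs(crossprod(w)); diag(cc) <- NA
    cat(sprintf(" (max |cos| = %.3f)", max(cc, na.rm = TRUE)))
  }
  cat("\n")
})

setMethod("show", "CCAFilterBank", function(object) {
  cat(sprintf(
    "CCAFilterBank: %d classes, K=%d, trained at %d samples (%.3f s)\n",
    length(object@A), object@nComponents, object@windowLen,
    object@windowLen / object@fSample))
  r1 <- vapply(object@cors, `[`, numeric(1), 1L)
  cat("  first canonical correlations:",
      paste(sprintf("%.3f", r1), collapse = " "), "\n")
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d classes, d=%d, shrinkage gamma=%g\n",
              nrow(object@means), ncol(object@means), object@gamma))
})

setMethod("show", "StopConfig", function(object) {
  cat(sprintf(
    "StopConfig: N=%d P=%.2f chunk=%d samples, window %d..%d @ %g Hz\n",
    object@N, object@P, object@chunkSamples, object@minWindow,
    object@maxWindow, object@fSample))
})

setMethod("show", "Decision", function(object) {
  cat(sprintf("Decision: class %d at %d samples (%.3f s)%s, %d evaluations\n",
              object@label, object@stopWindow, object@stopTime,
              if (object@forced) " [forced]" else "", nrow(object@trace)))
})

setMethod("show", "ModelCache", function(object) {
  cat(sprintf(
    "ModelCache: %d window lengths (%d..%d samples, chunk %d) @ %g Hz\n",
    length(object@windows), min(object@windows), max(object@windows),
    object@chunkSamples, object@fSample))
})

setMethod("show", "SNREstimate", function(object) {
  cat(sprintf("SNREstimate: %.3f (signal %.4g / noise %.4g, %g Hz bins)\n",
              object@snr, object@signalPower, object@noisePower,
              object@resolution))
})
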