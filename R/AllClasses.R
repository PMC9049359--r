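#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for an L-channel, T-sample EEG segment together with its sampling
#' rate and channel labels. All pipeline stages (filtering, feature extraction,
#' online classification) accept either a `Recording` or a bare channels x
#' samples matrix.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of channel labels, one per row of `data`.
#'
#' @seealso [Recording()], [simulateTrial()], [readRecording()]
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric", channels = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channels) != nrow(object@data))
    msg <- c(msg, "one channel label per data row is required")
  if (length(msg)) msg else TRUE
})

#' Labeled set of fixed-length trials
#'
#' Holds trials cut from recordings, each a channels x samples matrix of
#' identical shape, with class labels in `1..nClasses`. This is the input to
#' filter-bank training, LDA training and all cross-validated evaluation.
#'
#' @slot trials list of channels x samples matrices, all the same dimension.
#' @slot labels integer class labels, one per trial.
#' @slot fs sampling rate in Hz.
#' @slot nClasses number of target classes C.
#' @slot channels channel labels shared by all trials.
#'
#' @seealso [TrialSet()], [simulateSession()]
#' @export
setClass("TrialSet",
  representation(trials = "list", labels = "integer", fs = "numeric",
                 nClasses = "integer", channels = "character"))

setValidity("TrialSet", function(object) {
  msg <- character()
  if (length(object@trials) != length(object@labels))
    msg <- c(msg, "one label per trial is required")
  if (length(object@trials)) {
    dims <- vapply(object@trials, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all trials must share the same channels x samples shape")
    if (dims[1, 1] != length(object@channels))
      msg <- c(msg, "channel labels must match trial rows")
  }
  if (any(object@labels < 1L) || any(object@labels > object@nClasses))
    msg <- c(msg, "labels must lie in 1..nClasses")
  if (length(msg)) msg else TRUE
})

#' Synthetic SSVEP session configuration
#'
#' Parameters of the synthetic EEG generator: montage size, class count,
#' stimulation and sampling frequency, target narrow-band SNR, background
#' noise spectral slope, and per-trial phase/amplitude variability.
#'
#' The `snr` field is the target value of the narrow-band SNR estimator
#' ([snr60Hz()]): power at the stimulation frequency divided by the mean power
#' of the 0.25 Hz bins within +-1.25 Hz of it. Because the stimulation bin also
#' contains noise, that estimator has a floor of 1; configured values at or
#' below 1 produce no stimulus-locked component at all.
#'
#' @slot nChannels number of EEG channels L (>= 2).
#' @slot nClasses number of target classes C (>= 2).
#' @slot fStim stimulation (flicker) frequency in Hz.
#' @slot fSample sampling rate in Hz.
#' @slot snr target narrow-band SNR (linear; see Details).
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @slot phaseJitter sd of the per-trial response phase, radians.
#' @slot ampJitter relative sd of the per-trial response amplitude.
#' @slot seed RNG seed (NA for "use current RNG state").
#'
#' @seealso [synthConfig()], [simulateTrial()], [simulateSession()]
#' @export
setClass("SynthConfig",
  representation(nChannels = "integer", nClasses = "integer",
                 fStim = "numeric", fSample = "numeric", snr = "numeric",
                 noiseExponent = "numeric", phaseJitter = "numeric",
                 ampJitter = "numeric", seed = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nChannels < 2L) msg <- c(msg, "at least 2 channels required")
  if (object@nClasses < 2L) msg <- c(msg, "at least 2 classes required")
  if (object@fStim >= object@fSample / 2)
    msg <- c(msg, "fStim must be below the Nyquist frequency")
  if (object@snr < 0) msg <- c(msg, "snr must be non-negative")
  if (object@phaseJitter < 0 || object@ampJitter < 0)
    msg <- c(msg, "jitter parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Class-specific scalp topographies
#'
#' C unit-norm channel-weight vectors, one scalp pattern per target class.
#' Spatial coding means each gaze target evokes the 60 Hz response with a
#' different topography; classification works exactly because these patterns
#' are distinct.
#'
#' @slot weights L x C numeric matrix; each column has unit Euclidean norm.
#' @slot minSeparation the separation constraint the matrix was built under:
#'   all pairwise absolute cosine similarities are <= 1 - minSeparation.
#'
#' @seealso [makeTopographies()]
#' @export
setClass("Topographies",
  representation(weights = "matrix", minSeparation = "numeric"))

setValidity("Topographies", function(object) {
  msg <- character()
  nrm <- sqrt(colSums(object@weights^2))
  if (any(abs(nrm - 1) > 1e-8)) msg <- c(msg, "columns must be unit norm")
  C <- ncol(object@weights)
  if (C >= 2) {
    cc <- abs(crossprod(object@weights))
    diag(cc) <- 0
    if (any(cc >= 1 - 1e-12)) msg <- c(msg, "classes must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' CCA spatial filter bank
#'
#' Per-class canonical correlation filters trained at one specific window
#' length: a spatial filter `A[[c]]` (L x K) for the EEG and a reference
#' filter `B[[c]]` (2 x K) for the sin/cos reference, plus the canonical
#' correlations attained on the training data. Feature extraction applies the
#' *fixed* trained filters to new windows; CCA is never re-solved on test data.
#'
#' @slot A list of L x K spatial filters, one per class.
#' @slot B list of 2 x K reference filters, one per class.
#' @slot cors list of canonical correlation vectors (descending), one per class.
#' @slot windowLen window length in samples the bank was trained at.
#' @slot fStim stimulation frequency in Hz.
#' @slot fSample sampling rate in Hz.
#' @slot nComponents number of canonical pairs kept (K <= 2).
#'
#' @seealso [trainFilterBank()], [extractFeatures()]
#' @export
setClass("CCAFilterBank",
  representation(A = "list", B = "list", cors = "list",
                 windowLen = "integer", fStim = "numeric",
                 fSample = "numeric", nComponents = "integer"))

setValidity("CCAFilterBank", function(object) {
  msg <- character()
  if (length(object@A) != length(object@B) ||
      length(object@A) != length(object@cors))
    msg <- c(msg, "A, B and cors must have one entry per class")
  if (object@nComponents > 2L)
    msg <- c(msg, "at most 2 canonical pairs exist against a 2-row reference")
  bad <- vapply(object@cors, function(r)
    any(r < -1e-9 | r > 1 + 1e-9) || is.unsorted(rev(r)), logical(1))
  if (any(bad))
    msg <- c(msg, "canonical correlations must lie in [0,1], non-increasing")
  if (length(msg)) msg else TRUE
})

#' Gaussian linear discriminant model
#'
#' Equal-covariance Gaussian classifier over CCA feature vectors: per-class
#' centroids, pooled within-class covariance and class priors. Posteriors come
#' from Bayes' theorem with multivariate Gaussian class conditionals; the
#' shared normalisation constant cancels.
#'
#' @slot means C x d matrix of class centroids.
#' @slot covariance d x d pooled within-class covariance (regularised if
#'   ill-conditioned).
#' @slot priors class prior probabilities, non-negative, summing to 1.
#' @slot gamma the shrinkage weight actually applied to the covariance.
#'
#' @seealso [trainLDA()], [ldaPosterior()], [ldaClassify()]
#' @export
setClass("LDAModel",
  representation(means = "matrix", covariance = "matrix",
                 priors = "numeric", gamma = "numeric"))

setValidity("LDAModel", function(object) {
  msg <- character()
  d <- ncol(object@means)
  if (!identical(dim(object@covariance), c(d, d)))
    msg <- c(msg, "covariance must be d x d")
  if (length(object@priors) != nrow(object@means))
    msg <- c(msg, "one prior per class required")
  if (any(object@priors < 0) || abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must be non-negative and sum to 1")
  if (any(abs(object@covariance - t(object@covariance)) > 1e-8))
    msg <- c(msg, "covariance must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Dynamic stopping configuration
#'
#' Parameters of the online stopping rule: the decision is final when N
#' consecutive classifications on growing windows have returned the same label,
#' each with winning-class posterior >= P. Windows grow by `chunkSamples` (the
#' amplifier delivery quantum) up to `maxWindow`, at which point a forced
#' decision is emitted.
#'
#' @slot N required number of consecutive agreements (>= 1).
#' @slot P posterior threshold in [0, 1].
#' @slot chunkSamples chunk size in samples (default 131).
#' @slot fSample sampling rate in Hz.
#' @slot minWindow first window length eligible for evaluation, samples.
#' @slot maxWindow timeout window length, samples.
#' @slot holdOnWeak if TRUE, a same-label evaluation below P leaves the
#'   agreement counter unchanged instead of resetting it to 0.
#' @slot includeForced if TRUE (default) forced timeout decisions count in
#'   session accuracy; if FALSE they are excluded.
#' @slot gapSeconds inter-trial gaze-shift time added to the ITR denominator
#'   (0 by default).
#'
#' @seealso [stopConfig()], [runTrial()], [runSession()]
#' @export
setClass("StopConfig",
  representation(N = "integer", P = "numeric", chunkSamples = "integer",
                 fSample = "numeric", minWindow = "integer",
                 maxWindow = "integer", holdOnWeak = "logical",
                 includeForced = "logical", gapSeconds = "numeric"))

setValidity("StopConfig", function(object) {
  msg <- character()
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (object@P < 0 || object@P > 1) msg <- c(msg, "P must lie in [0, 1]")
  if (object@chunkSamples < 1L) msg <- c(msg, "chunkSamples must be >= 1")
  if (object@minWindow > object@maxWindow)
    msg <- c(msg, "minWindow must not exceed maxWindow")
  if (object@gapSeconds < 0) msg <- c(msg, "gapSeconds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Online decision for one trial
#'
#' Result of running the dynamic stopping engine on one chunked EEG stream:
#' the predicted class, the window length and time at which data collection
#' stopped, whether the decision was forced by the timeout, and the per-chunk
#' trace of (window length, label, winning posterior).
#'
#' @slot label predicted class index.
#' @slot stopWindow window length in samples at the decision.
#' @slot stopTime stopWindow / fSample, seconds.
#' @slot forced TRUE if maxWindow (or the end of the stream) was reached
#'   before the stopping criterion was satisfied.
#' @slot trace data.frame with columns `window`, `label`, `posterior`, one row
#'   per evaluated chunk.
#'
#' @seealso [runTrial()]
#' @export
setClass("Decision",
  representation(label = "integer", stopWindow = "integer",
                 stopTime = "numeric", forced = "logical",
                 trace = "data.frame"))

#' Per-window-length model cache
#'
#' The online engine classifies windows of every multiple of the chunk size, so
#' the CCA filter bank and the LDA model are retrained for every such window
#' length on the training trials trimmed to that length. This class holds the
#' full map window length -> (CCAFilterBank, LDAModel) plus the band-pass
#' filter used throughout.
#'
#' @slot windows integer vector of cached window lengths (samples).
#' @slot banks list of [CCAFilterBank-class], named by window length.
#' @slot ldas list of [LDAModel-class], named by window length.
#' @slot coeffs FIR band-pass coefficients applied to every window.
#' @slot fStim stimulation frequency in Hz.
#' @slot fSample sampling rate in Hz.
#' @slot chunkSamples chunk quantum in samples.
#'
#' @seealso [buildModelCache()], [evaluateWindow()]
#' @export
setClass("ModelCache",
  representation(windows = "integer", banks = "list", ldas = "list",
                 coeffs = "numeric", fStim = "numeric", fSample = "numeric",
                 chunkSamples = "integer"))

setValidity("ModelCache", function(object) {
  msg <- character()
  if (length(object@banks) != length(object@windows) ||
      length(object@ldas) != length(object@windows))
    msg <- c(msg, "one bank and one LDA per cached window length")
  wl <- vapply(object@banks, function(b) b@windowLen, integer(1))
  if (length(wl) && any(wl != object@windows))
    msg <- c(msg, "each bank's trained window length must equal its key")
  if (length(msg)) msg else TRUE
})

#' Narrow-band SNR estimate
#'
#' Periodogram power at the stimulation frequency divided by the mean power of
#' the 0.25 Hz bins from 1.25 Hz below to 1.25 Hz above it, excluding the
#' stimulation bin itself (10 noise bins at exact resolution).
#'
#' @slot signalPower channel-averaged periodogram power at the stimulation bin.
#' @slot noisePower channel-averaged mean power over the flanking noise bins.
#' @slot snr signalPower / noisePower.
#' @slot resolution frequency resolution of the periodogram, Hz.
#'
#' @seealso [snr60Hz()]
#' @export
setClass("SNREstimate",
  representation(signalPower = "numeric", noisePower = "numeric",
                 snr = "numeric", resolution = "numeric"))
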