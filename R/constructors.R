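#' Create a Recording
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channels optional channel labels; defaults to `"Ch1".."ChL"`.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(2 * 100), 2), fs = 100)
#' nSamples(rec)
#' @export
Recording <- function(data, fs, channels = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(nrow(data)))
  new("Recording", data = data, fs = as.numeric(fs),
      channels = as.character(channels))
}

#' Create a TrialSet
#'
#' @param trials list of channels x samples matrices (or [Recording-class]
#'   objects) of identical shape.
#' @param labels class labels in `1..nClasses`, one per trial.
#' @param fs sampling rate in Hz.
#' @param nClasses number of classes; defaults to `max(labels)`.
#' @param channels optional channel labels.
#' @return A [TrialSet-class] object.
#' @export
TrialSet <- function(trials, labels, fs, nClasses = max(labels),
                     channels = NULL) {
  trials <- lapply(trials, function(t) {
    if (is(t, "Recording")) t@data else as.matrix(t)
  })
  if (is.null(channels)) {
    channels <- if (length(trials)) paste0("Ch", seq_len(nrow(trials[[1]])))
                else character()
  }
  new("TrialSet", trials = trials, labels = as.integer(labels),
      fs = as.numeric(fs), nClasses = as.integer(nClasses),
      channels = as.character(channels))
}

#' Configure the synthetic SSVEP generator
#'
#' Defaults emulate the recording setup the pipeline targets: a 32-channel
#' montage sampled at 2048 Hz, five gaze targets encoded in the scalp
#' topography of a 60 Hz flicker response.
#'
#' @param nChannels number of channels L.
#' @param nClasses number of classes C.
#' @param fStim stimulation frequency, Hz.
#' @param fSample sampling rate, Hz.
#' @param snr target narrow-band SNR (see [SynthConfig-class]).
#' @param noiseExponent spectral slope alpha of the 1/f^alpha background
#'   (0 gives white noise).
#' @param phaseJitter sd of the per-trial response phase, radians.
#' @param ampJitter relative sd of the per-trial response amplitude.
#' @param seed RNG seed; NA uses the current RNG state.
#' @return A [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nChannels = 8, fSample = 512, snr = 4, seed = 1)
#' @export
synthConfig <- function(nChannels = 32, nClasses = 5, fStim = 60,
                        fSample = 2048, snr = 4, noiseExponent = 1,
                        phaseJitter = 0.2, ampJitter = 0.2, seed = NA) {
  new("SynthConfig", nChannels = as.integer(nChannels),
      nClasses = as.integer(nClasses), fStim = as.numeric(fStim),
      fSample = as.numeric(fSample), snr = as.numeric(snr),
      noiseExponent = as.numeric(noiseExponent),
      phaseJitter = as.numeric(phaseJitter),
      ampJitter = as.numeric(ampJitter), seed = as.numeric(seed))
}

#' Configure the dynamic stopping rule
#'
#' @param N required consecutive agreeing classifications (default 2).
#' @param P posterior threshold (default 0.95).
#' @param chunkSamples chunk quantum in samples (default 131, the amplifier
#'   delivery size at 2048 Hz).
#' @param fSample sampling rate, Hz.
#' @param minWindow first window eligible for evaluation, samples; defaults to
#'   the chunk size (and is raised to the filter length + 1 by
#'   [buildModelCache()] when a longer filter is in use).
#' @param maxWindow timeout, samples; default 4 s worth (the training trial
#'   length).
#' @param holdOnWeak see [StopConfig-class].
#' @param includeForced see [StopConfig-class].
#' @param gapSeconds see [StopConfig-class].
#' @return A [StopConfig-class] object.
#' @examples
#' stopConfig(N = 2, P = 0.95)
#' @export
stopConfig <- function(N = 2, P = 0.95, chunkSamples = 131, fSample = 2048,
                       minWindow = chunkSamples,
                       maxWindow = round(4 * fSample), holdOnWeak = FALSE,
                       includeForced = TRUE, gapSeconds = 0) {
  new("StopConfig", N = as.integer(N), P = as.numeric(P),
      chunkSamples = as.integer(chunkSamples), fSample = as.numeric(fSample),
      minWindow = as.integer(minWindow), maxWindow = as.integer(maxWindow),
      holdOnWeak = isTRUE(holdOnWeak), includeForced = isTRUE(includeForced),
      gapSeconds = as.numeric(gapSeconds))
}
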