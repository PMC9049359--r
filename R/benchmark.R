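#' Synthetic cohort comparison of dynamic stopping vs. fixed windows
#'
#' Simulates a cohort of synthetic subjects spanning a range of SSVEP response
#' strengths and, for each subject, compares the dynamic stopping engine
#' against the best fixed analysis window:
#'
#' 1. a training session is simulated and the per-window-length model cache
#'    is built from it;
#' 2. the ITR-optimal fixed window is determined on the training data by
#'    leave-one-trial-out cross-validation;
#' 3. a fresh online session is simulated; dynamic stopping is run on it, and
#'    the fixed-window alternative classifies the same trials at the (cached
#'    length nearest to the) optimal fixed window;
#' 4. both are scored by ITR.
#'
#' Subjects differ in target SNR (geometrically spaced over `snrRange`) and in
#' their scalp topographies; everything is reproducible from `seed`.
#'
#' @param nSubjects number of synthetic subjects (default 20).
#' @param snrRange range of target narrow-band SNRs, geometrically spaced.
#' @param nTrainSequences training sequences per subject (default 30).
#' @param nOnlineSequences online sequences per subject (default 5).
#' @param trialDuration trial length in seconds (default 4).
#' @param nChannels,fSample montage size and sampling rate.
#' @param N,P stopping parameters (defaults 2 and 0.95).
#' @param chunkSamples chunk quantum (default 131).
#' @param filterOrder FIR band-pass order (default 66).
#' @param fixedGrid window grid (seconds) for the optimal fixed window.
#' @param seed base RNG seed.
#' @param verbose print one progress line per subject.
#' @return data.frame with one row per subject: configured and measured SNR,
#'   dynamic stopping accuracy / mean stop time / ITR, the optimal fixed
#'   window, and fixed-window accuracy / ITR on the same online trials.
#' @export
runDSBenchmark <- function(nSubjects = 20, snrRange = c(0.5, 8),
                           nTrainSequences = 30, nOnlineSequences = 5,
                           trialDuration = 4, nChannels = 32, fSample = 2048,
                           N = 2, P = 0.95, chunkSamples = 131,
                           filterOrder = 66,
                           fixedGrid = seq(0.25, 2, by = 0.25),
                           seed = 1, verbose = FALSE) {
  snrs <- exp(seq(log(snrRange[1]), log(snrRange[2]), length.out = nSubjects))
  seeds <- .subSeeds(seed, 3L * nSubjects)
  h <- designBandpass(filterOrder, c(55, 65), fSample)
  scfg <- stopConfig(N = N, P = P, chunkSamples = chunkSamples,
                     fSample = fSample,
                     maxWindow = round(trialDuration * fSample))
  rows <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    topo <- makeTopographies(nChannels, 5, seed = seeds[3 * s - 2])
    cfgTrain <- synthConfig(nChannels = nChannels, fSample = fSample,
                            snr = snrs[s], seed = seeds[3 * s - 1])
    cfgOnline <- synthConfig(nChannels = nChannels, fSample = fSample,
                             snr = snrs[s], seed = seeds[3 * s])
    training <- simulateSession(nTrainSequences, trialDuration, cfgTrain, topo)
    trainF <- filterTrials(h, training)
    cache <- buildModelCache(trainF, scfg, h, prefiltered = TRUE)
    ofw <- optimalFixedWindow(trainF, fixedGrid)
    online <- simulateSession(nOnlineSequences, trialDuration, cfgOnline, topo)

    ds <- runSession(online, cache = cache, config = scfg)

    wFix <- cache@windows[which.min(abs(cache@windows -
                                          ofw$Tstar * fSample))]
    predFix <- vapply(trials(online), function(X)
      evaluateWindow(X[, seq_len(wFix), drop = FALSE], cache)$label,
      integer(1))
    accFix <- mean(predFix == trialLabels(online))
    tFix <- wFix / fSample
    snrMeas <- mean(vapply(trials(online)[1:5], function(X)
      snrValue(snr60Hz(X, fs = fSample)), numeric(1)))
    rows[[s]] <- data.frame(
      subject = s, snr = snrs[s], snrMeasured = snrMeas,
      accDS = ds$accuracy, meanStopTime = ds$meanStopTime,
      itrDS = ds$itrBitsMin, nForced = ds$nForced,
      fixedWindow = tFix, accFixed = accFix,
      itrFixed = itr(max(accFix, 1e-12), 5, tFix))
    if (verbose)
      message(sprintf(
        "subject %2d: snr %.2f  DS acc %.2f @ %.2fs (%.1f bits/min)  fixed acc %.2f @ %.2fs (%.1f bits/min)",
        s, snrs[s], ds$accuracy, ds$meanStopTime, ds$itrBitsMin,
        accFix, tFix, rows[[s]]$itrFixed))
  }
  do.call(rbind, rows)
}
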