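#' Chunk-aligned window lengths
#'
#' The window lengths the online engine can evaluate: every multiple of the
#' chunk size within `[minWindow, maxWindow]`. At the default 131-sample
#' chunks and a 4 s / 2048 Hz timeout this yields `floor(8192/131) = 62`
#' lengths (131, 262, ..., 8122).
#'
#' @param chunkSamples chunk quantum in samples.
#' @param minWindow smallest admissible window, samples.
#' @param maxWindow timeout window, samples.
#' @return Integer vector of window lengths.
#' @examples
#' length(chunkWindows(131, 131, 8192))  # 62
#' @export
chunkWindows <- function(chunkSamples, minWindow = chunkSamples, maxWindow) {
  chunkSamples <- as.integer(chunkSamples)
  kmin <- as.integer(ceiling(minWindow / chunkSamples))
  kmax <- as.integer(floor(maxWindow / chunkSamples))
  if (kmax < kmin) stop("no chunk multiple lies in [minWindow, maxWindow]")
  chunkSamples * (kmin:kmax)
}

#' Build the per-window-length model cache
#'
#' Filters the training trials, then for every chunk-aligned window length
#' trims them to that length and trains the class-specific CCA filter bank and
#' the LDA classifier on the trimmed data. Online windows are then always
#' classified by models trained at exactly their own length, which is what
#' keeps accuracy stable on short growing windows.
#'
#' The smallest cached window is raised to `length(coeffs) + 1` if the
#' zero-phase filter is longer than the configured minimum (a window must
#' exceed the filter length to be filterable).
#'
#' @param training a raw (unfiltered) [TrialSet-class]; trials must be at
#'   least `maxWindow` samples long.
#' @param config a [StopConfig-class].
#' @param coeffs FIR coefficients from [designBandpass()].
#' @param fStim stimulation frequency in Hz.
#' @param nComponents canonical pairs kept per class.
#' @param prefiltered set TRUE if `training` has already been band-pass
#'   filtered with `coeffs` (skips the internal filtering pass).
#' @return A [ModelCache-class].
#' @export
buildModelCache <- function(training, config = stopConfig(fSample = sampleRate(training)),
                            coeffs = designBandpass(66, fs = sampleRate(training)),
                            fStim = 60, nComponents = 2, prefiltered = FALSE) {
  stopifnot(is(training, "TrialSet"), is(config, "StopConfig"))
  if (nSamples(training) < config@maxWindow)
    stop("training trials are shorter than maxWindow")
  minW <- max(config@minWindow, length(coeffs) + 1L)
  windows <- chunkWindows(config@chunkSamples, minW, config@maxWindow)
  filtered <- if (prefiltered) training else filterTrials(coeffs, training)
  fs <- sampleRate(training)
  C <- nClasses(training)
  labs <- trialLabels(training)
  if (any(tabulate(labs, C) < 2L)) stop("every class needs >= 2 trials")
  wmax <- max(windows)
  Y <- makeReference(fStim, fs, wmax)
  ref <- .refStats(Y, windows)
  stats <- lapply(trials(filtered), function(X)
    .trialStats(X[, seq_len(wmax), drop = FALSE], Y, windows))

  banks <- vector("list", length(windows))
  ldas <- vector("list", length(windows))
  n <- length(stats)
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    A <- vector("list", C); B <- vector("list", C); cors <- vector("list", C)
    for (cl in seq_len(C)) {
      sc <- .pooledScatter(stats[labs == cl], wi, w, ref)
      fit <- .ccaCore(sc$Sxx, sc$Sxy, sc$Syy, df = sc$Ttot - 1)
      K <- min(nComponents, length(fit$cor))
      A[[cl]] <- fit$A[, seq_len(K), drop = FALSE]
      B[[cl]] <- fit$B[, seq_len(K), drop = FALSE]
      cors[[cl]] <- fit$cor[seq_len(K)]
    }
    banks[[wi]] <- new("CCAFilterBank", A = A, B = B, cors = cors,
                       windowLen = w, fStim = fStim, fSample = fs,
                       nComponents = as.integer(nComponents))
    flat <- .flattenStats(stats, wi)
    F0 <- vapply(seq_len(C), function(cl)
      .featuresBatch(flat, wi, w, ref, A[[cl]][, 1L], B[[cl]][, 1L]),
      numeric(n))
    ldas[[wi]] <- trainLDA(F0, labs)
  }
  names(banks) <- names(ldas) <- as.character(windows)
  new("ModelCache", windows = windows, banks = banks, ldas = ldas,
      coeffs = as.numeric(coeffs), fStim = fStim, fSample = fs,
      chunkSamples = config@chunkSamples)
}

#' Classify one window with the length-matched models
#'
#' Band-pass filters the window, extracts the CCA feature vector with the
#' filter bank trained at exactly this window length, and applies the matching
#' LDA. The window length must be one of the cached lengths.
#'
#' @param window L x w matrix or [Recording-class].
#' @param cache a [ModelCache-class].
#' @return List with `label` (class index), `posterior` (winning class
#'   posterior) and `features`.
#' @export
evaluateWindow <- function(window, cache) {
  X <- .asSignal(window)
  w <- ncol(X)
  key <- as.character(w)
  if (!key %in% names(cache@banks))
    stop(sprintf("window length %d is not cached", w))
  Xf <- applyZeroPhase(cache@coeffs, X)
  f <- extractFeatures(Xf, cache@banks[[key]])
  post <- ldaPosterior(cache@ldas[[key]], f)
  lab <- which.max(post)
  list(label = lab, posterior = post[lab], features = f)
}

# Full per-chunk trace of a trial: evaluate every cached window length the
# trial covers, without stopping. Used by the (N, P) grid search.
.fullTrace <- function(X, cache) {
  X <- .asSignal(X)
  ws <- cache@windows[cache@windows <= ncol(X)]
  rows <- lapply(ws, function(w) {
    ev <- evaluateWindow(X[, seq_len(w), drop = FALSE], cache)
    data.frame(window = w, label = ev$label, posterior = ev$posterior)
  })
  do.call(rbind, rows)
}

#' Apply the N-consecutive / posterior-threshold stopping rule
#'
#' Scans a sequence of per-window (label, posterior) evaluations and returns
#' the 1-based index at which the decision becomes final: the first position
#' where N consecutive evaluations have returned the same label, each with
#' posterior >= P. An evaluation below threshold resets the agreement counter
#' to 0 (or leaves it unchanged when `holdOnWeak` and the label repeats); an
#' above-threshold evaluation with a new label restarts the counter at 1.
#'
#' `N = 1` degenerates to a pure posterior-threshold stopper; `P = 0` to pure
#' label-stability stopping.
#'
#' @param labels integer labels, one per evaluation.
#' @param posteriors winning-class posteriors, same length.
#' @param N required consecutive agreements.
#' @param P posterior threshold.
#' @param holdOnWeak see [StopConfig-class].
#' @return The stopping index, or `NA` if the criterion is never met.
#' @examples
#' applyStopRule(c(1, 1), c(0.99, 0.98), N = 2, P = 0.95)        # 2
#' applyStopRule(c(1, 2, 2), c(0.99, 0.99, 0.99), N = 2, P = 0.95)  # 3
#' @export
applyStopRule <- function(labels, posteriors, N, P, holdOnWeak = FALSE) {
  if (length(labels) != length(posteriors))
    stop("labels and posteriors must have equal length")
  count <- 0L
  prev <- NA_integer_
  for (i in seq_along(labels)) {
    same <- !is.na(prev) && labels[i] == prev
    if (posteriors[i] >= P) {
      count <- if (same) count + 1L else 1L
    } else if (!(holdOnWeak && same)) {
      count <- 0L
    }
    prev <- labels[i]
    if (count >= N) return(i)
  }
  NA_integer_
}

#' Run the dynamic stopping engine on one trial
#'
#' Consumes the chunk stream, growing the analysis window by one chunk at a
#' time. Every chunk-aligned window from the model cache is classified with
#' its length-matched models, and data collection stops as soon as N
#' consecutive classifications agree with posterior >= P. If the stream or
#' the `maxWindow` timeout is exhausted first, the last label is emitted as a
#' forced decision.
#'
#' @param stream a list of L x chunk matrices (from [chunkStream()]), or a
#'   [Recording-class]/matrix which is chunked internally.
#' @param cache a [ModelCache-class].
#' @param config a [StopConfig-class] (N, P, windows, flags).
#' @return A [Decision-class].
#' @export
runTrial <- function(stream, cache, config) {
  stopifnot(is(cache, "ModelCache"), is(config, "StopConfig"))
  if (!is.list(stream)) stream <- chunkStream(stream, config@chunkSamples)
  if (!length(stream)) stop("insufficient data: empty stream")
  window <- NULL
  count <- 0L
  prev <- NA_integer_
  trace <- list()
  for (chunk in stream) {
    window <- if (is.null(window)) chunk else cbind(window, chunk)
    w <- ncol(window)
    if (w > config@maxWindow) break
    if (!as.character(w) %in% names(cache@banks)) next
    ev <- evaluateWindow(window, cache)
    trace[[length(trace) + 1L]] <-
      data.frame(window = w, label = ev$label, posterior = ev$posterior)
    same <- !is.na(prev) && ev$label == prev
    if (ev$posterior >= config@P) {
      count <- if (same) count + 1L else 1L
    } else if (!(config@holdOnWeak && same)) {
      count <- 0L
    }
    prev <- ev$label
    if (count >= config@N) {
      return(new("Decision", label = as.integer(ev$label),
                 stopWindow = as.integer(w), stopTime = w / config@fSample,
                 forced = FALSE, trace = do.call(rbind, trace)))
    }
  }
  if (!length(trace))
    stop("insufficient data: stream ended before the minimum window")
  tr <- do.call(rbind, trace)
  last <- nrow(tr)
  new("Decision", label = as.integer(tr$label[last]),
      stopWindow = as.integer(tr$window[last]),
      stopTime = tr$window[last] / config@fSample,
      forced = TRUE, trace = tr)
}

#' Run an online session
#'
#' Applies [runTrial()] to every trial stream and summarises the session:
#' accuracy (forced timeout decisions included or excluded per the config),
#' mean stopping time, the resulting ITR (with T the mean stopping time plus
#' the configured inter-trial gap), and a per-target breakdown.
#'
#' @param streams a [TrialSet-class] (its labels are used), or a list of
#'   recordings/matrices.
#' @param labels true class labels (ignored when `streams` is a TrialSet).
#' @param cache a [ModelCache-class].
#' @param config a [StopConfig-class].
#' @return List with `decisions` (list of [Decision-class]), `accuracy`,
#'   `meanStopTime` (s), `itrBitsMin`, `nForced` and `perTarget` (data.frame).
#' @export
runSession <- function(streams, labels = NULL, cache, config) {
  if (is(streams, "TrialSet")) {
    labels <- trialLabels(streams)
    streams <- trials(streams)
  }
  if (length(streams) != length(labels))
    stop("one true label per stream is required")
  if (!length(streams)) stop("need at least one trial")
  decisions <- lapply(streams, runTrial, cache = cache, config = config)
  pred <- vapply(decisions, decisionLabel, integer(1))
  tsec <- vapply(decisions, stopTime, numeric(1))
  forced <- vapply(decisions, function(d) d@forced, logical(1))
  used <- if (config@includeForced) rep(TRUE, length(pred)) else !forced
  G <- if (any(used)) mean(pred[used] == labels[used]) else NA_real_
  Tm <- mean(tsec) + config@gapSeconds
  C <- length(cache@banks[[1]]@A)
  per <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    idx <- labels == cl
    data.frame(target = cl, n = sum(idx),
               accuracy = mean(pred[idx] == cl),
               meanTime = mean(tsec[idx]))
  }))
  list(decisions = decisions, accuracy = G, meanStopTime = mean(tsec),
       itrBitsMin = itr(max(G, 1e-12), C, Tm),
       nForced = sum(forced), perTarget = per)
}
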