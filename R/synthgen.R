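#' Generate class-specific scalp topographies
#'
#' Draws C unit-norm channel-weight vectors, one scalp pattern per target
#' class, with all pairwise absolute cosine similarities at most
#' `1 - minSeparation`. With `minSeparation = 1` the patterns are exactly
#' orthonormal. Deterministic for a fixed seed.
#'
#' For plausible montages (L much larger than C) random directions are nearly
#' orthogonal and the constraint is met immediately; in low dimensions a
#' repulsion refinement is run, and an error is raised if the requested
#' separation is infeasible (e.g. 5 near-orthogonal patterns cannot exist in 2
#' channels).
#'
#' @param L number of channels (>= 2).
#' @param C number of classes (>= 2).
#' @param minSeparation required separation in `[0, 1]`; pairwise |cosine|
#'   must not exceed `1 - minSeparation`. The default 0.5 is a deliberately
#'   conservative guess at real inter-class similarity and should be treated
#'   as tunable.
#' @param seed RNG seed.
#' @return A [Topographies-class] object (L x C unit columns).
#' @examples
#' topo <- makeTopographies(32, 5, seed = 1)
#' max(abs(crossprod(topographyWeights(topo))) - diag(5))
#' @export
makeTopographies <- function(L, C, minSeparation = 0.5, seed = NULL) {
  L <- as.integer(L); C <- as.integer(C)
  if (C < 2L) stop("C must be >= 2")
  if (L < 2L) stop("L must be >= 2")
  if (minSeparation < 0 || minSeparation > 1)
    stop("minSeparation must lie in [0, 1]")
  rho <- 1 - minSeparation

  if (minSeparation == 1) {
    if (C > L)
      stop(sprintf("cannot place %d orthogonal patterns in %d channels", C, L))
    W <- .withSeed(seed, qr.Q(qr(matrix(stats::rnorm(L * C), L, C))))
    # fix sign for determinism across BLAS conventions
    W <- sweep(W, 2, sign(W[1, ] + (W[1, ] == 0)), "*")
    return(new("Topographies", weights = W, minSeparation = minSeparation))
  }

  W <- .withSeed(seed, {
    best <- NULL
    for (try in 1:20) {
      W <- matrix(stats::rnorm(L * C), L, C)
      W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
      # repulsion refinement: push apart pairs exceeding the allowed cosine
      for (it in 1:500) {
        G <- crossprod(W); diag(G) <- 0
        viol <- abs(G) > rho
        if (!any(viol)) break
        step <- W %*% (G * viol) * 0.5
        W <- W - step
        W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
      }
      G <- crossprod(W); diag(G) <- 0
      if (all(abs(G) <= rho + 1e-9)) { best <- W; break }
    }
    best
  })
  if (is.null(W))
    stop(sprintf(
      "infeasible separation: %d patterns with |cosine| <= %.3f in %d channels",
      C, rho, L))
  new("Topographies", weights = W, minSeparation = minSeparation)
}

# Two-sided noise power spectrum used by the synthesiser: E|FFT_j|^2 for
# j = 1..n/2-1, scaled so the time-domain variance per channel is 1.
.noisePowerSpectrum <- function(n, fs, alpha) {
  j <- seq_len(floor(n / 2) - 1L)
  fj <- j * fs / n
  shape <- fj^(-alpha)
  c0 <- n^2 / (2 * sum(shape))
  list(j = j, f = fj, power = c0 * shape)
}

# One draw of L-channel 1/f^alpha noise (channels x n), unit variance per
# channel, spatially correlated through a random unit-row mixing matrix.
.synthNoise <- function(L, n, fs, alpha) {
  ps <- .noisePowerSpectrum(n, fs, alpha)
  half <- length(ps$j)
  Z <- matrix(complex(real = stats::rnorm(half * L),
                      imaginary = stats::rnorm(half * L)),
              half, L) * sqrt(ps$power / 2)
  spec <- matrix(complex(real = 0), n, L)
  spec[ps$j + 1L, ] <- Z
  spec[n + 1L - ps$j, ] <- Conj(Z)
  W <- t(Re(stats::mvfft(spec, inverse = TRUE)) / n)
  M <- matrix(stats::rnorm(L * L), L, L)
  M <- sweep(M, 1, sqrt(rowSums(M^2)), "/")
  M %*% W
}

# Stimulus tone amplitude (time domain, summed over channels through the unit
# norm topography) calibrated so that the expected narrow-band SNR estimator
# equals max(snr, 1). Calibration is anchored at the estimator's canonical
# 4-second window.
.toneAmplitude <- function(config) {
  snr <- config@snr
  if (is.infinite(snr)) return(1)
  target <- max(snr, 1)
  if (target <= 1) return(0)
  nCal <- round(4 * config@fSample)
  ps <- .noisePowerSpectrum(nCal, config@fSample, config@noiseExponent)
  res <- config@fSample / nCal                       # 0.25 Hz
  bins <- round((config@fStim + seq(-1.25, 1.25, by = res)) / res)
  stimBin <- round(config@fStim / res)
  noiseBins <- setdiff(bins, stimBin)
  pNoise <- mean(ps$power[noiseBins])                # ps$power[j] is bin j
  pStim <- ps$power[stimBin]
  a2 <- (target * pNoise - pStim) * config@nChannels * 4 / nCal^2
  sqrt(max(a2, 0))
}

#' Simulate one SSVEP trial
#'
#' Generates an L-channel EEG segment containing a narrow-band response at the
#' stimulation frequency with the scalp pattern of the requested class,
#' embedded in spatially mixed 1/f^alpha background noise. The per-trial
#' response is `a * sin(2*pi*fStim*t + phi)` with phase and amplitude jitter
#' drawn per trial; the amplitude is calibrated so the narrow-band SNR
#' estimator recovers `config@snr` in expectation (see [SynthConfig-class]).
#'
#' `snr = Inf` gives the noiseless limit (unit-amplitude rank-1 sinusoid),
#' `snr = 0` a signal-free recording.
#'
#' @param classLabel class index in `1..C`.
#' @param duration trial length in seconds (at least one stimulation cycle).
#' @param config a [SynthConfig-class].
#' @param topographies a [Topographies-class] with matching L and C.
#' @param seed optional RNG seed (defaults to the current RNG state).
#' @return A [Recording-class] of `round(duration * fSample)` samples.
#' @examples
#' cfg <- synthConfig(nChannels = 8, fSample = 512, snr = Inf)
#' topo <- makeTopographies(8, 5, seed = 1)
#' rec <- simulateTrial(1, 0.5, cfg, topo)
#' @export
simulateTrial <- function(classLabel, duration, config, topographies,
                          seed = NULL) {
  stopifnot(is(config, "SynthConfig"), is(topographies, "Topographies"))
  W <- topographies@weights
  if (nrow(W) != config@nChannels || ncol(W) != config@nClasses)
    stop("topographies do not match the configured montage")
  classLabel <- as.integer(classLabel)
  if (classLabel < 1L || classLabel > config@nClasses)
    stop(sprintf("class index %d out of range 1..%d", classLabel,
                 config@nClasses))
  n <- round(duration * config@fSample)
  if (duration <= 0 || n < config@fSample / config@fStim)
    stop("duration must cover at least one stimulation cycle")

  .withSeed(seed, {
    a0 <- .toneAmplitude(config)
    phi <- config@phaseJitter * stats::rnorm(1)
    a <- a0 * max(0, 1 + config@ampJitter * stats::rnorm(1)) /
      sqrt(1 + config@ampJitter^2)
    t <- (seq_len(n) - 1) / config@fSample
    s <- a * sin(2 * pi * config@fStim * t + phi)
    X <- W[, classLabel] %o% s
    if (!is.infinite(config@snr))
      X <- X + .synthNoise(config@nChannels, n, config@fSample,
                           config@noiseExponent)
    Recording(X, config@fSample)
  })
}

#' Simulate a training or online session
#'
#' Produces `C * nSequences` labeled trials. Each sequence visits every class
#' exactly once in randomized order, mirroring the balanced cueing protocol of
#' a spatially-coded BCI session. Reproducible under the config seed.
#'
#' @param nSequences number of sequences (>= 1); a training session uses 30.
#' @param trialDuration trial length in seconds (4 in the emulated protocol).
#' @param config a [SynthConfig-class]; its `seed` drives all randomness.
#' @param topographies a [Topographies-class].
#' @return A [TrialSet-class] with `nSequences` trials per class.
#' @examples
#' cfg <- synthConfig(nChannels = 8, fSample = 512, snr = 4, seed = 1)
#' topo <- makeTopographies(8, 5, seed = 2)
#' ts <- simulateSession(2, 1, cfg, topo)
#' table(trialLabels(ts))
#' @export
simulateSession <- function(nSequences, trialDuration, config, topographies) {
  nSequences <- as.integer(nSequences)
  if (nSequences < 1L) stop("nSequences must be >= 1")
  C <- config@nClasses
  .withSeed(if (is.na(config@seed)) NULL else config@seed, {
    labels <- as.integer(unlist(lapply(seq_len(nSequences),
                                       function(s) sample.int(C))))
    trialList <- lapply(labels, function(lab)
      eegData(simulateTrial(lab, trialDuration, config, topographies)))
    TrialSet(trialList, labels, fs = config@fSample, nClasses = C)
  })
}

#' Split a recording into amplifier-style chunks
#'
#' Yields consecutive, non-overlapping chunks of exactly `chunkSamples`
#' samples, in order. A final partial chunk is withheld (never emitted),
#' matching the behaviour of an acquisition driver that delivers data only in
#' full buffers. At 2048 Hz and 131-sample chunks this caps the online update
#' rate at 2048/131 = 15.6 Hz.
#'
#' @param recording a [Recording-class] or channels x samples matrix.
#' @param chunkSamples chunk size in samples (default 131).
#' @return List of channels x `chunkSamples` matrices.
#' @examples
#' rec <- Recording(matrix(rnorm(2 * 700), 2), fs = 2048)
#' length(chunkStream(rec, 131))  # 5 full chunks; 45 samples withheld
#' @export
chunkStream <- function(recording, chunkSamples = 131) {
  X <- .asSignal(recording)
  chunkSamples <- as.integer(chunkSamples)
  if (chunkSamples < 1L) stop("chunkSamples must be >= 1")
  k <- ncol(X) %/% chunkSamples
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i)
    X[, ((i - 1L) * chunkSamples + 1L):(i * chunkSamples), drop = FALSE])
}
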