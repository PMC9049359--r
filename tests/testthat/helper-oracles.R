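# Independent oracles and shared small-scale fixtures.

# Brute-force first canonical correlation by direction search: coarse grid
# over unit spatial filters (L <= 3) and reference angles, refined with
# Nelder-Mead. Independent of the whitening/SVD solver.
ccaOracle <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  L <- nrow(X)
  stopifnot(L <= 3)
  aFromPar <- function(p) {
    if (L == 2) c(cos(p[1]), sin(p[1]))
    else c(cos(p[1]) * cos(p[2]), sin(p[1]) * cos(p[2]), sin(p[2]))
  }
  score <- function(p) {
    a <- aFromPar(p[-length(p)])
    b <- c(cos(p[length(p)]), sin(p[length(p)]))
    px <- drop(a %*% Xc); py <- drop(b %*% Yc)
    if (sd(px) == 0 || sd(py) == 0) return(0)
    -abs(cor(px, py))
  }
  npar <- if (L == 2) 2 else 3
  grid <- seq(0, pi, length.out = 13)
  pars <- as.matrix(expand.grid(rep(list(grid), npar)))
  vals <- apply(pars, 1, score)
  p0 <- pars[which.min(vals), ]
  opt <- optim(p0, score, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  -opt$value
}

# Straightforward scan implementation of the stopping rule: the decision is
# final at the first index whose last N evaluations all meet the posterior
# threshold and share one label.
stopOracle <- function(labels, posteriors, N, P) {
  for (i in seq_along(labels)) {
    if (i < N) next
    idx <- (i - N + 1):i
    if (all(posteriors[idx] >= P) && length(unique(labels[idx])) == 1)
      return(i)
  }
  NA_integer_
}

# Small-montage study conditions used throughout the unit tests: 8 channels
# at 512 Hz keep every pipeline property intact at a fraction of the cost of
# the full 32-channel / 2048 Hz setup.
.fixtures <- new.env()

smallTopo <- function() {
  if (is.null(.fixtures$topo))
    .fixtures$topo <- makeTopographies(8, 5, seed = 101)
  .fixtures$topo
}

smallConfig <- function(snr = 6, seed = 11, ...) {
  synthConfig(nChannels = 8, fSample = 512, snr = snr, seed = seed, ...)
}

# A filtered training set plus its matching cache, built once.
smallSystem <- function() {
  if (is.null(.fixtures$system)) {
    fs <- 512
    h <- designBandpass(66, c(55, 65), fs)
    train <- simulateSession(6, 2, smallConfig(snr = 6, seed = 21),
                             smallTopo())
    scfg <- stopConfig(N = 2, P = 0.95, chunkSamples = 64, fSample = fs,
                       maxWindow = 2 * fs)
    trainF <- filterTrials(h, train)
    cache <- buildModelCache(trainF, scfg, h, prefiltered = TRUE)
    .fixtures$system <- list(fs = fs, h = h, train = train, trainF = trainF,
                             scfg = scfg, cache = cache)
  }
  .fixtures$system
}

# Noiseless trials: pure rank-1 sinusoids through the class topographies.
# Useful for exact canonical-correlation limits; note that classification
# degenerates in the exactly noiseless limit (every nonzero projection of a
# pure sinusoid correlates perfectly with the reference), so separability
# tests use separableSet() below instead.
noiselessSet <- function(nPerClass = 2, duration = 1, fs = 512) {
  cfg <- synthConfig(nChannels = 8, fSample = fs, snr = Inf,
                     phaseJitter = 0, ampJitter = 0)
  topo <- smallTopo()
  labels <- rep(1:5, each = nPerClass)
  trialList <- lapply(labels, function(lab)
    eegData(simulateTrial(lab, duration, cfg, topo)))
  TrialSet(trialList, labels, fs = fs, nClasses = 5)
}

# Practically separable trials: orthogonal scalp patterns and a very strong
# (but finite) SNR with ordinary trial-to-trial variability, so cross-class
# projections are essentially noise, within-class feature variance stays
# non-degenerate, and every pipeline stage classifies at accuracy 1.
.sepTopo <- function() {
  if (is.null(.fixtures$sepTopo))
    .fixtures$sepTopo <- makeTopographies(8, 5, minSeparation = 1, seed = 103)
  .fixtures$sepTopo
}

separableSet <- function(nPerClass = 6, duration = 2, fs = 512, seed = 107) {
  cfg <- synthConfig(nChannels = 8, fSample = fs, snr = 50,
                     phaseJitter = 0.05, ampJitter = 0.05)
  labels <- rep(1:5, each = nPerClass)
  trialList <- lapply(seq_along(labels), function(i)
    eegData(simulateTrial(labels[i], duration, cfg, .sepTopo(),
                          seed = seed + i)))
  TrialSet(trialList, labels, fs = fs, nClasses = 5)
}
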