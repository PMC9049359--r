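#' Information transfer rate
#'
#' Wolpaw-style ITR in bits per minute for a C-class selection with accuracy G
#' and selection time T seconds:
#' `ITR = (60 / T) * (log2 C + G log2 G + (1 - G) log2((1 - G) / (C - 1)))`.
#' The `G log2 G` term is taken as 0 at `G = 1` (continuity), so perfect
#' accuracy gives `(60 / T) * log2 C` and chance accuracy `G = 1/C` gives 0.
#' The formula is convex in G with its minimum (zero) exactly at chance;
#' below-chance accuracies therefore yield small positive values again. They
#' are returned as computed, flagged with a warning rather than clamped.
#'
#' @param G classification accuracy in `(0, 1]` (vectorised).
#' @param C number of classes (>= 2).
#' @param T seconds per selection (> 0, vectorised).
#' @return ITR in bits/min.
#' @examples
#' itr(1, 5, 60)      # 2.3219 bits/min
#' itr(0.2, 5, 1)     # 0: chance carries no information
#' @export
itr <- function(G, C, T) {
  if (any(C < 2)) stop("C must be >= 2")
  if (any(T <= 0)) stop("T must be positive")
  if (any(G <= 0 | G > 1)) stop("G must lie in (0, 1]")
  if (any(G < 1 / C))
    warning("accuracy below chance: ITR value is not meaningful")
  bits <- log2(C) + ifelse(G > 0, G * log2(G), 0) +
    ifelse(G < 1, (1 - G) * log2((1 - G) / (C - 1)), 0)
  (60 / T) * bits
}

# Leave-one-trial-out accuracy at several window lengths simultaneously,
# sharing the per-trial sufficient statistics. windows in samples, ascending.
# leak = TRUE deliberately skips the exclusion (negative control).
.looMulti <- function(training, windows, fStim = 60, nComponents = 2,
                      leak = FALSE) {
  windows <- as.integer(sort(windows))
  fs <- sampleRate(training)
  C <- nClasses(training)
  labs <- trialLabels(training)
  n <- nTrials(training)
  if (any(tabulate(labs, C) < 2L)) stop("every class needs >= 2 trials")
  if (max(windows) > nSamples(training))
    stop("window exceeds the trial length")
  wmax <- max(windows)
  Y <- makeReference(fStim, fs, wmax)
  ref <- .refStats(Y, windows)
  stats <- lapply(trials(training), function(X)
    .trialStats(X[, seq_len(wmax), drop = FALSE], Y, windows))

  acc <- numeric(length(windows))
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    flat <- .flattenStats(stats, wi)
    # full per-class banks (first canonical pair is all the features need)
    banks <- vector("list", C)
    for (cl in seq_len(C)) {
      sc <- .pooledScatter(stats[labs == cl], wi, w, ref)
      banks[[cl]] <- .ccaCore(sc$Sxx, sc$Sxy, sc$Syy, df = sc$Ttot - 1)
    }
    F0 <- vapply(banks, function(fit)
      .featuresBatch(flat, wi, w, ref, fit$A[, 1L], fit$B[, 1L]), numeric(n))
    if (leak) {
      model <- trainLDA(F0, labs)
      acc[wi] <- mean(ldaClassify(model, F0) == labs)
      next
    }
    correct <- 0L
    for (i in seq_len(n)) {
      ci <- labs[i]
      keep <- setdiff(which(labs == ci), i)
      sc <- .pooledScatter(stats[keep], wi, w, ref)
      fit <- .ccaCore(sc$Sxx, sc$Sxy, sc$Syy, df = sc$Ttot - 1)
      Fi <- F0
      Fi[, ci] <- .featuresBatch(flat, wi, w, ref, fit$A[, 1L], fit$B[, 1L])
      model <- trainLDA(Fi[-i, , drop = FALSE], labs[-i])
      if (ldaClassify(model, Fi[i, ]) == ci) correct <- correct + 1L
    }
    acc[wi] <- correct / n
  }
  acc
}

#' Leave-one-trial-out cross-validated accuracy
#'
#' For each trial, the class-specific CCA filter bank of its class and all LDA
#' training features are rebuilt with that trial excluded, the trial is
#' classified, and the fraction correct is returned. The held-out trial
#' contributes to neither the spatial filters nor the classifier, so there is
#' no leakage.
#'
#' @param training a [TrialSet-class] (already band-pass filtered).
#' @param windowLen window length in samples.
#' @param fStim stimulation frequency in Hz.
#' @param nComponents canonical pairs kept in the bank.
#' @return Accuracy in `[0, 1]`.
#' @export
looAccuracy <- function(training, windowLen, fStim = 60, nComponents = 2) {
  .looMulti(training, windowLen, fStim, nComponents)[1]
}

#' Optimal fixed window length
#'
#' Evaluates `itr(looAccuracy(w), C, w)` over a grid of window lengths and
#' returns the ITR-maximising one; ties resolve to the shortest window (ITR
#' is inversely proportional to T at fixed accuracy, so shorter is the
#' conservative choice).
#'
#' @param training a filtered [TrialSet-class].
#' @param windows numeric grid of window lengths in seconds.
#' @param fStim stimulation frequency in Hz.
#' @return List with `Tstar` (seconds) and `table` (data.frame of window,
#'   accuracy, itr).
#' @export
optimalFixedWindow <- function(training, windows, fStim = 60) {
  if (!length(windows)) stop("empty window grid")
  fs <- sampleRate(training)
  windows <- sort(as.numeric(windows))
  ws <- as.integer(round(windows * fs))
  G <- .looMulti(training, ws, fStim)
  tab <- data.frame(window = windows, accuracy = G,
                    itr = itr(pmax(G, 1e-12), nClasses(training), windows))
  best <- order(-tab$itr, tab$window)[1]
  list(Tstar = tab$window[best], table = tab)
}

#' Narrow-band SNR at the stimulation frequency
#'
#' Ratio of periodogram power at the stimulation frequency to the mean power
#' of the 0.25 Hz-spaced bins from 1.25 Hz below to 1.25 Hz above it,
#' excluding the stimulation bin itself (10 noise bins at exact resolution).
#' The recording is zero-padded to the next 4-second multiple so the bins
#' align with the 0.25 Hz grid; recordings shorter than 4 s warn that the
#' true spectral resolution is degraded. Powers are averaged over channels
#' before the ratio is formed.
#'
#' @param recording a [Recording-class] or channels x samples matrix.
#' @param fStim stimulation frequency in Hz (default 60).
#' @param fs sampling rate; taken from the recording when available.
#' @param channels optional subset of channel indices to average over.
#' @return An [SNREstimate-class].
#' @export
snr60Hz <- function(recording, fStim = 60, fs = NULL, channels = NULL) {
  X <- .asSignal(recording)
  if (is(recording, "Recording")) fs <- sampleRate(recording)
  if (is.null(fs)) stop("fs is required for a bare matrix")
  if (!is.null(channels)) X <- X[channels, , drop = FALSE]
  n <- ncol(X)
  if (fStim + 1.25 >= fs / 2) stop("analysis band exceeds Nyquist")
  block <- round(4 * fs)
  if (n < block)
    warning("recording shorter than 4 s: 0.25 Hz resolution is nominal only")
  nfft <- as.integer(block * ceiling(n / block))
  res <- fs / nfft
  freqs <- fStim + seq(-1.25, 1.25, by = 0.25)
  bins <- round(freqs / res) + 1L          # 1-based fft indices
  stimBin <- round(fStim / res) + 1L
  noiseBins <- setdiff(bins, stimBin)
  P <- matrix(0, nrow(X), length(bins))
  for (ch in seq_len(nrow(X))) {
    spec <- stats::fft(c(X[ch, ], numeric(nfft - n)))
    P[ch, ] <- Mod(spec[bins])^2
  }
  sig <- mean(P[, bins == stimBin])
  noi <- mean(P[, bins != stimBin])
  new("SNREstimate", signalPower = sig, noisePower = noi,
      snr = sig / noi, resolution = res)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation with the two-sided t-distributed p-value, as
#' used to relate per-subject SSVEP response strength to ITR.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with `r` and `p`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cohort summary statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1) of every numeric
#' column of a per-subject results table, as in a cohort performance table's
#' Mean / Std. dev. rows.
#'
#' @param results data.frame with one row per subject.
#' @return data.frame with rows `mean` and `sd` over the numeric columns.
#' @examples
#' cohortSummary(data.frame(itr = c(50, 80, 110)))
#' @export
cohortSummary <- function(results) {
  if (nrow(results) < 2) stop("need at least 2 subjects")
  num <- vapply(results, is.numeric, logical(1))
  m <- vapply(results[num], mean, numeric(1))
  s <- vapply(results[num], stats::sd, numeric(1))
  out <- rbind(mean = m, sd = s)
  as.data.frame(out)
}

#' Grid search over the stopping parameters N and P
#'
#' Simulates dynamic stopping playback for every (N, P) combination and scores
#' it by ITR. By default the search is cross-validated over sequences (models
#' trained on the other folds, playback on the held-out fold) to avoid the
#' optimism of tuning and evaluating on the same trials; `folds = 1` evaluates
#' on the training data directly. Because the per-chunk (label, posterior)
#' trace does not depend on N or P, each trial is evaluated once and the
#' stopping rule is replayed over the trace for every grid point. Ties resolve
#' to the larger N, then the larger P (the more conservative rule).
#'
#' @param training a raw (unfiltered) [TrialSet-class].
#' @param Ngrid integer grid for N (default 1..5).
#' @param Pgrid numeric grid for P (default 0.5..0.99).
#' @param base a [StopConfig-class] providing chunking, windows and flags.
#' @param coeffs FIR coefficients from [designBandpass()].
#' @param folds number of cross-validation folds over sequences (default 5).
#' @param fStim stimulation frequency in Hz.
#' @return List with `N`, `P` and `surface` (data.frame of N, P, accuracy,
#'   mean stop time and ITR).
#' @export
gridSearchNP <- function(training, Ngrid = 1:5,
                         Pgrid = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99),
                         base = stopConfig(fSample = sampleRate(training)),
                         coeffs = designBandpass(66, fs = sampleRate(training)),
                         folds = 5, fStim = 60) {
  if (!length(Ngrid) || !length(Pgrid)) stop("empty N or P grid")
  if (base@maxWindow > nSamples(training))
    stop("maxWindow exceeds the trial length")
  C <- nClasses(training)
  n <- nTrials(training)
  seqIdx <- (seq_len(n) - 1L) %/% C + 1L
  nSeq <- max(seqIdx)
  folds <- min(folds, nSeq)
  foldOf <- ((seqIdx - 1L) %% folds) + 1L
  labs <- trialLabels(training)

  traces <- vector("list", n)
  for (fd in seq_len(folds)) {
    test <- which(foldOf == fd)
    train <- if (folds == 1) seq_len(n) else which(foldOf != fd)
    cache <- buildModelCache(training[train], base, coeffs, fStim = fStim)
    for (i in test)
      traces[[i]] <- .fullTrace(trials(training)[[i]], cache)
  }

  grid <- expand.grid(N = as.integer(Ngrid), P = as.numeric(Pgrid))
  out <- lapply(seq_len(nrow(grid)), function(g) {
    N <- grid$N[g]; P <- grid$P[g]
    hit <- logical(n); tsec <- numeric(n); used <- logical(n)
    for (i in seq_len(n)) {
      tr <- traces[[i]]
      st <- applyStopRule(tr$label, tr$posterior, N, P,
                          holdOnWeak = base@holdOnWeak)
      forced <- is.na(st)
      if (forced) st <- nrow(tr)
      hit[i] <- tr$label[st] == labs[i]
      tsec[i] <- tr$window[st] / sampleRate(training)
      used[i] <- !forced || base@includeForced
    }
    G <- mean(hit[used])
    Tm <- mean(tsec) + base@gapSeconds
    data.frame(N = N, P = P, accuracy = G, meanTime = Tm,
               itr = itr(max(G, 1e-12), C, Tm))
  })
  surface <- do.call(rbind, out)
  best <- order(-surface$itr, -surface$N, -surface$P)[1]
  list(N = surface$N[best], P = surface$P[best], surface = surface)
}

#' Bundled cohort benchmark table
#'
#' Published per-subject online results of a 14-subject spatially-coded SSVEP
#' BCI study with dynamic stopping: mean classification time, online and
#' offline accuracy, and ITR. Used by the acceptance machinery to recompute
#' the cohort aggregates.
#'
#' @return data.frame with columns `subject`, `classif_time_s`, `acc_online`,
#'   `acc_offline`, `itr_bits_min`.
#' @export
dsCohortResults <- function() {
  utils::read.csv(system.file("extdata", "ds_cohort.csv",
                              package = "ssvepDS"))
}

#' Bundled cross-study ITR comparison table
#'
#' Reported fixed-length and dynamic-length ITRs (bits/min) of related
#' dynamic stopping studies and of the spatially-coded study this package
#' implements (row `this_study`).
#'
#' @return data.frame with columns `study`, `itr_fixed`, `itr_dynamic`.
#' @export
relatedStudiesITR <- function() {
  utils::read.csv(system.file("extdata", "related_studies.csv",
                              package = "ssvepDS"))
}
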