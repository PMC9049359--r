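#' Sinusoidal CCA reference signal
#'
#' The 2 x n reference `[sin(2*pi*fStim*t); cos(2*pi*fStim*t)]` with
#' `t = 0, 1/fSample, 2/fSample, ...`. The two quadrature rows let the CCA
#' reference filter absorb any fixed response phase.
#'
#' @param fStim stimulation frequency in Hz (below Nyquist).
#' @param fSample sampling rate in Hz.
#' @param nSamples number of samples (>= 2).
#' @return 2 x nSamples matrix with rows `sin` and `cos`.
#' @examples
#' makeReference(60, 2048, 4)[, 1]  # t = 0: sin 0, cos 1
#' @export
makeReference <- function(fStim, fSample, nSamples) {
  if (fStim >= fSample / 2) stop("fStim must be below the Nyquist frequency")
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("nSamples must be >= 1")
  t <- (seq_len(nSamples) - 1) / fSample
  rbind(sin = sin(2 * pi * fStim * t), cos = cos(2 * pi * fStim * t))
}

# --- sufficient-statistics machinery -------------------------------------
#
# All CCA fits in this package are solved from centered scatter matrices
#   Sxx = X Xt - sx sxt / w,  Sxy = X Yt - sx syt / w,  Syy = Y Yt - sy syt / w
# accumulated per trial and per window length. This makes per-window-length
# retraining and leave-one-trial-out refits cheap: removing a trial is a
# subtraction, and each refit costs O(L^3) instead of a pass over the data.

# Solve CCA from scatter matrices. Returns A (L x K), B (2 x K) and the
# canonical correlations (descending, clamped to [0, 1]). Projections through
# A and B have unit variance w.r.t. the scatter normalisation (w - 1).
.ccaCore <- function(Sxx, Sxy, Syy, df) {
  Cxx <- Sxx / df; Cxy <- Sxy / df; Cyy <- Syy / df
  ex <- eigen(Cxx, symmetric = TRUE)
  tolx <- max(ex$values) * 1e-10
  keep <- ex$values > tolx
  rankDef <- !all(keep)
  Ux <- ex$vectors[, keep, drop = FALSE]
  Wx <- sweep(Ux, 2, sqrt(ex$values[keep]), "/")   # whitener: Wx' Cxx Wx = I
  ey <- eigen(Cyy, symmetric = TRUE)
  keepy <- ey$values > max(ey$values) * 1e-10
  rankDef <- rankDef || !all(keepy)
  Uy <- ey$vectors[, keepy, drop = FALSE]
  Wy <- sweep(Uy, 2, sqrt(ey$values[keepy]), "/")
  M <- t(Wx) %*% Cxy %*% Wy
  sv <- svd(M)
  K <- min(dim(M))
  r <- pmin(pmax(sv$d[seq_len(K)], 0), 1)
  list(A = Wx %*% sv$u[, seq_len(K), drop = FALSE],
       B = Wy %*% sv$v[, seq_len(K), drop = FALSE],
       cor = r, rankDeficient = rankDef)
}

# Per-trial cumulative statistics at a set of window lengths.
# X: channels x samples (already filtered); Y: 2 x >=max(windows) reference.
# Returns list with G (L x L x nw), Cxy (L x 2 x nw), sx (L x nw).
.trialStats <- function(X, Y, windows) {
  L <- nrow(X); nw <- length(windows)
  G <- array(0, c(L, L, nw)); Cxy <- array(0, c(L, 2, nw))
  sx <- matrix(0, L, nw)
  g <- matrix(0, L, L); cxy <- matrix(0, L, 2); s <- numeric(L)
  prev <- 0L
  for (i in seq_len(nw)) {
    w <- windows[i]
    idx <- (prev + 1L):w
    Xb <- X[, idx, drop = FALSE]
    Yb <- Y[, idx, drop = FALSE]
    g <- g + tcrossprod(Xb)
    cxy <- cxy + tcrossprod(Xb, Yb)
    s <- s + rowSums(Xb)
    G[, , i] <- g; Cxy[, , i] <- cxy; sx[, i] <- s
    prev <- w
  }
  list(G = G, Cxy = Cxy, sx = sx)
}

# Reference-side cumulative statistics (shared by all trials).
.refStats <- function(Y, windows) {
  nw <- length(windows)
  Gy <- array(0, c(2, 2, nw)); sy <- matrix(0, 2, nw)
  g <- matrix(0, 2, 2); s <- numeric(2)
  prev <- 0L
  for (i in seq_len(nw)) {
    idx <- (prev + 1L):windows[i]
    Yb <- Y[, idx, drop = FALSE]
    g <- g + tcrossprod(Yb); s <- s + rowSums(Yb)
    Gy[, , i] <- g; sy[, i] <- s
    prev <- windows[i]
  }
  list(Gy = Gy, sy = sy)
}

# Pool per-trial stats (a list of .trialStats results restricted to window
# index wi) into centered scatter matrices for the concatenation of those
# trials, with the reference restarted at t = 0 for every trial.
.pooledScatter <- function(statList, wi, w, ref) {
  nT <- length(statList)
  L <- nrow(statList[[1]]$sx)
  G <- matrix(0, L, L); Cxy <- matrix(0, L, 2); sx <- numeric(L)
  for (st in statList) {
    G <- G + st$G[, , wi]
    Cxy <- Cxy + st$Cxy[, , wi]
    sx <- sx + st$sx[, wi]
  }
  Gy <- nT * ref$Gy[, , wi]
  sy <- nT * ref$sy[, wi]
  Ttot <- nT * w
  list(Sxx = G - tcrossprod(sx) / Ttot,
       Sxy = Cxy - tcrossprod(sx, sy) / Ttot,
       Syy = Gy - tcrossprod(sy) / Ttot,
       Ttot = Ttot)
}

# Flatten the per-trial statistics at window index wi into matrices suited
# for batch quadratic forms: G as L^2 x n, Cxy as 2L x n, sx as L x n.
.flattenStats <- function(statList, wi) {
  n <- length(statList)
  L <- nrow(statList[[1]]$sx)
  list(
    G = vapply(statList, function(st) as.numeric(st$G[, , wi]),
               numeric(L * L)),
    Cxy = vapply(statList, function(st) as.numeric(st$Cxy[, , wi]),
                 numeric(L * 2L)),
    sx = vapply(statList, function(st) st$sx[, wi], numeric(L)))
}

# First-canonical-pair |correlation| for every trial at once, from flattened
# statistics. Equivalent to looping .featureFromStats over trials.
.featuresBatch <- function(flat, wi, w, ref, a, b) {
  sy <- ref$sy[, wi]
  vb <- drop(t(b) %*% (ref$Gy[, , wi] - tcrossprod(sy) / w) %*% b)
  sxa <- drop(crossprod(flat$sx, a))
  va <- drop(crossprod(flat$G, as.numeric(tcrossprod(a)))) - sxa^2 / w
  cv <- drop(crossprod(flat$Cxy, as.numeric(a %o% b))) -
    sxa * drop(crossprod(sy, b)) / w
  ok <- va > 0 & vb > 0
  f <- numeric(length(va))
  f[ok] <- pmin(abs(cv[ok]) / sqrt(va[ok] * vb), 1)
  f
}

# Correlation of the first canonical projections for one trial at window
# index wi, from its sufficient statistics (per-window centering).
.featureFromStats <- function(st, wi, w, ref, a, b) {
  sx <- st$sx[, wi]
  sy <- ref$sy[, wi]
  va <- drop(t(a) %*% (st$G[, , wi] - tcrossprod(sx) / w) %*% a)
  vb <- drop(t(b) %*% (ref$Gy[, , wi] - tcrossprod(sy) / w) %*% b)
  cv <- drop(t(a) %*% (st$Cxy[, , wi] - tcrossprod(sx, sy) / w) %*% b)
  if (va <= 0 || vb <= 0) return(0)
  min(abs(cv) / sqrt(va * vb), 1)
}

#' Solve the canonical correlation problem
#'
#' Finds projections `A` of the multichannel signal and `B` of the sinusoidal
#' reference maximising the correlation of the projected time courses. Both
#' inputs are centered internally. Up to `K = 2` canonical pairs are returned
#' (the reference has two rows), with correlations sorted descending in
#' `[0, 1]` and unit-variance projections. Rank-deficient inputs reduce K with
#' a warning.
#'
#' @param X L x T signal matrix (or [Recording-class]).
#' @param Y 2 x T reference from [makeReference()].
#' @return List with `A` (L x K), `B` (2 x K) and `cor` (length K).
#' @examples
#' Y <- makeReference(60, 512, 512)
#' out <- solveCCA(Y + 0, Y)   # self-correlation: cor = c(1, 1)
#' @export
solveCCA <- function(X, Y) {
  X <- .asSignal(X)
  if (!is.matrix(Y)) stop("Y must be a matrix")
  Tn <- ncol(X)
  if (ncol(Y) != Tn) stop("X and Y must have the same number of samples")
  if (Tn <= nrow(X) + nrow(Y))
    stop(sprintf("too few samples (%d) for %d + %d variables",
                 Tn, nrow(X), nrow(Y)))
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  out <- .ccaCore(tcrossprod(Xc), tcrossprod(Xc, Yc), tcrossprod(Yc),
                  df = Tn - 1)
  if (out$rankDeficient)
    warning("rank-deficient input: returning a reduced number of canonical pairs")
  out[c("A", "B", "cor")]
}

#' Train the class-specific CCA filter bank
#'
#' For each class, the training trials of that class are trimmed to the first
#' `windowLen` samples and concatenated along time, and CCA is solved against
#' the sinusoidal reference (restarted at `t = 0` for each trial, exactly as a
#' test window is referenced). The resulting per-class filters are fixed; they
#' are never re-solved on test data.
#'
#' @param training a [TrialSet-class] (normally already band-pass filtered).
#' @param windowLen window length in samples (<= trial length).
#' @param fStim stimulation frequency in Hz.
#' @param nComponents number of canonical pairs to keep (1 or 2; the feature
#'   vector uses the first).
#' @return A [CCAFilterBank-class].
#' @export
trainFilterBank <- function(training, windowLen, fStim = 60,
                            nComponents = 2) {
  windowLen <- as.integer(windowLen)
  if (windowLen > nSamples(training))
    stop("windowLen exceeds the trial length")
  C <- nClasses(training)
  labs <- trialLabels(training)
  if (!all(seq_len(C) %in% labs)) stop("every class needs training trials")
  if (any(tabulate(labs, C) < 2L)) stop("every class needs >= 2 trials")
  fs <- sampleRate(training)
  Y <- makeReference(fStim, fs, windowLen)
  ref <- .refStats(Y, windowLen)
  stats <- lapply(trials(training), function(X)
    .trialStats(X[, seq_len(windowLen), drop = FALSE], Y, windowLen))
  A <- vector("list", C); B <- vector("list", C); cors <- vector("list", C)
  for (cl in seq_len(C)) {
    sc <- .pooledScatter(stats[labs == cl], 1L, windowLen, ref)
    fit <- .ccaCore(sc$Sxx, sc$Sxy, sc$Syy, df = sc$Ttot - 1)
    K <- min(nComponents, length(fit$cor))
    A[[cl]] <- fit$A[, seq_len(K), drop = FALSE]
    B[[cl]] <- fit$B[, seq_len(K), drop = FALSE]
    cors[[cl]] <- fit$cor[seq_len(K)]
  }
  new("CCAFilterBank", A = A, B = B, cors = cors, windowLen = windowLen,
      fStim = fStim, fSample = fs, nComponents = as.integer(nComponents))
}

#' Extract the CCA feature vector of a window
#'
#' Projects the window through each class's fixed spatial filter and the
#' regenerated reference through the class's reference filter, and records the
#' absolute correlation of the first canonical pair. The feature vector has
#' one entry per class; the attended class should produce the largest value.
#' Degenerate windows (zero variance after filtering) yield a 0 feature with
#' a warning rather than NaN.
#'
#' @param X L x w window (or [Recording-class]); `w` must equal the bank's
#'   trained window length.
#' @param bank a [CCAFilterBank-class].
#' @return Numeric feature vector of length C, values in `[0, 1]`.
#' @export
extractFeatures <- function(X, bank) {
  X <- .asSignal(X)
  w <- ncol(X)
  if (w != bank@windowLen)
    stop(sprintf("window length %d does not match the bank's %d samples",
                 w, bank@windowLen))
  if (anyNA(X)) stop("NaN/NA in input window")
  Y <- makeReference(bank@fStim, bank@fSample, w)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  C <- length(bank@A)
  f <- numeric(C)
  degenerate <- FALSE
  for (cl in seq_len(C)) {
    px <- drop(crossprod(bank@A[[cl]][, 1L], Xc))
    py <- drop(crossprod(bank@B[[cl]][, 1L], Yc))
    vx <- sum(px^2); vy <- sum(py^2)
    if (vx <= 0 || vy <= 0) {
      degenerate <- TRUE
      f[cl] <- 0
    } else {
      f[cl] <- min(abs(sum(px * py)) / sqrt(vx * vy), 1)
    }
  }
  if (degenerate)
    warning("degenerate (zero-variance) window: feature set to 0")
  f
}
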