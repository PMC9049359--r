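#' Design the band-pass FIR filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass of even order, returning
#' `order + 1` symmetric coefficients. The default 55-65 Hz band isolates the
#' 60 Hz stimulation frequency; order 66 is the operating point that trades
#' filter sharpness against the shortest classifiable window (the zero-phase
#' application needs windows longer than the filter).
#'
#' Note on selectivity: at fs = 2048 Hz a 67-tap filter has a wide transition
#' band, so attenuation close to the pass band is mild; deep (> 20 dB)
#' suppression at 45/75 Hz requires orders of several hundred. The pipeline
#' relies on the CCA reference for the fine frequency selectivity and uses
#' this filter to reject out-of-band power.
#'
#' @param order filter order (even, >= 2).
#' @param band pass band `c(low, high)` in Hz, default `c(55, 65)`.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of `order + 1` coefficients, with attributes
#'   `order`, `band` and `fs`.
#' @examples
#' h <- designBandpass(66, c(55, 65), 2048)
#' length(h)
#' @export
designBandpass <- function(order, band = c(55, 65), fs = 2048) {
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L)
    stop("order must be an even integer >= 2")
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2")
  h <- signal::fir1(order, band / (fs / 2), type = "pass")
  h <- as.numeric(h)
  attr(h, "order") <- order
  attr(h, "band") <- band
  attr(h, "fs") <- fs
  h
}

#' Frequency response of an FIR filter
#'
#' Magnitude of the transfer function on a frequency grid; the zero-phase
#' (forward-backward) application realises the squared magnitude.
#'
#' @param coeffs FIR coefficients.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz (defaults to the `fs` attribute of `coeffs`).
#' @param zeroPhase if TRUE return the forward-backward magnitude `|H|^2`.
#' @return Numeric vector of magnitudes.
#' @export
filterResponse <- function(coeffs, freqs, fs = attr(coeffs, "fs"),
                           zeroPhase = FALSE) {
  if (is.null(fs)) stop("fs is required")
  k <- seq_along(coeffs) - 1
  H <- vapply(freqs, function(f)
    Mod(sum(coeffs * exp(-2i * pi * f * k / fs))), numeric(1))
  if (zeroPhase) H^2 else H
}

#' Apply a zero-phase band-pass filter
#'
#' Forward-backward application of the linear-phase FIR: each channel is
#' reflection-padded by the filter length at both ends, convolved with the
#' filter twice (once time-reversed), and trimmed back to the input length.
#' The net phase shift is zero at every frequency and the effective magnitude
#' response is the squared single-pass response. Channels are filtered
#' independently and the output has the same shape as the input.
#'
#' @param coeffs FIR coefficients from [designBandpass()].
#' @param recording a [Recording-class] or channels x samples matrix.
#' @return Same class as the input, filtered.
#' @examples
#' h <- designBandpass(66, c(55, 65), 2048)
#' t <- (0:999) / 2048
#' x <- rbind(sin(2 * pi * 60 * t))
#' y <- applyZeroPhase(h, x)
#' @export
applyZeroPhase <- function(coeffs, recording) {
  X <- .asSignal(recording)
  lh <- length(coeffs)
  n <- ncol(X)
  if (n <= lh)
    stop(sprintf("window too short: %d samples <= filter length %d", n, lh))
  # mirror-reflect lh samples at each end to suppress edge transients
  pad <- cbind(X[, lh:1, drop = FALSE], X, X[, n:(n - lh + 1), drop = FALSE])
  # forward-backward pass == centered convolution with conv(h, rev(h));
  # h is symmetric so this is the autocorrelation of h (length 2*lh - 1)
  g <- stats::convolve(coeffs, coeffs, type = "open")
  np <- ncol(pad)
  nfft <- stats::nextn(np + length(g) - 1L, c(2, 3, 5))
  Gf <- stats::fft(c(g, numeric(nfft - length(g))))
  P <- rbind(t(pad), matrix(0, nfft - np, nrow(X)))
  Y <- Re(stats::mvfft(stats::mvfft(P) * Gf, inverse = TRUE)) / nfft
  # centered alignment: total delay of the symmetric kernel is lh - 1 samples
  out <- t(Y[(lh - 1L + lh + 1L):(lh - 1L + lh + n), , drop = FALSE])
  if (is(recording, "Recording")) {
    recording@data <- out
    recording
  } else out
}

#' Grid search over the FIR filter order
#'
#' For each candidate order, runs the full offline pipeline on the training
#' data (zero-phase filtering, class-specific CCA filter banks, LDA,
#' leave-one-trial-out accuracy at `evalWindow`) and scores it by information
#' transfer rate. Returns the ITR-maximising order; ties are broken toward the
#' lowest order, since a shorter filter permits shorter minimum windows.
#'
#' @param training a [TrialSet-class] of raw (unfiltered) trials.
#' @param orders integer vector of candidate (even) filter orders.
#' @param evalWindow evaluation window in seconds.
#' @param band pass band in Hz.
#' @param fStim stimulation frequency in Hz.
#' @return List with `bestOrder` and `table` (a data.frame of order, accuracy
#'   and ITR in bits/min).
#' @export
searchFilterOrder <- function(training, orders, evalWindow = 1,
                              band = c(55, 65), fStim = 60) {
  orders <- as.integer(orders)
  if (!length(orders)) stop("empty order grid")
  fs <- sampleRate(training)
  w <- round(evalWindow * fs)
  if (w > nSamples(training))
    stop("evalWindow exceeds the trial length")
  if (any(orders + 1 >= w))
    stop("grid contains orders too long for the evaluation window")
  res <- lapply(orders, function(ord) {
    h <- designBandpass(ord, band, fs)
    filt <- filterTrials(h, training)
    G <- looAccuracy(filt, w, fStim = fStim)
    data.frame(order = ord, accuracy = G,
               itr = itr(G, nClasses(training), evalWindow))
  })
  tab <- do.call(rbind, res)
  best <- tab$order[order(-tab$itr, tab$order)][1]
  list(bestOrder = best, table = tab)
}

#' Filter every trial of a TrialSet
#'
#' Convenience wrapper applying [applyZeroPhase()] to each trial.
#'
#' @param coeffs FIR coefficients.
#' @param training a [TrialSet-class].
#' @return The filtered [TrialSet-class].
#' @export
filterTrials <- function(coeffs, training) {
  training@trials <- lapply(training@trials,
                            function(t) applyZeroPhase(coeffs, t))
  training
}
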