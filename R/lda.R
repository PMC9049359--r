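#' Train the Gaussian linear discriminant classifier
#'
#' Estimates per-class centroids and the pooled within-class covariance
#' (unbiased, scatter summed over classes divided by `n - C`), with class
#' priors defaulting to uniform (the cueing protocol is balanced). If the
#' pooled covariance is ill-conditioned it is shrunk toward its diagonal,
#' `(1 - gamma) * Sigma + gamma * diag(Sigma)`, with the smallest
#' `gamma` in `{0, 1e-4, 1e-2, 1e-1}` that brings the condition number below
#' `1e8`; a zero-variance feature dimension additionally gets a tiny ridge and
#' a warning.
#'
#' @param features n x d matrix of feature vectors (rows are samples).
#' @param labels integer class labels in `1..C`.
#' @param priors optional class priors (non-negative, normalised internally);
#'   default uniform.
#' @return An [LDAModel-class].
#' @examples
#' f <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20) + 3, 10))
#' m <- trainLDA(f, rep(1:2, each = 10))
#' ldaClassify(m, c(3, 3))
#' @export
trainLDA <- function(features, labels, priors = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features); d <- ncol(features)
  C <- max(labels)
  if (any(tabulate(labels, C) < 2L))
    stop("every class needs >= 2 samples")
  if (n < d + 1L) stop("need more samples than feature dimensions")
  mu <- matrix(0, C, d)
  S <- matrix(0, d, d)
  for (cl in seq_len(C)) {
    Fc <- features[labels == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(Fc)
    Xc <- sweep(Fc, 2, mu[cl, ])
    S <- S + crossprod(Xc)
  }
  Sigma <- S / (n - C)
  if (any(diag(Sigma) <= 0)) {
    warning("zero-variance feature dimension: adding a small ridge")
    diag(Sigma) <- diag(Sigma) + max(diag(Sigma), 1) * 1e-8
  }
  gamma <- 0
  for (g in c(0, 1e-4, 1e-2, 1e-1)) {
    gamma <- g
    Sg <- (1 - g) * Sigma + g * diag(diag(Sigma), d)
    ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < 1e8) break
  }
  if (gamma > 0) Sigma <- (1 - gamma) * Sigma + gamma * diag(diag(Sigma), d)
  if (is.null(priors)) priors <- rep(1 / C, C)
  priors <- priors / sum(priors)
  new("LDAModel", means = mu, covariance = Sigma, priors = priors,
      gamma = gamma)
}

# log class-conditional densities up to the shared Gaussian constant
.ldaLogDens <- function(model, F) {
  R <- chol(model@covariance)
  C <- nrow(model@means)
  out <- matrix(0, nrow(F), C)
  for (cl in seq_len(C)) {
    z <- backsolve(R, t(sweep(F, 2, model@means[cl, ])), transpose = TRUE)
    out[, cl] <- -0.5 * colSums(z^2) + log(model@priors[cl])
  }
  out
}

#' Class posterior probabilities
#'
#' Bayes' rule over equal-covariance Gaussian class conditionals: the shared
#' normalising constant cancels and the computation runs in log space with a
#' log-sum-exp reduction, so posteriors are exact to machine precision and sum
#' to 1.
#'
#' @param model an [LDAModel-class].
#' @param f a feature vector of length d, or an n x d matrix of vectors.
#' @return Posterior matrix (n x C); a vector input gives a length-C vector.
#' @export
ldaPosterior <- function(model, f) {
  single <- is.null(dim(f))
  F <- if (single) matrix(f, nrow = 1) else as.matrix(f)
  if (ncol(F) != ncol(model@means))
    stop("feature dimension does not match the model")
  if (any(!is.finite(F))) stop("NaN/Inf in feature vector")
  ld <- .ldaLogDens(model, F)
  m <- apply(ld, 1, max)
  p <- exp(ld - m)
  p <- p / rowSums(p)
  if (single) drop(p) else p
}

#' Classify a feature vector
#'
#' Maximum-posterior classification; exact ties resolve to the lowest class
#' index.
#'
#' @inheritParams ldaPosterior
#' @return Integer class index (vector for matrix input).
#' @export
ldaClassify <- function(model, f) {
  p <- ldaPosterior(model, f)
  if (is.null(dim(p))) which.max(p) else apply(p, 1, which.max)
}
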