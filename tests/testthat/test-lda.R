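test_that("LDA estimates centroids and pooled covariance correctly", {
  set.seed(1)
  f <- matrix(c(rnorm(200, 0), rnorm(200, 10)), ncol = 1)
  lab <- rep(1:2, each = 200)
  m <- trainLDA(f, lab)
  expect_equal(classMeans(m)[, 1], c(0, 10), tolerance = 0.2)

  # duplicating every sample leaves the model unchanged up to the
  # (n - C) vs (2n - C) unbiased-pooling factor
  m2 <- trainLDA(rbind(f, f), c(lab, lab))
  expect_equal(classMeans(m2), classMeans(m), tolerance = 1e-12)
  expect_equal(pooledCovariance(m2) * (2 * 400 - 2) / 2,
               pooledCovariance(m) * (400 - 2), tolerance = 1e-10)

  # hand-computed pooled covariance on 6 fixed points, 2 classes in 2-D
  pts <- rbind(c(0, 0), c(2, 0), c(1, 3),   # class 1, mean (1, 1)
               c(4, 4), c(6, 4), c(5, 7))   # class 2, mean (5, 5)
  scatter1 <- rbind(c(2, 0), c(0, 6))       # both classes share this scatter
  expected <- (scatter1 + scatter1) / (6 - 2)
  mh <- trainLDA(pts, c(1, 1, 1, 2, 2, 2))
  expect_equal(pooledCovariance(mh), expected, tolerance = 1e-10)

  expect_error(trainLDA(pts, c(1, 1, 1, 1, 1, 2)), ">= 2 samples")
})

test_that("posteriors are normalised, symmetric and logistic in 1-D", {
  m <- new("LDAModel", means = matrix(c(1, -1), 2, 1),
           covariance = matrix(1, 1, 1), priors = c(0.5, 0.5), gamma = 0)
  # closed-form logistic value at f = 0.5
  expect_equal(ldaPosterior(m, 0.5)[1], 1 / (1 + exp(-2 * 0.5)),
               tolerance = 1e-12)
  # equidistant point: exact symmetry
  expect_equal(ldaPosterior(m, 0), c(0.5, 0.5), tolerance = 1e-12)
  # normalisation
  set.seed(2)
  P <- ldaPosterior(m, matrix(rnorm(50), 50, 1))
  expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-12)
  expect_error(ldaPosterior(m, NaN), "NaN")
})

test_that("argmax classification matches direct density evaluation", {
  set.seed(3)
  d <- 3
  mu <- matrix(rnorm(4 * d, sd = 2), 4, d)
  A <- matrix(rnorm(d * d), d); Sigma <- crossprod(A) + diag(d)
  m <- new("LDAModel", means = mu, covariance = Sigma,
           priors = rep(0.25, 4), gamma = 0)
  dens <- function(f, cl) {
    z <- f - mu[cl, ]
    exp(-0.5 * drop(z %*% solve(Sigma, z))) /
      sqrt((2 * pi)^d * det(Sigma))
  }
  for (i in 1:100) {
    f <- rnorm(d, sd = 3)
    direct <- vapply(1:4, dens, numeric(1), f = f)
    expect_equal(ldaClassify(m, f), which.max(direct))
    expect_equal(ldaPosterior(m, f), direct / sum(direct), tolerance = 1e-9)
  }

  # exact tie resolves to the lowest class index
  mt <- new("LDAModel", means = matrix(c(1, -1), 2, 1),
            covariance = matrix(1, 1, 1), priors = c(0.5, 0.5), gamma = 0)
  expect_equal(ldaClassify(mt, 0), 1L)
})

test_that("accuracy approaches the Bayes rate as training grows", {
  set.seed(4)
  gen <- function(n) {
    lab <- rep(1:2, each = n)
    f <- matrix(rnorm(2 * n * 2), ncol = 2)
    f[lab == 2, ] <- f[lab == 2, ] + 1.2
    list(f = f, lab = lab)
  }
  test <- gen(2000)
  acc <- vapply(c(20, 200, 2000), function(n) {
    tr <- gen(n)
    mean(ldaClassify(trainLDA(tr$f, tr$lab), test$f) == test$lab)
  }, numeric(1))
  # Bayes rate for two spherical Gaussians at distance 1.2*sqrt(2)
  bayes <- pnorm(1.2 * sqrt(2) / 2)
  expect_true(all(diff(acc) > -0.02))     # monotone within sampling error
  expect_gt(acc[3], bayes - 0.02)
})
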