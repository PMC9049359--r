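test_that("the sinusoidal reference is exact", {
  Y <- makeReference(60, 2048, 1)
  expect_equal(Y[, 1], c(sin = 0, cos = 1))
  # one second at 60 Hz completes exactly 60 cycles: last-sample phase check
  Y1 <- makeReference(60, 2048, 2049)
  expect_equal(unname(Y1[1, 2049]), sin(2 * pi * 60), tolerance = 1e-9)
  # sin/cos rows orthogonal over whole cycles
  Yf <- makeReference(60, 2048, 2048)
  expect_lt(abs(sum(Yf[1, ] * Yf[2, ])) / 2048, 1e-12)
  expect_true(all(abs(Yf) <= 1))
  expect_error(makeReference(1200, 2048, 100), "Nyquist")
})

test_that("solveCCA recovers self-correlation and the white-noise null", {
  Y <- makeReference(60, 512, 1000)
  out <- suppressWarnings(solveCCA(Y + 0, Y))
  expect_equal(out$cor, c(1, 1), tolerance = 1e-9)

  set.seed(4)
  X <- matrix(rnorm(4 * 8192), 4)
  Yl <- makeReference(60, 2048, 8192)
  expect_true(all(solveCCA(X, Yl)$cor < 0.1))

  expect_error(solveCCA(matrix(rnorm(12), 3), makeReference(60, 512, 4)),
               "few samples")
})

test_that("solveCCA agrees with the brute-force direction-search oracle", {
  set.seed(11)
  Y <- makeReference(60, 512, 300)
  for (L in c(2, 3)) {
    for (rep in 1:4) {
      # random mixtures of reference plus noise give non-trivial optima
      X <- matrix(rnorm(L, sd = 0.7), L) %*% Y[1, , drop = FALSE] +
        matrix(rnorm(L, sd = 0.7), L) %*% Y[2, , drop = FALSE] +
        matrix(rnorm(L * 300), L)
      r1 <- solveCCA(X, Y)$cor[1]
      expect_equal(r1, ccaOracle(X, Y), tolerance = 1e-3)
    }
  }
})

test_that("canonical correlations are invariant to invertible channel mixing", {
  set.seed(21)
  Y <- makeReference(60, 512, 600)
  X <- matrix(rnorm(5, sd = 0.5), 5) %*% Y[1, , drop = FALSE] +
    matrix(rnorm(5 * 600), 5)
  r0 <- solveCCA(X, Y)$cor
  M <- matrix(rnorm(25), 5) + diag(5)      # invertible mixing
  r1 <- solveCCA(M %*% X, Y)$cor
  expect_equal(r0, r1, tolerance = 1e-8)
  # channel scaling too
  r2 <- solveCCA(diag(c(5, 0.1, 2, 1, 3)) %*% X, Y)$cor
  expect_equal(r0, r2, tolerance = 1e-8)
})

test_that("filter banks train on trimmed concatenations and enforce lengths", {
  clean <- noiselessSet(nPerClass = 2, duration = 1)
  bank <- trainFilterBank(clean, 256)
  expect_equal(trainedWindow(bank), 256L)
  r1 <- vapply(canonicalCors(bank), `[`, numeric(1), 1L)
  expect_equal(r1, rep(1, 5), tolerance = 1e-6)

  # extraction refuses a mismatched window
  expect_error(extractFeatures(matrix(rnorm(8 * 200), 8), bank),
               "does not match")

  # trial order within a class does not change the correlations
  sys <- smallSystem()
  perm <- order(trialLabels(sys$trainF))   # regroup trials by class
  b1 <- trainFilterBank(sys$trainF, 256)
  b2 <- trainFilterBank(sys$trainF[perm], 256)
  expect_equal(canonicalCors(b1), canonicalCors(b2), tolerance = 1e-9)
})

test_that("feature vectors peak at the attended class and stay in [0, 1]", {
  sep <- separableSet()
  bank <- trainFilterBank(sep, 512)
  for (cl in 1:5) {
    idx <- which(trialLabels(sep) == cl)[1]
    f <- extractFeatures(trials(sep)[[idx]][, 1:512], bank)
    expect_equal(which.max(f), cl)
    expect_gt(max(f), 0.4)
  }

  # all-zero window: degenerate policy returns zeros with a warning
  expect_warning(fz <- extractFeatures(matrix(0, 8, 512), bank),
                 "degenerate")
  expect_equal(fz, rep(0, 5))
  expect_error(extractFeatures(matrix(NaN, 8, 512), bank), "NaN")

  # property sweep: features bounded in [0, 1] on random windows
  set.seed(31)
  for (i in 1:200) {
    f <- extractFeatures(matrix(rnorm(8 * 512), 8), bank)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("solveCCA matches stats::cancor on well-conditioned input", {
  set.seed(41)
  X <- matrix(rnorm(6 * 400), 6)
  Y <- makeReference(60, 512, 400)
  o <- solveCCA(X, Y)
  cc <- cancor(t(X - rowMeans(X)), t(Y - rowMeans(Y)))
  expect_equal(o$cor, cc$cor, tolerance = 1e-10)
})
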