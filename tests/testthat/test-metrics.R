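test_that("the ITR formula reproduces its closed-form limits and values", {
  expect_equal(itr(1, 5, 60), log2(5), tolerance = 1e-12)      # 2.3219
  expect_equal(itr(0.2, 5, 1), 0, tolerance = 1e-12)           # chance
  expect_equal(itr(0.9, 5, 1.4), 70.84, tolerance = 0.01)
  # strictly increasing in G above chance, strictly decreasing in T
  G <- seq(0.25, 1, by = 0.05)
  expect_true(all(diff(itr(G, 5, 1)) > 0))
  expect_true(all(diff(itr(0.9, 5, c(0.5, 1, 2, 4))) < 0))
  # below chance: flagged with a warning, not clamped; the formula is convex
  # with its minimum (zero) exactly at chance, so the value is >= 0 again
  expect_warning(v <- itr(0.1, 5, 1), "below chance")
  expect_gte(v, 0)
  expect_error(itr(0.9, 1, 1), "C must")
  expect_error(itr(0.9, 5, 0), "T must")
})

test_that("leave-one-out accuracy is exact on separable data and null-calibrated", {
  sys <- smallSystem()
  clean <- filterTrials(sys$h, separableSet())
  expect_equal(suppressWarnings(looAccuracy(clean, 512)), 1)

  # permuted labels: chance within a binomial 99% interval
  sys <- smallSystem()
  perm <- sys$trainF
  set.seed(71)
  perm@labels <- sample(perm@labels)
  G <- looAccuracy(perm, 256)
  ci <- qbinom(c(0.005, 0.995), nTrials(perm), 0.2) / nTrials(perm)
  expect_gte(G, ci[1])
  expect_lte(G, ci[2])
})

test_that("deliberate leakage inflates accuracy (negative control)", {
  # a noisy, hard fixture: low SNR, few trials
  fs <- 512
  h <- designBandpass(66, c(55, 65), fs)
  ts <- filterTrials(h, simulateSession(4, 1, smallConfig(snr = 1.6, seed = 73),
                                        smallTopo()))
  honest <- ssvepDS:::.looMulti(ts, 256L)[1]
  leaky <- ssvepDS:::.looMulti(ts, 256L, leak = TRUE)[1]
  expect_gt(leaky, honest)
})

test_that("the optimal fixed window maximises ITR with shortest-window ties", {
  sys <- smallSystem()
  ofw <- optimalFixedWindow(sys$trainF, c(0.25, 0.5, 1, 1.5))
  expect_equal(ofw$Tstar, ofw$table$window[which.max(ofw$table$itr)])
  # accuracy is non-decreasing with window length (within sampling noise)
  expect_true(all(diff(ofw$table$accuracy) > -0.1))

  # single-point grid returns that point
  expect_equal(optimalFixedWindow(sys$trainF, 0.5)$Tstar, 0.5)

  # saturating accuracy: ITR ~ 1/T picks the short end by the tie-break
  clean <- filterTrials(sys$h, separableSet())
  satur <- suppressWarnings(optimalFixedWindow(clean, c(1, 1.5, 2)))
  expect_equal(satur$table$accuracy, rep(1, 3))
  expect_equal(satur$Tstar, 1)
})

test_that("narrow-band SNR matches analytic expectations", {
  fs <- 512; n <- 4 * fs
  t <- (0:(n - 1)) / fs
  a <- 0.5; sigma <- 1
  # tone at an exact 0.25 Hz bin + white noise: expected ratio
  # (a n / 2)^2 / (n sigma^2) + 1
  expected <- a^2 * n / (4 * sigma^2) + 1
  set.seed(81)
  m <- mean(vapply(1:40, function(i) {
    x <- rbind(a * sin(2 * pi * 60 * t) + rnorm(n, sd = sigma))
    snrValue(snr60Hz(x, fs = fs))
  }, numeric(1)))
  expect_gt(m, expected * 0.75)
  expect_lt(m, expected * 1.25)

  # white noise alone: flat spectrum, snr ~ 1
  mW <- mean(vapply(1:60, function(i)
    snrValue(snr60Hz(rbind(rnorm(n)), fs = fs)), numeric(1)))
  expect_gt(mW, 0.8); expect_lt(mW, 1.25)

  # doubling a strong tone quadruples the excess power (averaged draws: the
  # 10-bin noise mean has heavy ratio tails on single periodograms)
  r1 <- mean(vapply(1:20, function(i)
    snrValue(snr60Hz(rbind(10 * sin(2 * pi * 60 * t) + rnorm(n)), fs = fs)),
    numeric(1)))
  r2 <- mean(vapply(1:20, function(i)
    snrValue(snr60Hz(rbind(20 * sin(2 * pi * 60 * t) + rnorm(n)), fs = fs)),
    numeric(1)))
  expect_equal(r2 / r1, 4, tolerance = 0.25)

  expect_warning(snr60Hz(rbind(rnorm(fs)), fs = fs), "resolution")
  expect_error(snr60Hz(rbind(rnorm(n)), fs = 100), "Nyquist")
})

test_that("pearson correlation matches the direct formula", {
  x <- c(2.1, 3.5, 4.4, 5.0, 6.2, 7.7, 8.1, 9.3, 10.0, 11.4, 12.5, 13.1,
         14.8, 15.2)
  y <- 1.3 * x + c(0.4, -0.2, 0.5, -0.6, 0.1, 0.9, -0.8, 0.3, -0.1, 0.6,
                   -0.4, 0.2, -0.9, 0.7)
  out <- pearsonCor(x, y)
  # direct product-moment computation
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tHand <- rHand * sqrt(12 / (1 - rHand^2))
  expect_equal(out$r, rHand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(tHand), 12), tolerance = 1e-12)
  expect_equal(pearsonCor(x, 2 * x)$r, 1, tolerance = 1e-12)
  expect_error(pearsonCor(x, rep(1, 14)), "zero variance")
})

test_that("cohort summaries compute mean and sample sd per column", {
  d <- data.frame(a = c(3, 3, 3), b = c(1, 2, 3))
  s <- cohortSummary(d)
  expect_equal(s["mean", "a"], 3)
  expect_equal(s["sd", "a"], 0)
  expect_equal(s["sd", "b"], 1)
  expect_error(cohortSummary(d[1, , drop = FALSE]), "at least 2")
})

test_that("the (N, P) grid search scores rules by cross-validated ITR", {
  sys <- smallSystem()
  base <- stopConfig(chunkSamples = 64, fSample = 512, maxWindow = 512)
  gs <- gridSearchNP(sys$train, Ngrid = 1:2, Pgrid = c(0.5, 0.95),
                     base = base, coeffs = sys$h, folds = 2)
  expect_equal(nrow(gs$surface), 4L)
  expect_true(gs$N %in% 1:2 && gs$P %in% c(0.5, 0.95))
  # reproducible: deterministic given the same inputs
  gs2 <- gridSearchNP(sys$train, Ngrid = 1:2, Pgrid = c(0.5, 0.95),
                      base = base, coeffs = sys$h, folds = 2)
  expect_identical(gs$surface, gs2$surface)

  # degenerate grid (N = 1, P = 0): always stops at the first eligible
  # window, so mean time equals that window and ITR follows directly
  g1 <- gridSearchNP(sys$train, Ngrid = 1, Pgrid = 0,
                     base = base, coeffs = sys$h, folds = 2)
  expect_equal(g1$surface$meanTime, 128 / 512)
  expect_equal(g1$surface$itr,
               itr(max(g1$surface$accuracy, 1e-12), 5, 128 / 512))
})
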