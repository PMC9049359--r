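test_that("chunk-aligned window arithmetic matches the protocol", {
  # 4 s at 2048 Hz in 131-sample chunks: floor(8192/131) = 62 lengths
  w <- chunkWindows(131, 131, 8192)
  expect_length(w, 62L)
  expect_equal(w[1], 131L)
  expect_equal(w[62], 8122L)
  expect_true(all(diff(w) == 131L))
  expect_error(chunkWindows(131, 200, 250), "no chunk multiple")
})

test_that("the stopping rule automaton matches the brute-force oracle", {
  # spec'd hand cases
  expect_equal(applyStopRule(c(1, 1), c(0.99, 0.98), 2, 0.95), 2L)
  expect_equal(applyStopRule(c(1, 2, 2), c(0.99, 0.99, 0.99), 2, 0.95), 3L)
  # sub-threshold evaluation breaks the run
  expect_equal(applyStopRule(c(1, 1, 1), c(0.99, 0.5, 0.99), 2, 0.95), NA_integer_)
  # N = 1: pure posterior threshold; P = 0: pure stability
  expect_equal(applyStopRule(c(3, 1), c(0.2, 0.96), 1, 0.95), 2L)
  expect_equal(applyStopRule(c(1, 2, 2), c(0.1, 0.1, 0.1), 2, 0), 3L)

  # 1000 scripted random streams against the independent scan oracle
  set.seed(55)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    lab <- sample(1:3, n, replace = TRUE)
    post <- round(runif(n), 2)
    N <- sample(1:4, 1)
    P <- sample(c(0, 0.5, 0.8, 0.95), 1)
    expect_identical(applyStopRule(lab, post, N, P), stopOracle(lab, post, N, P))
  }
})

test_that("hold-on-weak keeps the agreement run alive through weak repeats", {
  lab <- c(1, 1, 1); post <- c(0.99, 0.5, 0.99)
  expect_equal(applyStopRule(lab, post, 2, 0.95, holdOnWeak = TRUE), 3L)
  # a weak different label still resets
  expect_identical(applyStopRule(c(1, 2, 1), post, 2, 0.95, holdOnWeak = TRUE),
                   NA_integer_)
})

test_that("the model cache validates its keys and refuses uncached lengths", {
  sys <- smallSystem()
  cache <- sys$cache
  expect_equal(cachedWindows(cache),
               chunkWindows(64, 67 + 1, 1024))
  for (key in as.character(cachedWindows(cache)))
    expect_equal(trainedWindow(cache@banks[[key]]), as.integer(key))
  expect_error(evaluateWindow(matrix(rnorm(8 * 100), 8), cache), "not cached")
  expect_error(buildModelCache(sys$train[1:10],
                               stopConfig(chunkSamples = 64, fSample = 512,
                                          maxWindow = 4096),
                               sys$h),
               "shorter than maxWindow")
})

test_that("evaluateWindow equals the manual pipeline composition", {
  sys <- smallSystem()
  cache <- sys$cache
  X <- trials(sys$train)[[3]][, 1:256]
  ev <- evaluateWindow(X, cache)
  Xf <- applyZeroPhase(sys$h, X)
  f <- extractFeatures(Xf, cache@banks[["256"]])
  post <- ldaPosterior(cache@ldas[["256"]], f)
  expect_equal(ev$features, f)
  expect_equal(ev$label, unname(which.max(post)))
  expect_equal(ev$posterior, unname(max(post)))
  # determinism
  expect_identical(ev, evaluateWindow(X, cache))
})

test_that("runTrial stops on agreement, forces at timeout, and traces chunks", {
  sys <- smallSystem()
  sep <- separableSet()
  sepCache <- buildModelCache(sep, sys$scfg, sys$h)
  cfgSep <- synthConfig(nChannels = 8, fSample = 512, snr = 50,
                        phaseJitter = 0.05, ampJitter = 0.05)
  rec <- simulateTrial(2, 2, cfgSep, .sepTopo(), seed = 301)
  d <- runTrial(rec, sepCache, sys$scfg)
  expect_equal(decisionLabel(d), 2L)
  expect_false(d@forced)
  # stops early, well before the 2 s timeout; the first eligible window is
  # 128 (the 67-tap filter forces skipping the 64-sample chunk), and every
  # eligible window up to the stop is evaluated exactly once
  expect_lte(d@stopWindow, 512L)
  expect_equal(stopTime(d), d@stopWindow / 512)
  expect_equal(decisionTrace(d)$window,
               chunkWindows(64, 128, d@stopWindow))
  # the trace itself satisfies the stopping rule at its last row exactly
  tr <- decisionTrace(d)
  expect_equal(applyStopRule(tr$label, tr$posterior, 2, 0.95), nrow(tr))

  # pure noise: mostly forced timeouts at the last cached window
  cfgN <- smallConfig(snr = 0, seed = 91)
  recN <- simulateTrial(1, 2, cfgN, smallTopo())
  dN <- runTrial(recN, sys$cache, stopConfig(N = 5, P = 0.999,
                                             chunkSamples = 64, fSample = 512,
                                             maxWindow = 1024))
  expect_true(dN@forced)
  expect_equal(dN@stopWindow, 1024L)

  # stream ending before the minimum window is an error
  expect_error(runTrial(list(matrix(rnorm(8 * 64), 8)), sys$cache, sys$scfg),
               "insufficient data")

  # stop windows are multiples of the chunk size
  expect_true(d@stopWindow %% 64 == 0)
})

test_that("sessions summarise accuracy, latency and ITR sensibly", {
  sys <- smallSystem()
  clean <- separableSet()
  cleanCache <- suppressWarnings(buildModelCache(clean, sys$scfg, sys$h))
  online <- separableSet(nPerClass = 2, seed = 207)
  sess <- runSession(online, cache = cleanCache, config = sys$scfg)
  expect_equal(sess$accuracy, 1)
  expect_equal(sess$nForced, 0L)
  # separable trials stop early: all well under half the 2 s timeout
  expect_true(all(vapply(sess$decisions, function(d) d@stopWindow,
                         integer(1)) <= 512L))
  expect_equal(sess$perTarget$accuracy, rep(1, 5))

  # chance behaviour at snr = 0: accuracy near 1/C, timeouts dominate
  cfgN <- smallConfig(snr = 0, seed = 92)
  noise <- simulateSession(4, 2, cfgN, smallTopo())
  sessN <- runSession(noise, cache = sys$cache,
                      config = stopConfig(N = 4, P = 0.999,
                                          chunkSamples = 64, fSample = 512,
                                          maxWindow = 1024))
  ci <- qbinom(c(0.005, 0.995), 20, 0.2) / 20
  expect_gte(sessN$accuracy, ci[1])
  expect_lte(sessN$accuracy, ci[2])
  expect_gt(sessN$nForced, 10)
})

test_that("mean stop time decreases with SNR and with laxer stopping rules", {
  sys <- smallSystem()
  times <- vapply(c(1.5, 4, 8), function(s) {
    online <- simulateSession(6, 2, smallConfig(snr = s, seed = 93),
                              smallTopo())
    runSession(online, cache = sys$cache, config = sys$scfg)$meanStopTime
  }, numeric(1))
  expect_true(all(diff(times) < 0.15))   # non-increasing within noise
  expect_lt(times[3], times[1])

  # raising P or N never shortens stopping on a fixed trial set (exact)
  online <- simulateSession(3, 2, smallConfig(snr = 3, seed = 94),
                            smallTopo())
  mst <- function(N, P)
    runSession(online, cache = sys$cache,
               config = stopConfig(N = N, P = P, chunkSamples = 64,
                                   fSample = 512,
                                   maxWindow = 1024))$meanStopTime
  expect_lte(mst(2, 0.8), mst(2, 0.95))
  expect_lte(mst(2, 0.95), mst(3, 0.95))
  expect_lte(mst(1, 0.95), mst(2, 0.95))
})
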