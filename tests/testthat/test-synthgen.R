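test_that("topographies honour orthogonality, determinism and feasibility", {
  # full separation = orthonormal basis
  topo <- makeTopographies(5, 5, minSeparation = 1, seed = 1)
  W <- topographyWeights(topo)
  expect_equal(crossprod(W), diag(5), tolerance = 1e-12)

  # determinism under a fixed seed
  t1 <- makeTopographies(32, 5, seed = 1)
  t2 <- makeTopographies(32, 5, seed = 1)
  expect_identical(topographyWeights(t1), topographyWeights(t2))

  # separation constraint holds
  cc <- abs(crossprod(topographyWeights(t1))); diag(cc) <- 0
  expect_lte(max(cc), 0.5 + 1e-9)

  # 5 near-orthogonal patterns cannot exist in 2 channels
  expect_error(makeTopographies(2, 5, minSeparation = 0.9),
               "infeasible|orthogonal")
})

test_that("noiseless trials are rank-1 sinusoids with unit canonical correlation", {
  cfg <- smallConfig(snr = Inf, phaseJitter = 0, ampJitter = 0)
  rec <- simulateTrial(3, 1, cfg, smallTopo())
  X <- eegData(rec)
  expect_equal(dim(X), c(8L, 512L))
  expect_lte(qr(X)$rank, 1L)
  Y <- makeReference(60, 512, 512)
  r <- suppressWarnings(solveCCA(X, Y)$cor)
  expect_equal(r[1], 1, tolerance = 1e-9)
})

test_that("snr = 0 produces no stimulation-frequency component", {
  cfg <- smallConfig(snr = 0, seed = 5)
  m <- mean(vapply(1:30, function(i)
    snrValue(snr60Hz(simulateTrial(1, 4, cfg, smallTopo(), seed = i))),
    numeric(1)))
  # estimator floor is 1 on pure noise; no tone means no excess
  expect_lt(m, 1.3)
  expect_gt(m, 0.75)
})

test_that("generator SNR calibration matches the estimator within 20 percent", {
  cfg <- smallConfig(snr = 4, seed = 9)
  m <- mean(vapply(1:60, function(i)
    snrValue(snr60Hz(simulateTrial(1 + i %% 5, 4, cfg, smallTopo(),
                                   seed = 1000 + i))),
    numeric(1)))
  expect_gt(m, 4 * 0.8)
  expect_lt(m, 4 * 1.2)
})

test_that("sessions are balanced, sized C*nSequences and reproducible", {
  cfg <- smallConfig(snr = 2, seed = 33)
  ts <- simulateSession(30, 1, cfg, smallTopo())
  expect_equal(nTrials(ts), 150L)
  expect_equal(unname(table(trialLabels(ts))), rep(30L, 5), ignore_attr = TRUE)

  one <- simulateSession(1, 1, cfg, smallTopo())
  expect_equal(sort(trialLabels(one)), 1:5)

  a <- simulateSession(2, 1, cfg, smallTopo())
  b <- simulateSession(2, 1, cfg, smallTopo())
  expect_identical(trials(a), trials(b))
  expect_identical(trialLabels(a), trialLabels(b))
})

test_that("chunking withholds partial chunks and fixes the update rate", {
  rec <- Recording(matrix(rnorm(2 * 655), 2), fs = 2048)
  expect_length(chunkStream(rec, 131), 5L)
  rec2 <- Recording(matrix(rnorm(2 * 700), 2), fs = 2048)
  chunks <- chunkStream(rec2, 131)
  expect_length(chunks, 5L)
  expect_true(all(vapply(chunks, ncol, integer(1)) == 131L))
  # amplifier-limited update rate: 2048 / 131 chunks per second
  expect_equal(2048 / 131, 15.63, tolerance = 1e-3)
})

test_that("classification accuracy is non-decreasing in configured SNR", {
  fs <- 512
  h <- designBandpass(66, c(55, 65), fs)
  acc <- vapply(c(0, 0.5, 2, 8), function(s) {
    ts <- simulateSession(6, 1, smallConfig(snr = s, seed = 77), smallTopo())
    looAccuracy(filterTrials(h, ts), 256)
  }, numeric(1))
  tol <- 0.1  # sampling error at 30 trials
  expect_true(all(diff(acc) > -tol))
  expect_gt(acc[4], acc[1] + 0.2)
  # chance floor at snr = 0: binomial 99% interval around 1/5 for 30 trials
  ci <- qbinom(c(0.005, 0.995), 30, 0.2) / 30
  expect_gte(acc[1], ci[1])
  expect_lte(acc[1], ci[2])
})
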