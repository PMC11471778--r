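test_that("trial ITPC reproduces its closed-form values", {
  # identical phases cluster perfectly
  same <- makeComplexEpochs(matrix(exp(1i * 0.7), 5, 3))
  expect_equal(itpcTrial(same)[1, ], rep(1, 3))

  # symmetric phases cancel
  quad <- makeComplexEpochs(matrix(exp(1i * c(0, pi / 2, pi, 3 * pi / 2)),
                                   4, 3))
  expect_lt(max(itpcTrial(quad)), 1e-12)

  # two trials at 0 and pi/2: |mean| = sqrt(2)/2
  pair <- makeComplexEpochs(matrix(exp(1i * c(0, pi / 2)), 2, 3))
  expect_equal(itpcTrial(pair)[1, 1], sqrt(2) / 2)

  amp <- makeComplexEpochs(matrix(2 * exp(1i * 0.3), 2, 3))
  expect_error(itpcTrial(amp), "unit-modulus")
})

test_that("trial PAC is the mean vector length with a calibrated null", {
  one <- makeComplexEpochs(matrix(2 + 0i, 1, 3))
  expect_equal(pacTrial(one)[1, ], rep(2, 3))

  unitSame <- makeComplexEpochs(matrix(exp(1i * 1.1), 7, 3))
  expect_equal(pacTrial(unitSame)[1, ], rep(1, 3), tolerance = 1e-12)

  set.seed(9)
  nTr <- 10000
  r <- rgamma(nTr, 4)
  phi <- runif(nTr, -pi, pi)
  null <- makeComplexEpochs(matrix(r * exp(1i * phi), nTr, 1))
  expect_lt(pacTrial(null)[1, 1], 0.05 * mean(r))
})

test_that("stimulus-wide PAC localises simulated coupling and is calibrated on noise", {
  rec <- genPacRecording("global", fs = 200, duration = 60, fPhase = 2,
                         fAmp = 40, coupling = 1, noiseSd = 0.5, seed = 1)
  pm <- globalPac(rec, nSurrogates = 200, seed = 2)
  raw <- pm@raw[, , 1]
  ix <- which(raw == max(raw), arr.ind = TRUE)
  expect_equal(pm@phaseFreqs[ix[1]], 2)
  expect_equal(pm@ampFreqs[ix[2]], 40)
  expect_gt(pm@z[ix[1], ix[2], 1], 3)
  off <- pm@z[, , 1]
  off[pm@phaseFreqs == 2, abs(pm@ampFreqs - 40) <= 5] <- NA
  expect_lt(stats::median(abs(off), na.rm = TRUE), 2)

  set.seed(3)
  recN <- ContinuousRecording(matrix(rnorm(200 * 60), 1), 200)
  pmN <- globalPac(recN, nSurrogates = 500, seed = 11)
  z <- as.vector(pmN@z)
  expect_lt(stats::median(abs(z)), 2)
  expect_lt(abs(mean(z)), 0.3)
  expect_lt(abs(stats::sd(z) - 1), 0.4)

  expect_error(globalPac(recN, nSurrogates = 50), ">= 100")
  expect_error(globalPac(ContinuousRecording(rnorm(200 * 5), 200)),
               "10 cycles")
})

test_that("TRF-based ITPC equals trial ITPC on non-overlapping events", {
  fs <- 200
  onsets <- seq(2, 57, by = 2)     # epochs never overlap
  rec <- makePhaseResetRecording(onsets, 60, fs, noiseSd = 0.2, seed = 2)
  up <- unitPhase(bandpassAnalytic(rec, bandSpec("theta", 4, 8)))
  ev <- data.frame(story_id = "story1", onset_s = onsets)
  stim <- buildStimulusMatrix(ev, fs, nSamples = nSamples(rec),
                              features = "word_onset")
  res <- trfItpc(stim, up, -0.2, 0.6, lambda = 0)
  itpc <- itpcTrial(epochData(up, onsets, pre = 0.2, post = 0.6))
  expect_lt(max(abs(Mod(coefArray(res)[1, , 1]) - itpc[1, ])), 1e-6)
})

test_that("TRF-based ITPC tracks trial ITPC through overlapping naturalistic onsets", {
  fs <- 200
  tr <- genOnsets(120, 3, 0.1, seed = 5)
  rec <- makePhaseResetRecording(tr@onsets, 120, fs, noiseSd = 0.5,
                                 seed = 3)
  up <- unitPhase(bandpassAnalytic(rec, bandSpec("theta", 4, 8)))
  ev <- data.frame(story_id = "story1", onset_s = tr@onsets)
  stim <- buildStimulusMatrix(ev, fs, nSamples = nSamples(rec),
                              features = "word_onset")
  res <- trfItpc(stim, up, -0.2, 0.6, lambda = 0)
  itpc <- itpcTrial(suppressMessages(
    epochData(up, tr@onsets, pre = 0.2, post = 0.6)))
  expect_gt(cor(Mod(coefArray(res)[1, , 1]), itpc[1, ]), 0.95)
})

test_that("TRF-based ITPC null and perfect-reset limits hold", {
  fs <- 100
  n <- fs * 120
  onsets <- genOnsets(120, 2, 0.2, seed = 6)@onsets
  ev <- data.frame(story_id = "story1", onset_s = onsets)
  stim <- buildStimulusMatrix(ev, fs, nSamples = n,
                              features = "word_onset")

  # phase unrelated to onsets: |beta| near zero at all lags
  set.seed(7)
  zRand <- matrix(exp(1i * cumsum(rnorm(n, 0, 0.3))), 1)
  bund <- new("AnalyticBundle", z = zRand, kind = "unit_phase", fs = fs,
              phaseBand = bandSpec("b", 1, 8),
              ampBand = bandSpec("b", 1, 8),
              stories = trfpac:::.singleStory(n), nZeroAmp = 0L)
  res0 <- trfItpc(stim, bund, -0.2, 0.6, lambda = 0)
  expect_lt(max(Mod(coefArray(res0))), 0.2)

  # deterministic phase reset to 0 at every onset: |beta| = 1 at lag 0
  # (regular, well-separated onsets keep the lag columns orthogonal)
  onsets <- seq(1, 119)
  ev <- data.frame(story_id = "story1", onset_s = onsets)
  stim <- buildStimulusMatrix(ev, fs, nSamples = n,
                              features = "word_onset")
  phase <- rep(0.9, n)
  idx <- trfpac:::.onsetToSample(onsets, fs)
  phase[idx] <- 0
  bundR <- new("AnalyticBundle", z = matrix(exp(1i * phase), 1),
               kind = "unit_phase", fs = fs,
               phaseBand = bandSpec("b", 1, 8),
               ampBand = bandSpec("b", 1, 8),
               stories = trfpac:::.singleStory(n), nZeroAmp = 0L)
  resR <- trfItpc(stim, bundR, 0, 0.05, lambda = 0)
  lag0 <- which(lagAxis(resR) == 0)
  expect_equal(Mod(coefArray(resR)[1, lag0, 1]), 1, tolerance = 1e-9)
})

test_that("TRF-based PAC recovers burst latency and feature attribution", {
  fs <- 200
  events <- genOnsets(60, 2, 0.2, seed = 8)
  nw <- length(events@onsets)
  set.seed(9)
  f <- sample(c(1, 3), nw, replace = TRUE)

  rec2 <- genPacRecording("onset_locked", fs, 60, 2, 40,
                          coupling = 2 * mean(f), events = events,
                          noiseSd = 0.3, seed = 10)
  rec3 <- genPacRecording("feature_scaled", fs, 60, 2, 40, coupling = 2,
                          events = events, featureValues = f,
                          noiseSd = 0.3, seed = 11)
  ev <- data.frame(story_id = "story1", onset_s = events@onsets,
                   feat = f - mean(f))
  slow <- bandSpec("slow", 1, 3); fast <- bandSpec("fast", 30, 50)
  run <- function(rec) {
    carrier <- pacCarrier(bandpassAnalytic(rec, slow),
                          bandpassAnalytic(rec, fast))
    stim <- buildStimulusMatrix(ev, fs, nSamples = nSamples(rec))
    trfPac(stim, carrier, -0.2, 0.6)
  }
  res2 <- run(rec2); res3 <- run(rec3)

  # onset-locked bursts peak near the simulated latency (150 ms)
  g2 <- gfp(res2)
  pk <- lagAxis(res2)[which.max(g2["word_onset", ])]
  expect_lt(abs(pk - 0.15), 0.05)

  # the valued feature column lights up only when coupling scales with it
  expect_gt(max(gfp(res3)["feat", ]), 3 * max(g2["feat", ]))

  # no coupling: attribution indistinguishable from a shuffled-onset null
  rec0 <- genPacRecording("onset_locked", fs, 60, 2, 40, coupling = 0,
                          events = events, noiseSd = 0.3, seed = 12)
  res0 <- run(rec0)
  evShuf <- ev
  evShuf$onset_s <- sort(runif(nw, 0, 59.5))
  stimShuf <- suppressWarnings(
    buildStimulusMatrix(evShuf, fs, nSamples = nSamples(rec0)))
  carrier0 <- pacCarrier(bandpassAnalytic(rec0, slow),
                         bandpassAnalytic(rec0, fast))
  resShuf <- trfPac(stimShuf, carrier0, -0.2, 0.6)
  expect_lt(max(gfp(res0)["word_onset", ]),
            3 * max(gfp(resShuf)["word_onset", ]))
})

test_that("global field power is the channel-mean squared magnitude", {
  beta <- array(complex(real = c(1, 2), imaginary = c(0, 1)), c(1, 1, 2))
  k <- TRFKernel(beta, 0, 100)
  res <- new("ComplexTRFResult", kernel = k, kind = "pac")
  expect_equal(unname(gfp(res)[1, 1]), (1 + 5) / 2)

  kOne <- TRFKernel(beta[, , 1, drop = FALSE], 0, 100)
  expect_equal(unname(gfp(kOne)[1, 1]), Mod(beta[1, 1, 1])^2)

  k2 <- k; k2@beta <- 2 * k@beta
  expect_equal(gfp(k2), 4 * gfp(k))
})
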