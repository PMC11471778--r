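test_that("band-passed analytic signals carry the right amplitude and phase", {
  fs <- 200
  n <- fs * 10
  rec <- ContinuousRecording(sin(2 * pi * 6 * (0:(n - 1)) / fs), fs)
  ab <- bandpassAnalytic(rec, bandSpec("theta", 4, 8))
  mid <- 400:1600
  amp <- Mod(signalData(ab)[1, mid])
  expect_lt(stats::sd(amp) / mean(amp), 0.01)
  dph <- diff(Arg(signalData(ab)[1, mid]))
  dph <- (dph + pi) %% (2 * pi) - pi
  freqHat <- mean(dph) * fs / (2 * pi)
  expect_lt(abs(freqHat - 6) / 6, 0.01)

  # out-of-band signal is attenuated below 1% of input RMS
  rec2 <- ContinuousRecording(sin(2 * pi * 30 * (0:(n - 1)) / fs), fs)
  ab2 <- bandpassAnalytic(rec2, bandSpec("theta", 4, 8))
  expect_lt(sqrt(mean(Mod(signalData(ab2)[1, mid])^2)),
            0.01 * sqrt(mean(rec2@signal^2)))

  zero <- bandpassAnalytic(ContinuousRecording(numeric(n), fs),
                           bandSpec("theta", 4, 8))
  expect_equal(max(Mod(signalData(zero))), 0)

  expect_error(bandpassAnalytic(rec, bandSpec("bad", 50, 120)), "Nyquist")
})

test_that("zero-phase filtering preserves in-band phase; causal delays it", {
  fs <- 200
  n <- fs * 10
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 6 * t)
  rec <- ContinuousRecording(x, fs)
  mid <- 500:1500
  zp <- Re(signalData(bandpassAnalytic(rec, bandSpec("theta", 4, 8)))[1, ])
  analytic0 <- trfpac:::.analytic(x)
  dphi <- Arg(trfpac:::.analytic(zp)[mid] / analytic0[mid])
  expect_lt(max(abs(dphi)), 0.01)

  cz <- Re(signalData(bandpassAnalytic(rec, bandSpec("theta", 4, 8),
                                       causal = TRUE))[1, ])
  h <- trfpac:::.firBandpass(fs, 4, 8)
  gd <- (length(h) - 1) / 2
  expect_gt(cor(cz[(gd + 501):(gd + 1500)], x[501:1500]), 0.999)
})

test_that("unit-phase normalisation is exact, idempotent and flags zeros", {
  fs <- 100
  z <- matrix(complex(modulus = runif(200, 0.5, 2),
                      argument = runif(200, -pi, pi)), 1)
  a <- new("AnalyticBundle", z = z, kind = "amp_weighted", fs = fs,
           phaseBand = bandSpec("b", 1, 4), ampBand = bandSpec("b", 1, 4),
           stories = trfpac:::.singleStory(200), nZeroAmp = 0L)
  u <- unitPhase(a)
  expect_true(all(abs(Mod(signalData(u)) - 1) < 1e-12))
  expect_equal(Arg(signalData(u)), Arg(signalData(a)), tolerance = 1e-12)
  u2 <- unitPhase(u)
  expect_equal(signalData(u2), signalData(u))

  z0 <- z; z0[1, 5] <- 0
  a0 <- new("AnalyticBundle", z = z0, kind = "amp_weighted", fs = fs,
            phaseBand = bandSpec("b", 1, 4), ampBand = bandSpec("b", 1, 4),
            stories = trfpac:::.singleStory(200), nZeroAmp = 0L)
  u0 <- unitPhase(a0)
  expect_equal(u0@nZeroAmp, 1L)
  expect_equal(signalData(u0)[1, 5], 0 + 0i)
})

test_that("the PAC carrier combines high-band amplitude with low-band phase", {
  fs <- 200
  rec <- genPacRecording("global", fs, 20, coupling = 1, noiseSd = 0.2,
                         seed = 4)
  lo <- bandpassAnalytic(rec, bandSpec("slow", 1, 3))
  hi <- bandpassAnalytic(rec, bandSpec("fast", 30, 50))
  carrier <- pacCarrier(lo, hi)
  expect_equal(Mod(signalData(carrier)), Mod(signalData(hi)))
  expect_equal(Arg(signalData(carrier)), Arg(signalData(lo)),
               tolerance = 1e-9)

  # unit amplitude reduces the carrier to the unit-phase signal
  ones <- hi
  ones@z <- matrix(complex(modulus = 1, argument = Arg(signalData(hi))),
                   nrow = 1)
  expect_equal(signalData(pacCarrier(lo, ones)),
               signalData(unitPhase(lo)), tolerance = 1e-9)

  expect_warning(pacCarrier(hi, lo), "reaches into")

  # scenario-1 coupling: time-mean carrier beats an amplitude-shifted copy
  amp <- Mod(signalData(hi)[1, ])
  ph <- signalData(unitPhase(lo))[1, ]
  expect_gt(Mod(mean(amp * ph)),
            Mod(mean(c(amp[-(1:800)], amp[1:800]) * ph)))
})

test_that("epoching cuts onset-centred windows and reports dropped events", {
  fs <- 100
  n <- fs * 10
  x <- seq_len(n) / n
  rec <- ContinuousRecording(x, fs)
  ep <- epochData(rec, 5, pre = 0.5, post = 0.5)
  expect_equal(dim(ep@data), c(1, 1, 101))
  expect_equal(ep@data[1, 1, 51], x[501])   # t = 0 sample equals onset sample
  expect_true(any(ep@times == 0))

  expect_message(ep2 <- epochData(rec, c(0.1, 3, 5, 9.9), 0.5, 0.5),
                 "dropped")
  expect_equal(dim(ep2@data)[1], 2)
  expect_equal(ep2@nDropped, 2L)

  ep3 <- epochData(rec, c(3, 3.2), 0.5, 0.5)  # overlap is allowed
  expect_equal(dim(ep3@data)[1], 2)
})

test_that("Morlet decomposition localises frequency and scales quadratically", {
  fs <- 200
  n <- fs * 10
  rec <- ContinuousRecording(sin(2 * pi * 10 * (0:(n - 1)) / fs), fs)
  ep <- epochData(rec, seq(2, 8, 0.5), pre = 0.75, post = 0.75)
  tfr <- morletTfr(ep)
  freqs <- attr(tfr, "freqs")
  pw <- apply(Mod(tfr)^2, 3, mean)
  expect_equal(which.max(pw), which.min(abs(freqs - 10)))

  zero <- epochData(ContinuousRecording(numeric(n), fs), 5, 0.75, 0.75)
  expect_equal(max(Mod(morletTfr(zero))), 0)

  rec2 <- ContinuousRecording(2 * sin(2 * pi * 10 * (0:(n - 1)) / fs), fs)
  ep2 <- epochData(rec2, seq(2, 8, 0.5), pre = 0.75, post = 0.75)
  pw2 <- apply(Mod(morletTfr(ep2))^2, 3, mean)
  expect_equal(pw2[which.max(pw)] / pw[which.max(pw)], 4, tolerance = 1e-6)

  tiny <- epochData(rec, 5, pre = 0.05, post = 0.05)
  expect_error(morletTfr(tiny), "shorter than the longest wavelet")
})

test_that("band-passed power never exceeds broadband power", {
  set.seed(6)
  fs <- 200
  rec <- ContinuousRecording(rnorm(fs * 20), fs)
  broad <- mean(rec@signal^2)
  for (b in defaultBands()) {
    bp <- Re(signalData(bandpassAnalytic(rec, b))[1, ])
    expect_lt(mean(bp^2), broad)
  }
})

test_that("cerebro-acoustic coherence behaves like a calibrated estimator", {
  set.seed(7)
  fs <- 100
  n <- fs * 100
  env <- as.numeric(stats::filter(rnorm(n), rep(1, 8), circular = TRUE))
  rec <- ContinuousRecording(rbind(env, rnorm(n)), fs)
  coh <- envCoherence(rec, env, segment = 4)
  freqs <- attr(coh, "freqs")
  band <- freqs > 0.5 & freqs < 10

  expect_gt(min(coh[1, band]), 0.99)          # self-coherence
  expect_true(all(coh >= 0 & coh <= 1 + 1e-12))

  nSeg <- length(seq(1, n - 4 * fs + 1, by = 2 * fs))
  expect_lt(abs(mean(coh[2, band]) - 1 / nSeg), 2 / nSeg)  # known bias level

  # coherence elevated only where a filtered copy of the envelope was added
  h <- trfpac:::.firBandpass(fs, 15, 25)
  mix <- trfpac:::.filterZeroPhase(h, env) + rnorm(n, 0, 0.5)
  rec2 <- ContinuousRecording(mix, fs)
  coh2 <- envCoherence(rec2, env, segment = 4)
  inBand <- freqs >= 16 & freqs <= 24
  outBand <- freqs >= 2 & freqs <= 10
  expect_gt(mean(coh2[1, inBand]), 5 * mean(coh2[1, outBand]))

  expect_error(envCoherence(rec, env[-1]), "length")
  expect_error(envCoherence(ContinuousRecording(rnorm(300), fs),
                            rnorm(300), segment = 2.9), "two segments")
})
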