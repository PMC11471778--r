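# Dense normal-equations oracle used to check the decomposition-based solver.
denseRidgeOracle <- function(X, Y, lambda)
  solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, Y))

designFromMatrix <- function(X, fs = 100) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  stim <- new("StimulusMatrix", values = X, fs = fs,
              stories = trfpac:::.singleStory(nrow(X)))
  buildLaggedDesign(stim, lagsSamples = 0L)
}

test_that("lagged designs shift features with zero padding and no story wraparound", {
  ev <- data.frame(story_id = "story1", onset_s = 0.5, val = 1)
  stim <- buildStimulusMatrix(ev, 10, nSamples = 20,
                              features = "val")
  d <- buildLaggedDesign(stim, lagsSamples = 0:2)
  hits <- which(d@X != 0, arr.ind = TRUE)
  expect_equal(unname(hits[order(hits[, 2]), "row"]), c(6, 7, 8))

  # single-lag design reproduces the stimulus column
  d0 <- buildLaggedDesign(stim, lagsSamples = 0L)
  expect_equal(unname(d0@X[, 1]), unname(stim@values[, 1]))

  # no leakage across the story boundary: a word at the very end of story 1
  # must not appear in story 2's lagged columns
  stories <- data.frame(story_id = c("a", "b"), start = c(1L, 101L),
                        end = c(100L, 200L))
  evEnd <- data.frame(story_id = "a", onset_s = 9.9, val = 1)
  stimEnd <- buildStimulusMatrix(evEnd, 10, stories = stories,
                                 features = "val")
  dEnd <- buildLaggedDesign(stimEnd, lagsSamples = 0:5)
  expect_equal(sum(abs(dEnd@X[101:200, ])), 0)
  expect_equal(sum(dEnd@X[1:100, ]), 1)  # lags past the edge are padded off

  set.seed(2)
  Xr <- matrix(rnorm(600), 200, 3)
  dR <- designFromMatrix(Xr)
  ev2 <- eigen(crossprod(dR@X), symmetric = TRUE)$values
  expect_true(all(ev2 > -1e-8))
  expect_lt(max(abs(crossprod(dR@X) - t(crossprod(dR@X)))), 1e-12)

  expect_error(buildLaggedDesign(stim, lagsSamples = 0:100), "lag span")
})

test_that("ridge solver matches the dense normal-equations oracle", {
  set.seed(11)
  X <- matrix(rnorm(200 * 12), 200, 12)
  Y <- matrix(rnorm(200 * 3), 200, 3)
  d <- designFromMatrix(X)

  for (lam in c(0.5, 5, 50)) {
    k <- fitTrf(d, Y, lam)
    expect_lt(max(abs(trfpac:::.coefMatrix(k) - denseRidgeOracle(X, Y, lam))),
              1e-8)
  }

  # lambda = 0 equals OLS
  k0 <- fitTrf(d, Y, 0)
  expect_lt(max(abs(trfpac:::.coefMatrix(k0) -
                      solve(crossprod(X), crossprod(X, Y)))), 1e-8)

  # eigen-mean rule: lambda is the mean eigenvalue of X'X
  ke <- fitTrf(d, Y, "eigenMean")
  expect_equal(ke@lambda, mean(eigen(crossprod(X))$values))
  expect_lt(max(abs(trfpac:::.coefMatrix(ke) -
                      denseRidgeOracle(X, Y, ke@lambda))), 1e-8)

  # orthonormal design: beta = X'Y at lambda 0
  Q <- qr.Q(qr(X))
  dq <- designFromMatrix(Q)
  kq <- fitTrf(dq, Y, 0)
  expect_lt(max(abs(trfpac:::.coefMatrix(kq) - crossprod(Q, Y))), 1e-10)

  # shrinkage: coefficient norm decreases monotonically in lambda
  norms <- vapply(c(0, 1, 10, 100, 1e4, 1e8), function(l)
    sqrt(sum(trfpac:::.coefMatrix(fitTrf(d, Y, l))^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-4)

  # rank deficiency is an explicit error at lambda 0
  Xs <- cbind(X, X[, 1])
  expect_error(fitTrf(designFromMatrix(Xs), Y, 0), "rank-deficient")
})

test_that("complex responses fit through the same real design", {
  set.seed(12)
  X <- matrix(rnorm(300 * 6), 300, 6)
  Y <- matrix(complex(real = rnorm(300), imaginary = rnorm(300)), 300, 1)
  d <- designFromMatrix(X)
  k <- fitTrf(d, Y, 2)
  oracle <- solve(crossprod(X) + 2 * diag(6), t(X) %*% Y)
  expect_lt(max(Mod(trfpac:::.coefMatrix(k) - oracle)), 1e-8)
  expect_true(is.complex(coefArray(k)))
})

test_that("prediction is linear and OLS residuals are orthogonal to the design", {
  set.seed(13)
  X <- matrix(rnorm(400 * 8), 400, 8)
  y <- rnorm(400)
  d <- designFromMatrix(X)

  kz <- fitTrf(d, y * 0, 0)
  expect_equal(max(abs(predictTrf(d, kz))), 0)

  k <- fitTrf(d, y, 0)
  resid <- y - predictTrf(d, k)[, 1]
  expect_lt(max(abs(crossprod(X, resid))), 1e-6)

  k2 <- fitTrf(d, rnorm(400), 0)
  ksum <- k
  ksum@beta <- k@beta + k2@beta
  expect_equal(predictTrf(d, ksum), predictTrf(d, k) + predictTrf(d, k2))
})

test_that("fitting on summed story cross-products equals concatenated fitting", {
  fx <- makeTwoStoryEvents(duration = 15)
  stim <- buildStimulusMatrix(fx$events, fx$fs, stories = fx$stories,
                              features = c("word_onset", "val"))
  d <- buildLaggedDesign(stim, 0, 0.2)
  set.seed(14)
  y <- rnorm(nrow(d@X))
  whole <- trfpac:::.ridgeSolve(crossprod(d@X), crossprod(d@X, y), 1)
  r1 <- fx$stories$start[1]:fx$stories$end[1]
  r2 <- fx$stories$start[2]:fx$stories$end[2]
  summed <- trfpac:::.ridgeSolve(
    crossprod(d@X[r1, ]) + crossprod(d@X[r2, ]),
    crossprod(d@X[r1, ], y[r1]) + crossprod(d@X[r2, ], y[r2]), 1)
  expect_equal(whole$beta, summed$beta, tolerance = 1e-12)
})

test_that("leave-one-story-out scoring recovers planted structure", {
  fx <- makeTwoStoryEvents(duration = 30)
  stim <- buildStimulusMatrix(fx$events, fx$fs, stories = fx$stories,
                              features = c("word_onset", "val"))
  truth <- makeTruthKernel(fx$fs)
  rec0 <- genTrfRecording(truth, stim, 0)
  st <- scoreCv(stim, rec0, 0, 0.3, lambda = 1e-8)
  expect_gt(min(scoreFrame(st)$r), 0.99)

  # independent-noise response scores at chance
  recN <- ContinuousRecording(matrix(rnorm(fx$nSamples), 1), fx$fs,
                              stories = fx$stories)
  stN <- scoreCv(stim, recN, 0, 0.3)
  nStory <- fx$stories$end[1]
  expect_lt(abs(mean(scoreFrame(stN)$r)), 3 / sqrt(nStory))

  # identical stories give identical fold scores
  ev1 <- fx$events[fx$events$story_id == "story1", ]
  ev2 <- ev1; ev2$story_id <- "story2"
  stimTwin <- buildStimulusMatrix(rbind(ev1, ev2), fx$fs,
                                  stories = fx$stories,
                                  features = c("word_onset", "val"))
  recTwin <- genTrfRecording(truth, stimTwin, 0)
  stTwin <- scoreCv(stimTwin, recTwin, 0, 0.3, lambda = 1e-8)
  tb <- scoreFrame(stTwin)
  expect_equal(tb$r[tb$fold == "story1"], tb$r[tb$fold == "story2"],
               tolerance = 1e-10)
})

test_that("score increments are zero on self, positive for causal features, antisymmetric", {
  fx <- makeTwoStoryEvents(duration = 30)
  stim <- buildStimulusMatrix(fx$events, fx$fs, stories = fx$stories,
                              features = c("word_onset", "val"))
  truth <- makeTruthKernel(fx$fs)
  rec <- genTrfRecording(truth, stim, 1, seed = 20)
  full <- scoreCv(stim, rec, 0, 0.3, model = "full")
  evNull <- makeNullFeatures(fx$events, "val", seed = 21)
  stimNull <- buildStimulusMatrix(evNull, fx$fs, stories = fx$stories,
                                  features = c("word_onset", "val"))
  null <- scoreCv(stimNull, rec, 0, 0.3, model = "null")

  self <- scoreIncrement(full, full)
  expect_true(all(self$increment == 0))

  inc <- scoreIncrement(full, null)
  expect_gt(attr(inc, "meanIncrement"), 0)

  rev <- scoreIncrement(null, full)
  expect_equal(rev$increment, -inc$increment)
})

test_that("windowed TRFs isolate the lag window holding the true kernel", {
  fx <- makeTwoStoryEvents(duration = 30)
  stim <- buildStimulusMatrix(fx$events, fx$fs, stories = fx$stories,
                              features = c("word_onset", "val"))
  lags <- seq(0.1, 0.2, by = 1 / fx$fs)
  beta <- array(0, c(2, length(lags), 1))
  beta[2, , 1] <- sin(pi * (lags - 0.1) / 0.1)
  truth <- TRFKernel(beta, lags, fx$fs,
                     featureNames = c("word_onset", "val"))
  rec <- genTrfRecording(truth, stim, 0.5, seed = 30)

  wt <- fitWindowedTrf(stim, rec)
  expect_length(wt$scores, 13)
  ms <- vapply(wt$scores, meanScore, numeric(1))
  expect_equal(which.max(ms), which.min(abs(wt$windows$start - 0.1)))

  recZ <- ContinuousRecording(matrix(0, 1, fx$nSamples), fx$fs,
                              stories = fx$stories)
  wz <- fitWindowedTrf(stim, recZ)
  expect_true(all(abs(vapply(wz$scores, meanScore, numeric(1))) < 1e-8))

  expect_error(fitWindowedTrf(stim, rec, window = 0.1003), "whole number")
  expect_error(fitWindowedTrf(stim, rec, span = c(-0.4, 0.85)),
               "whole windows")
})
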