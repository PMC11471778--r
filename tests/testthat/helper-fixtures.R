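# Shared fixture builders; everything is generated in code under fixed seeds.

# Two-story word-event table with one valued feature column.
makeTwoStoryEvents <- function(duration = 30, fs = 200, rate = 3,
                               seed = 1) {
  ev <- do.call(rbind, lapply(1:2, function(s) {
    tr <- genOnsets(duration, rate, 0.05, seed = seed + s,
                    storyId = paste0("story", s))
    nw <- length(tr@onsets)
    vals <- genFeatureValues(nw, means = 2, sds = 0.5, seed = seed + 10 + s)
    data.frame(story_id = paste0("story", s), onset_s = tr@onsets,
               val = vals$feat1)
  }))
  n <- as.integer(duration * fs)
  stories <- data.frame(story_id = c("story1", "story2"),
                        start = c(1L, n + 1L), end = c(n, 2L * n))
  list(events = ev, stories = stories, fs = fs, nSamples = 2L * n)
}

# Smooth two-feature ground-truth kernel on lags 0..0.3 s.
makeTruthKernel <- function(fs = 200, nChannels = 2) {
  lags <- seq(0, 0.3, by = 1 / fs)
  beta <- array(0, c(2, length(lags), nChannels))
  for (ch in seq_len(nChannels)) {
    beta[1, , ch] <- ch * sin(2 * pi * 5 * lags) * exp(-lags / 0.1)
    beta[2, , ch] <- cos(2 * pi * 4 * lags) * exp(-lags / 0.08) / ch
  }
  TRFKernel(beta, lags, fs, featureNames = c("word_onset", "val"))
}

# Recording whose 5 Hz phase resets at each onset, plus Gaussian noise.
makePhaseResetRecording <- function(onsets, duration, fs = 200,
                                    noiseSd = 0.3, seed = 1) {
  n <- as.integer(duration * fs)
  t <- (0:(n - 1)) / fs
  phase <- 2 * pi * 5 * t
  for (o in onsets) {
    idx <- t >= o
    phase[idx] <- 2 * pi * 5 * (t[idx] - o)
  }
  set.seed(seed)
  ContinuousRecording(cos(phase) + rnorm(n, 0, noiseSd), fs)
}

# EpochSet built directly from a trials x samples matrix of complex values
# (single channel), with time axis centred on 0.
makeComplexEpochs <- function(valuesByTrial, fs = 100) {
  nTr <- nrow(valuesByTrial)
  nS <- ncol(valuesByTrial)
  data <- array(as.complex(0), c(nTr, 1, nS))
  data[, 1, ] <- valuesByTrial
  half <- (nS - 1) / 2
  new("EpochSet", data = data, times = (-half:half) / fs, fs = fs,
      nDropped = 0L)
}
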