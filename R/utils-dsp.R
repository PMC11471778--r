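# Internal DSP and RNG helpers shared across modules.

# Evaluate `expr` under a local seed without touching the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), eval.parent(substitute(expr)))
}

# Analytic signal via the frequency-domain quadrature construction:
# z = x + i * H(x), with H the Hilbert transform.
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Windowed-sinc FIR band-pass (Hamming window). Transition width 25% of the
# lower edge, floored at 1 Hz; even order (type I, exactly linear phase).
.firBandpass <- function(fs, fLo, fHi) {
  if (fHi >= fs / 2) stop("band edge ", fHi, " Hz is at or above Nyquist")
  tw <- max(1, 0.25 * fLo)
  n <- ceiling(3.3 * fs / tw)
  if (n %% 2 == 1) n <- n + 1
  signal::fir1(n, c(fLo, fHi) / (fs / 2), type = "pass")
}

# Kaiser-window FIR low-pass from an attenuation/transition specification.
.firLowpassKaiser <- function(fs, fc, transitionBw, stopAttenDb) {
  beta <- if (stopAttenDb > 50) 0.1102 * (stopAttenDb - 8.7)
          else if (stopAttenDb >= 21)
            0.5842 * (stopAttenDb - 21)^0.4 + 0.07886 * (stopAttenDb - 21)
          else 0
  n <- ceiling((stopAttenDb - 7.95) / (2.285 * 2 * pi * transitionBw / fs))
  if (n %% 2 == 1) n <- n + 1
  signal::fir1(n, fc / (fs / 2), type = "low",
               window = signal::kaiser(n + 1, beta))
}

# Zero-phase filtering with a symmetric (linear-phase) FIR: single FFT pass
# compensated by the integer group delay. Exact for odd-length symmetric h.
.filterZeroPhase <- function(h, x) {
  gd <- (length(h) - 1) / 2
  y <- signal::fftfilt(h, c(x, numeric(length(h))))
  y[seq_along(x) + gd]
}

# Causal FIR filtering (zero initial state).
.filterCausal <- function(h, x) {
  y <- signal::fftfilt(h, c(x, numeric(length(h))))
  y[seq_along(x)]
}

# Map onset seconds to 1-based sample indices: nearest sample, ties broken
# toward the earlier sample. Sample k corresponds to t = (k-1)/fs.
.onsetToSample <- function(onsets, fs) {
  as.integer(ceiling(onsets * fs - 0.5)) + 1L
}

# Complex Morlet wavelet at frequency f with a given number of cycles,
# sampled at fs, truncated at +-4 sd of the Gaussian envelope. Scaled so that
# filtering a unit-amplitude sinusoid at f yields |coefficient| ~= 1.
.morletWavelet <- function(f, nCycles, fs) {
  sigmaT <- nCycles / (2 * pi * f)
  half <- max(1L, ceiling(4 * sigmaT * fs))
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigmaT^2))
  w / (sum(exp(-t^2 / (2 * sigmaT^2))) / 2)
}

# Same-length convolution of x with a centred kernel w (odd length).
.convSame <- function(x, w) {
  n <- length(x); half <- (length(w) - 1) / 2
  y <- signal::fftfilt(w, c(x, numeric(length(w))))
  y[seq_len(n) + half]
}

# Complex same-length convolution (fftfilt handles real only).
.convSameComplex <- function(x, w) {
  .convSame(x, Re(w)) + 1i * .convSame(x, Im(w))
}

# Pearson correlation that returns 0 (instead of NA) for zero-variance input.
.safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}
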