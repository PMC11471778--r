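---
title: "Methods: TRF encoding models and feature-resolved cross-frequency coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRF encoding models and feature-resolved cross-frequency coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements, the
choices made where the methodology was genuinely open, and what the synthetic
validations do and do not establish.

## 1. The forward encoding model

We model a continuous multichannel recording as the output of a linear
convolutional system driven by a word-level stimulus representation. For
channel $i$, feature $j$ and lag $\tau$,

$$y_i(t_n) = \sum_j \sum_{\tau=\tau_{\min}}^{\tau_{\max}}
  \beta_{ij}(\tau)\, x_j(t_n - \tau) + \varepsilon_{in},$$

with Gaussian residuals. Stacking lagged copies of every feature into a
design matrix $X$ (samples $\times$ features$\cdot$lags), the kernel — the
temporal response function, TRF — has the closed ridge form
$\hat\beta = (X^\top X + \lambda I)^{-1} X^\top Y$.

**Stimulus representation.** Word-level features (surprisal and entropy in
nats; constituency-tree depth and closing-node count) enter as combs: zero
everywhere, the word's value at the sample nearest its onset (ties broken
toward the earlier sample; R's 1-based indexing puts $t = 1$ s at 200 Hz on
sample 201). A word-onset comb of ones and the compressed acoustic envelope
control for event timing and acoustics. Depth counts labelled nodes from
root to preterminal inclusive, and close counts the brackets a word
terminates, its own preterminal included; both conventions include the
boundary nodes because the alternative (exclusive counting) only shifts each
feature by a constant, which the regression absorbs — the inclusive
convention keeps the values interpretable as node counts.

**Numerical choices.** The solver eigendecomposes the symmetric
positive-semidefinite $X^\top X$; one decomposition serves any $\lambda$,
and a complex response reuses the same real decomposition (the model is
linear, so real and imaginary parts solve independently). With
$\lambda = 0$ a smallest eigenvalue below $10^{-10}$ of the largest raises
an explicit rank-deficiency error rather than returning a garbage inverse.
The default $\lambda$ is the arithmetic mean of the eigenvalues of
$X^\top X$, computed on the training folds only. Lagged columns are
zero-padded at story edges and never wrap across stories; fitting on
concatenated stories is exactly the sum of per-story cross-products, which
is how `scoreCv()` shares work across cross-validation folds.

**Standardisation.** Columns are *not* z-scored by default. Scores are
scale-invariant, so standardisation only changes the meaning of $\lambda$ —
but it would break the exact algebraic identity between the complex TRF on
an onset comb and trial-based phase clustering (Section 3), which we treat
as the method's core correctness anchor. `scoreCv(standardize = TRUE)`
enables per-training-fold z-scoring when comparable penalisation across
heterogeneous features matters more.

**Evaluation.** Leave-one-story-out cross-validation with per-channel
Pearson correlation, and increments against matched null models built by
circularly shifting a feature's values across words within each story
(onsets intact, value multiset preserved). Matching the regressor count
between model and null removes the mechanical score advantage of extra
columns. The default random shift is uniform on $[5, n_\mathrm{words}-5]$
words — far enough to decorrelate adjacent words, bounded away from the
full cycle that would reproduce the original. Time-resolved contributions
use thirteen independent non-overlapping 100 ms lag windows spanning
$-400$ to $900$ ms.

## 2. Spectral machinery

Band-limited analysis uses linear-phase windowed-sinc FIR filters
(Hamming), transition width 25% of the band's lower edge floored at 1 Hz.
Zero-phase application compensates the symmetric filter's integer group
delay in a single FFT pass; `causal = TRUE` runs the filter forward only
(the signal is then delayed by the group delay), for analyses where
pre-onset leakage is worse than delay. The analytic signal is formed by
frequency-domain quadrature, so modulus and argument are instantaneous
amplitude and phase. The envelope path follows the auditory chain:
half-wave rectification, Kaiser low-pass (cutoff 20 Hz, transition 10 Hz,
60 dB stop-band), cube-root compression, resampling. Morlet decomposition
uses 32 log-spaced frequencies from 3 to 80 Hz with cycles interpolated
linearly from 2 to 7 across the grid — few cycles for temporal resolution
at low frequencies, more for spectral resolution at high — and scales
coefficients so a unit sinusoid yields unit magnitude. Cerebro-acoustic
coherence is Welch magnitude-squared coherence on 4 s Hann segments with
50% overlap; note its well-known positive bias of roughly $1/n_\mathrm{seg}$
on independent signals, which the tests verify rather than remove.

## 3. Phase clustering and coupling without trials

The trial-based estimators are
$\mathrm{ITPC}(t) = |\,\mathrm{mean}_\mathrm{trials}\, e^{i\phi(t)}|$ and
the mean vector length
$\mathrm{PAC}(t) = |\,\mathrm{mean}_\mathrm{trials}\, r(t)\,e^{i\phi(t)}|$,
where $\phi$ is low-band phase and $r$ high-band amplitude. The package's
central method replaces the trial average with a regression: fit the
complex TRF of the continuous signal $e^{i\phi(t)}$ (or
$r(t)e^{i\phi(t)}$, the `pacCarrier()`) on the lagged comb design. For an
onset-only comb with non-overlapping events and $\lambda = 0$, $X^\top X$
is diagonal and $|\hat\beta(\tau)|$ *equals* the trial estimator at lag
$\tau$; with overlapping naturalistic onsets the two remain tightly
correlated (the acceptance suite checks $> 0.95$; observed $\approx
0.998$). The payoff is feature resolution: adding a mean-centred valued
feature column attributes coupling to that feature, which the trial
average cannot do because it sees only the event-locked aggregate. Before
the PAC fit the carrier amplitude is divided by its per-channel time mean
(switchable), so $|\beta|$ reads as relative modulation across channels.
Channel summaries use global field power, the channel mean of $|\beta|^2$.

**Stimulus-wide PAC.** `globalPac()` scans phase (default 1–8 Hz in 1 Hz
steps) against amplitude frequencies (15–80 Hz in 5 Hz steps), extracting
both with 7-cycle Morlet wavelets and averaging the weighted phasor over
*time* instead of trials. Each bin is z-scored against surrogates in which
the amplitude series is cut once and its two segments swapped — this
preserves the amplitude autocorrelation while destroying its alignment to
phase. Cut points are drawn from the middle 80% of the series; near-edge
cuts yield surrogates nearly identical to the original and bias the null
upward. The resulting z is calibrated in location and scale but *not*
shape: the raw index is the modulus of a near-zero-mean complex average,
so its null is Rayleigh-like and right-skewed, and z inherits that skew.
Median $|z|$ on white noise sits well below 2, but a strict normality test
on null z-values will reject; threshold z-maps accordingly (the package
reports raw, surrogate moments and z so users can re-normalise).

## 4. What the synthetic generators emulate

`genOnsets()` produces quasi-rhythmic onset trains (Gaussian-jittered
intervals, 50 ms refractory floor); `genFeatureValues()` produces feature
sequences with controlled marginals and cross-correlations (integer-rounded
for the tree counts, so requested correlations hold only approximately
there); `genTrfRecording()` convolves known kernels with a stimulus and
adds Gaussian noise; `genPacRecording()` implements three coupling
mechanisms. The three-scenario contrast in `runPacScenarioBenchmark()` uses:

- **stimulus-wide**: fast amplitude $1 + c\,(1+\cos\phi_\mathrm{slow})/2$
  everywhere (peak at phase zero);
- **onset-locked**: the same modulation gated by Gaussian windows (FWHM
  150 ms by default) at onset + latency (150 ms);
- **feature-scaled**: onset-locked with each burst multiplied by the
  word's feature value.

The slow oscillator's phase performs a Brownian walk
(0.5 rad$/\sqrt{\mathrm{s}}$ by default, settable to 0) on top of its
nominal frequency. This mirrors the quasi-periodicity of real neural
rhythms and is also what makes the segment-swap surrogate meaningful: for
a strictly periodic oscillator a circular amplitude shift leaves the
modulation index exactly invariant and no surrogate contrast exists.
Deterministic unit checks (e.g. burst amplitude ratio between feature
levels) disable the drift.

In the benchmark, the onset-locked scenario's burst gain is set to the
replicate's mean feature gain of the feature-scaled scenario, so both carry
the same average coupling. The mean vector length then cannot separate them
(its paired p-value is approximately uniform; being a null check, it will
dip below any fixed threshold for a corresponding fraction of seeds), while
the TRF's valued-feature column separates them decisively and recovers the
burst latency to within one or two samples.

What the generators do **not** emulate: sensor topography and field spread,
the 1/f spectral background of real M/EEG, artifacts, non-Gaussian noise,
or acoustics beyond an amplitude-modulated carrier. Passing tests therefore
establish estimator correctness and calibration under the stated generative
model, not robustness to the full messiness of recorded data.

## 5. Statistics

Cluster-based permutation on channel-summary time courses: one-sample t per
sample, clusters of contiguous supra-threshold samples (default threshold:
the two-sided $t$ quantile at $\alpha = 0.05$ with the data's degrees of
freedom), cluster mass = summed t, null = sign-flipped subjects, cluster p
= rank of $|$mass$|$ among permutation maxima of 1024 permutations (the
attainable minimum is $1/(n_\mathrm{perm}+1)$). Spatio-temporal
sensor-adjacency clustering is deliberately reduced to 1-D time clustering
of global-field-power curves. Benjamini–Hochberg correction wraps
`stats::p.adjust` with boundary-inclusive rejection; paired comparisons
wrap `stats::t.test`, flagging zero-variance differences instead of
erroring.

## 6. Study sizes and limitations

The canned studies run at desk scale by design: the coupling benchmark uses
twenty replicates of 60 s at 200 Hz; the encoding study four stories of
40 s at 200 Hz, three channels, with the four-model roster and matched
nulls; calibration uses 500 null datasets of 20 subjects by 100 samples.
These sizes make every estimator's behaviour measurable while each study
stays in the seconds-to-minutes range.

Known limitations: the TRF assumes linearity and time-invariance within a
story; ridge with a single scalar $\lambda$ penalises all features equally
(no banded per-feature penalties, no boosting); the surrogate scheme uses a
single cut (finer segment shuffling would sharpen the null's tails); epochs
share samples when words are closer than the analysis window, which is
intended (naturalistic overlap) but means trial estimators are not
independent across events; and the WAV reader handles uncompressed PCM
only.
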