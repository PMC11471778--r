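#' Build a lagged design matrix
#'
#' For each feature and each lag tau on the grid, produces a column equal to
#' the feature delayed by tau samples (negative lags advance it). Shifts are
#' applied independently within each story with zero padding at the story
#' edges, so no sample leaks across story boundaries. Positive lags mean the
#' stimulus precedes the response.
#'
#' @param stim a \linkS4class{StimulusMatrix}.
#' @param tauMin,tauMax lag span in seconds (\code{tauMin < tauMax}); the
#'   grid is every sample from \code{round(tauMin*fs)} to
#'   \code{round(tauMax*fs)} inclusive.
#' @param lagsSamples integer lag grid in samples, overriding
#'   \code{tauMin}/\code{tauMax}.
#' @return A \linkS4class{LaggedDesign}; columns are grouped by feature with
#'   lags varying fastest.
#' @export
buildLaggedDesign <- function(stim, tauMin = 0, tauMax = 0.5,
                              lagsSamples = NULL) {
  fs <- stim@fs
  if (is.null(lagsSamples)) {
    if (tauMin >= tauMax) stop("'tauMin' must be below 'tauMax'")
    lagsSamples <- seq.int(round(tauMin * fs), round(tauMax * fs))
  }
  lagsSamples <- as.integer(lagsSamples)
  span <- max(lagsSamples) - min(lagsSamples)
  storyLens <- stim@stories$end - stim@stories$start + 1L
  if (any(storyLens <= span))
    stop("lag span (", span, " samples) exceeds story '",
         stim@stories$story_id[base::which(storyLens <= span)[1]],
         "' length")
  V <- stim@values
  n <- nrow(V); p <- ncol(V); L <- length(lagsSamples)
  X <- matrix(0, n, p * L)
  for (s in seq_len(nrow(stim@stories))) {
    a <- stim@stories$start[s]; b <- stim@stories$end[s]
    len <- b - a + 1L
    for (j in seq_len(p)) {
      col0 <- (j - 1L) * L
      for (l in seq_len(L)) {
        tau <- lagsSamples[l]
        # x_j(t - tau) within the story, zero-padded
        src <- (1L - min(0L, tau)):(len - max(0L, tau))
        if (length(src) < 1 || src[1] > src[length(src)]) next
        dst <- src + tau
        X[a - 1L + dst, col0 + l] <- V[a - 1L + src, j]
      }
    }
  }
  featNames <- colnames(V)
  colnames(X) <- paste0(rep(featNames, each = L), "@", lagsSamples)
  new("LaggedDesign", X = X, lagsSamples = lagsSamples, fs = fs,
      featureNames = featNames, stories = stim@stories)
}

.lambdaFromMode <- function(lambda, d) {
  if (is.character(lambda)) {
    mode <- match.arg(lambda, c("eigenMean", "zero"))
    if (mode == "zero") list(mode = "zero", value = 0)
    else list(mode = "eigenMean", value = mean(d))
  } else {
    if (lambda < 0) stop("'lambda' must be >= 0")
    list(mode = if (lambda == 0) "zero" else "fixed", value = lambda)
  }
}

# Core ridge solve from accumulated cross-products, via the eigendecomposition
# of the (symmetric PSD) autocorrelation matrix. Works for complex XtY.
.ridgeSolve <- function(XtX, XtY, lambda) {
  e <- eigen(XtX, symmetric = TRUE)
  d <- e$values
  lam <- .lambdaFromMode(lambda, d)
  if (lam$value == 0 && d[length(d)] < max(d, 0) * 1e-10)
    stop("X'X is rank-deficient (smallest eigenvalue ",
         format(d[length(d)]), "); use ridge regularisation")
  coefs <- e$vectors %*% ((t(e$vectors) %*% XtY) / (d + lam$value))
  list(beta = coefs, lambda = lam$value, lambdaMode = lam$mode)
}

#' Fit a temporal response function by closed-form ridge regression
#'
#' Solves \code{(X'X + lambda I) beta = X'Y} for the lagged design X and the
#' response Y (samples x channels). The solution uses the eigendecomposition
#' of X'X, which is numerically stable and lets a whole lambda path share one
#' decomposition. A complex response (analytic signal) is handled by solving
#' its real and imaginary parts against the same real design, yielding a
#' complex kernel.
#'
#' @param design a \linkS4class{LaggedDesign}.
#' @param response samples x channels matrix (numeric or complex), a vector,
#'   or a \linkS4class{ContinuousRecording}/\linkS4class{AnalyticBundle}
#'   (whose channels x samples signal is transposed internally).
#' @param lambda \code{"eigenMean"} (default: the arithmetic mean of the
#'   eigenvalues of X'X), \code{"zero"}/0 for ordinary least squares (errors
#'   on rank-deficient designs), or a fixed non-negative value.
#' @return A \linkS4class{TRFKernel}.
#' @export
fitTrf <- function(design, response, lambda = "eigenMean") {
  Y <- .asResponseMatrix(response, design)
  X <- design@X
  XtX <- crossprod(X)
  XtY <- if (is.complex(Y)) t(X) %*% Y else crossprod(X, Y)
  sol <- .ridgeSolve(XtX, XtY, lambda)
  .kernelFromCoefs(sol, design, colnames(Y))
}

.asResponseMatrix <- function(response, design) {
  if (is(response, "ContinuousRecording")) {
    if (!isTRUE(all.equal(response@fs, design@fs)))
      stop("sampling-rate mismatch between design and response")
    Y <- t(response@signal); colnames(Y) <- response@channelNames
  } else if (is(response, "AnalyticBundle")) {
    if (!isTRUE(all.equal(response@fs, design@fs)))
      stop("sampling-rate mismatch between design and response")
    Y <- t(response@z)
  } else {
    Y <- if (is.vector(response)) matrix(response, ncol = 1)
         else as.matrix(response)
  }
  if (nrow(Y) != nrow(design@X))
    stop("design has ", nrow(design@X), " samples but response has ",
         nrow(Y))
  if (any(!is.finite(Mod(Y)))) stop("response must be finite")
  Y
}

.kernelFromCoefs <- function(sol, design, chNames = NULL) {
  L <- length(design@lagsSamples)
  p <- length(design@featureNames)
  nc <- ncol(sol$beta)
  if (is.null(chNames)) chNames <- paste0("ch", seq_len(nc))
  beta <- array(0, c(p, L, nc))
  if (is.complex(sol$beta)) beta <- array(as.complex(beta), c(p, L, nc))
  for (j in seq_len(p))
    beta[j, , ] <- sol$beta[(j - 1L) * L + seq_len(L), , drop = FALSE]
  TRFKernel(beta, design@lagsSamples / design@fs, design@fs,
            lambda = sol$lambda, lambdaMode = sol$lambdaMode,
            featureNames = design@featureNames, channelNames = chNames)
}

# Flatten a kernel back to the (features*lags) x channels coefficient matrix.
.coefMatrix <- function(kernel) {
  d <- dim(kernel@beta)
  B <- matrix(if (is.complex(kernel@beta)) as.complex(0) else 0,
              d[1] * d[2], d[3])
  for (j in seq_len(d[1]))
    B[(j - 1L) * d[2] + seq_len(d[2]), ] <- kernel@beta[j, , ]
  B
}

#' Predict the response from a design and a kernel
#'
#' Computes \code{yhat = X beta}: the reconstruction of the recording implied
#' by the convolutional forward model. Linear in both arguments.
#'
#' @param design a \linkS4class{LaggedDesign}.
#' @param kernel a \linkS4class{TRFKernel} with matching feature and lag
#'   axes.
#' @return samples x channels matrix (complex if the kernel is complex).
#' @export
predictTrf <- function(design, kernel) {
  d <- dim(kernel@beta)
  if (d[1] != length(design@featureNames) ||
      d[2] != length(design@lagsSamples))
    stop("kernel shape (", d[1], " x ", d[2],
         ") does not match design (", length(design@featureNames), " x ",
         length(design@lagsSamples), ")")
  design@X %*% .coefMatrix(kernel)
}

#' Leave-one-story-out cross-validated TRF scores
#'
#' For each held-out story, fits the kernel on the remaining stories by
#' summing per-story cross-product matrices X'X and X'Y (exactly equivalent
#' to fitting on the concatenated stories), predicts the held-out story and
#' scores it with Pearson's correlation per channel. The regularisation is
#' recomputed on each training fold's X'X only.
#'
#' @param stim a \linkS4class{StimulusMatrix} with at least two stories.
#' @param rec the \linkS4class{ContinuousRecording} to model.
#' @param tauMin,tauMax,lagsSamples lag grid, as in
#'   \code{\link{buildLaggedDesign}}.
#' @param lambda as in \code{\link{fitTrf}}.
#' @param standardize z-score design columns using training-fold statistics
#'   before fitting (scores are scale-invariant; this only changes the
#'   meaning of lambda). Default FALSE.
#' @param model,band labels stored in the result.
#' @return A \linkS4class{ScoreTable}.
#' @export
scoreCv <- function(stim, rec, tauMin = 0, tauMax = 0.5,
                    lagsSamples = NULL, lambda = "eigenMean",
                    standardize = FALSE, model = "model",
                    band = "broadband") {
  st <- stim@stories
  if (nrow(st) < 2) stop("cross-validation needs at least two stories")
  if (nSamples(stim) != nSamples(rec))
    stop("stimulus and recording sample counts differ")
  design <- buildLaggedDesign(stim, tauMin, tauMax, lagsSamples)
  X <- design@X
  Y <- t(rec@signal)
  nc <- ncol(Y)
  rows <- lapply(seq_len(nrow(st)), function(s) st$start[s]:st$end[s])
  if (!standardize) {
    XtX <- lapply(rows, function(r) crossprod(X[r, , drop = FALSE]))
    XtY <- lapply(rows, function(r)
      crossprod(X[r, , drop = FALSE], Y[r, , drop = FALSE]))
  }
  res <- list()
  for (k in seq_len(nrow(st))) {
    tr <- setdiff(seq_len(nrow(st)), k)
    if (standardize) {
      trRows <- unlist(rows[tr])
      mu <- colMeans(X[trRows, , drop = FALSE])
      sdv <- apply(X[trRows, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[trRows, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[rows[[k]], , drop = FALSE], 2, mu), 2, sdv, "/")
      sol <- .ridgeSolve(crossprod(Xtr),
                         crossprod(Xtr, Y[trRows, , drop = FALSE]), lambda)
      yhat <- Xte %*% sol$beta
    } else {
      sol <- .ridgeSolve(Reduce(`+`, XtX[tr]), Reduce(`+`, XtY[tr]), lambda)
      yhat <- X[rows[[k]], , drop = FALSE] %*% sol$beta
    }
    yobs <- Y[rows[[k]], , drop = FALSE]
    r <- vapply(seq_len(nc), function(ch)
      .safeCor(Re(yhat[, ch]), yobs[, ch]), numeric(1))
    res[[k]] <- data.frame(fold = st$story_id[k],
                           channel = rec@channelNames, r = r,
                           stringsAsFactors = FALSE)
  }
  new("ScoreTable", model = model, band = band, table = do.call(rbind, res))
}

#' Score increment of a full model over its matched null model
#'
#' Per-channel, per-fold difference in cross-validated Pearson r between a
#' model and its feature-shuffled null. Comparing against a null with the
#' same number of regressors normalises for model size.
#'
#' @param full,null \linkS4class{ScoreTable}s over the same folds, channels
#'   and band.
#' @return data.frame with columns \code{fold}, \code{channel},
#'   \code{increment}; the grand mean is attached as attribute
#'   \code{"meanIncrement"}.
#' @export
scoreIncrement <- function(full, null) {
  a <- full@table; b <- null@table
  if (full@band != null@band) stop("band mismatch")
  if (nrow(a) != nrow(b) || !all(a$fold == b$fold) ||
      !all(a$channel == b$channel))
    stop("score tables have mismatched folds or channels")
  out <- data.frame(fold = a$fold, channel = a$channel,
                    increment = a$r - b$r, stringsAsFactors = FALSE)
  attr(out, "meanIncrement") <- mean(out$increment)
  out
}

#' Time-windowed TRF models
#'
#' Fits an independent TRF model for each non-overlapping lag window (default
#' thirteen 100 ms windows spanning -400 to 900 ms around word onset), each
#' model using only the lags inside its window, and scores each by
#' leave-one-story-out cross-validation.
#'
#' @param stim,rec,lambda,standardize as in \code{\link{scoreCv}}.
#' @param window window length in seconds (must be a whole number of
#'   samples).
#' @param span two-element numeric, start and end of the lag span in seconds;
#'   must divide into whole windows.
#' @param model label prefix for the per-window score tables.
#' @return list with \code{windows} (data.frame of window starts/ends in
#'   seconds) and \code{scores} (list of \linkS4class{ScoreTable}, one per
#'   window).
#' @export
fitWindowedTrf <- function(stim, rec, window = 0.1, span = c(-0.4, 0.9),
                           lambda = "eigenMean", standardize = FALSE,
                           model = "windowed") {
  fs <- stim@fs
  wSamp <- window * fs
  if (abs(wSamp - round(wSamp)) > 1e-9)
    stop("'window' must be a whole number of samples at fs = ", fs, " Hz")
  wSamp <- as.integer(round(wSamp))
  nWin <- (span[2] - span[1]) / window
  if (abs(nWin - round(nWin)) > 1e-9)
    stop("'span' must divide into whole windows")
  nWin <- as.integer(round(nWin))
  starts <- span[1] + window * (seq_len(nWin) - 1)
  scores <- vector("list", nWin)
  for (w in seq_len(nWin)) {
    lags <- as.integer(round(starts[w] * fs)) + 0:(wSamp - 1L)
    scores[[w]] <- scoreCv(stim, rec, lagsSamples = lags, lambda = lambda,
                           standardize = standardize,
                           model = sprintf("%s[%g,%g)", model, starts[w],
                                           starts[w] + window))
  }
  list(windows = data.frame(start = starts, end = starts + window),
       scores = scores)
}
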