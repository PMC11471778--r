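#' Syntactic word features from a bracketed constituency parse
#'
#' Parses Penn-Treebank-style S-expressions (one sentence per string) and
#' returns, per word in order: the token, its depth and its closing-node
#' count.
#'
#' Depth counts the labelled nodes on the path from the root to the word's
#' preterminal, both inclusive, and is a proxy for syntactic complexity.
#' Close counts the constituents the word terminates, i.e. the number of
#' closing brackets immediately following the token (the bottom-up count of
#' structure building, a proxy for integration/"merge"). Every word closes at
#' least its own preterminal; the final word of a sentence also closes the
#' root, so its count is at least 2.
#'
#' @param treeText character vector of bracketed parses, one sentence each.
#' @return data.frame with columns \code{sentence}, \code{token},
#'   \code{depth}, \code{close}.
#' @examples
#' parseBracketed("(S (NP (NN ik)) (VP (VB zie) (NP (DET een) (NN hond))))")
#' @export
parseBracketed <- function(treeText) {
  out <- lapply(seq_along(treeText), function(s) {
    res <- .parseOneTree(treeText[s], s)
    if (nrow(res)) res$sentence <- s
    res
  })
  do.call(rbind, out)[, c("sentence", "token", "depth", "close")]
}

.parseOneTree <- function(txt, sentence) {
  chars <- strsplit(txt, "")[[1]]
  n <- length(chars)
  depth <- 0L            # open labelled brackets
  i <- 1L
  tokens <- character(0); depths <- integer(0); closes <- integer(0)
  expectLabel <- FALSE   # TRUE right after an opening bracket
  readAtom <- function(i) {
    j <- i
    while (j <= n && !chars[j] %in% c("(", ")") && !grepl("\\s", chars[j]))
      j <- j + 1L
    list(atom = paste(chars[i:(j - 1L)], collapse = ""), nxt = j)
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch == "(") {
      depth <- depth + 1L; expectLabel <- TRUE; i <- i + 1L
    } else if (ch == ")") {
      if (depth == 0L)
        stop("unbalanced ')' at character ", i, " in sentence ", sentence)
      depth <- depth - 1L
      if (length(closes)) closes[length(closes)] <- closes[length(closes)] + 1L
      i <- i + 1L
    } else {
      a <- readAtom(i)
      if (expectLabel) {
        expectLabel <- FALSE     # constituent label
      } else {                   # leaf token
        tokens <- c(tokens, a$atom)
        depths <- c(depths, depth)
        closes <- c(closes, 0L)
      }
      i <- a$nxt
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' (", depth, " unclosed) at end of sentence ",
         sentence)
  if (!length(tokens))
    stop("empty tree in sentence ", sentence, ": no leaf tokens found")
  data.frame(token = tokens, depth = depths, close = closes,
             stringsAsFactors = FALSE)
}

#' Surprisal and entropy of a next-word distribution
#'
#' Given the probability distribution over the vocabulary for the upcoming
#' word, returns the surprisal of the observed word, \code{-ln p(observed)}
#' (prediction-error proxy), and the entropy of the distribution,
#' \code{-sum(p * ln p)} with \code{0 * ln 0 := 0} (uncertainty proxy). Both
#' are in nats.
#'
#' @param dist numeric probability vector (entries >= 0, summing to 1 within
#'   1e-6).
#' @param observedIndex index of the observed word in \code{dist}.
#' @return list with elements \code{surprisal} and \code{entropy}.
#' @export
infoMetrics <- function(dist, observedIndex) {
  if (any(dist < 0)) stop("probabilities must be non-negative")
  if (abs(sum(dist) - 1) > 1e-6)
    stop("distribution must sum to 1 (got ", format(sum(dist)), ")")
  if (observedIndex < 1 || observedIndex > length(dist))
    stop("'observedIndex' out of range")
  p <- dist[observedIndex]
  if (p == 0)
    stop("observed word has probability 0: surprisal is infinite")
  pos <- dist[dist > 0]
  list(surprisal = -log(p), entropy = -sum(pos * log(pos)))
}

#' Build the samples-by-features stimulus matrix
#'
#' Word-level features become comb columns: zero everywhere except at the
#' sample nearest each word onset (ties toward the earlier sample), which
#' carries the word's value; the \code{word_onset} comb carries ones. The
#' acoustic envelope, if supplied, is passed through as a dense column. Two
#' onsets mapping to the same sample are summed with a warning.
#'
#' @param events word-event data.frame with columns \code{story_id},
#'   \code{onset_s} and one column per word-level feature (onsets are
#'   story-relative seconds).
#' @param fs sampling rate in Hz.
#' @param nSamples total sample count (single story) if \code{stories} is
#'   NULL.
#' @param stories story segmentation data.frame (\code{story_id},
#'   \code{start}, \code{end}); defaults to one story of \code{nSamples}.
#' @param envelope optional envelope series of length equal to the total
#'   sample count.
#' @param features character vector naming the columns to build, from
#'   \code{"word_onset"}, \code{"envelope"} and the event-table feature
#'   columns. Defaults to onset comb plus all feature columns (plus envelope
#'   when given).
#' @return A \linkS4class{StimulusMatrix}.
#' @export
buildStimulusMatrix <- function(events, fs, nSamples = NULL, stories = NULL,
                                envelope = NULL, features = NULL) {
  if (is.null(stories)) {
    if (is.null(nSamples)) stop("supply 'nSamples' or 'stories'")
    stories <- .singleStory(nSamples,
      storyId = if (nrow(events)) events$story_id[1] else "story1")
  }
  nTot <- max(stories$end)
  featCols <- setdiff(names(events), c("story_id", "onset_s"))
  if (is.null(features))
    features <- c("word_onset", featCols,
                  if (!is.null(envelope)) "envelope")
  unknown <- setdiff(features, c("word_onset", "envelope", featCols))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  if ("envelope" %in% features) {
    if (is.null(envelope)) stop("'envelope' feature requested but not given")
    if (length(envelope) != nTot)
      stop("envelope length (", length(envelope),
           ") must equal sample count (", nTot, ")")
  }
  vals <- matrix(0, nTot, length(features),
                 dimnames = list(NULL, features))
  if (nrow(events)) {
    idx <- integer(nrow(events))
    for (s in seq_len(nrow(stories))) {
      inS <- events$story_id == stories$story_id[s]
      if (!any(inS)) next
      storyLen <- (stories$end[s] - stories$start[s] + 1) / fs
      bad <- events$onset_s[inS] >= storyLen
      if (any(bad))
        stop("onset ", format(events$onset_s[inS][bad][1]),
             " s beyond story '", stories$story_id[s], "' (", storyLen, " s)")
      idx[inS] <- stories$start[s] - 1L +
        .onsetToSample(events$onset_s[inS], fs)
    }
    orphan <- !(events$story_id %in% stories$story_id)
    if (any(orphan))
      stop("events reference unknown story: ",
           paste(unique(events$story_id[orphan]), collapse = ", "))
    if (anyDuplicated(idx))
      warning("multiple onsets map to the same sample; values summed")
    for (f in features) {
      if (f == "envelope") next
      v <- if (f == "word_onset") rep(1, nrow(events)) else events[[f]]
      acc <- tapply(v, idx, sum)
      vals[as.integer(names(acc)), f] <- as.numeric(acc)
    }
  }
  if ("envelope" %in% features) vals[, "envelope"] <- envelope
  new("StimulusMatrix", values = vals, fs = fs, stories = stories)
}

#' Mismatched (null) feature values
#'
#' Builds the shuffled-feature null used for null-model scoring: selected
#' feature columns are circularly shifted by a number of words within each
#' story, so onset timings and the per-story value multisets are preserved
#' exactly while the feature-to-word assignment is destroyed.
#'
#' @param events word-event data.frame (see
#'   \code{\link{buildStimulusMatrix}}).
#' @param which character vector of feature columns to shuffle.
#' @param shift shift in words (>= 1), or NULL to draw one uniformly from
#'   \code{[5, nWords - 5]} per story under \code{seed}.
#' @param seed integer seed for the random shift.
#' @return The event table with the selected columns shifted.
#' @export
makeNullFeatures <- function(events, which, shift = NULL, seed = NULL) {
  if (!length(which)) stop("'which' must name at least one feature")
  missing <- setdiff(which, names(events))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  if (!is.null(shift) && shift < 1) stop("'shift' must be >= 1")
  out <- events
  .withSeed(seed, {
    for (sid in unique(events$story_id)) {
      rows <- base::which(events$story_id == sid)
      n <- length(rows)
      k <- if (is.null(shift)) {
        if (n < 10) max(1L, n %/% 2L) else sample(5:(n - 5), 1)
      } else shift
      if (k >= n) {
        warning("shift ", k, " >= story length ", n, " in story '", sid,
                "'; wrapped", if (k %% n == 0) " (degenerate: identity)")
        k <- k %% n
      }
      if (k == 0) next
      perm <- c((n - k + 1):n, 1:(n - k))  # value of word i-k lands on word i
      for (f in which) out[rows, f] <- events[rows[perm], f]
    }
  })
  out
}

#' Variance inflation factors
#'
#' For each feature column, regresses it on all other columns and reports
#' \code{VIF = 1 / (1 - R^2)}. A perfectly collinear column yields
#' \code{Inf} rather than an error.
#'
#' @param features numeric matrix or data.frame of per-word feature values
#'   (>= 2 columns, more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(features) {
  X <- as.matrix(features)
  p <- ncol(X)
  if (p < 2) stop("need at least two features")
  if (nrow(X) < p + 1) stop("need at least nFeatures + 1 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("feat", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(out, colnames(X))
}
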