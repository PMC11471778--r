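#' One-sample cluster-based permutation test on a time course
#'
#' Computes a one-sample t statistic at each sample, forms clusters of
#' contiguous samples whose |t| exceeds the cluster-forming threshold
#' (positive and negative runs separately), and scores each cluster by its
#' mass (summed t). The null distribution of the maximum absolute cluster
#' mass is built by randomly sign-flipping subjects; each observed cluster's
#' p-value is the rank of its |mass| among the permutation maxima, so the
#' smallest attainable p is \code{1/(nPerm+1)}.
#'
#' @param data subjects x samples numeric matrix (>= 2 subjects).
#' @param nPerm number of permutations (default 1024; < 100 warns).
#' @param alpha two-sided tail probability defining the default
#'   cluster-forming threshold, the t quantile at \code{alpha} with
#'   \code{nSubjects - 1} degrees of freedom.
#' @param threshold explicit threshold on |t|, overriding \code{alpha}.
#' @param seed integer seed for the sign flips.
#' @return A \linkS4class{ClusterSet}. Zero-variance samples get t = 0.
#' @export
clusterPerm1d <- function(data, nPerm = 1024, alpha = 0.05,
                          threshold = NULL, seed = NULL) {
  data <- as.matrix(data)
  nS <- nrow(data); nT <- ncol(data)
  if (nS < 2) stop("need at least two subjects")
  if (nPerm < 100) warning("fewer than 100 permutations; p-values are coarse")
  if (is.null(threshold)) threshold <- stats::qt(1 - alpha / 2, nS - 1)
  sumsq <- colSums(data^2)
  tFrom <- function(m) {
    v <- (sumsq - nS * m^2) / (nS - 1)
    tt <- ifelse(v <= 0, 0, m / sqrt(v / nS))
    tt
  }
  clusterise <- function(tt) {
    supra <- sign(tt) * (abs(tt) > threshold)
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    keep <- base::which(r$values != 0)
    lapply(keep, function(k) (ends[k] - r$lengths[k] + 1L):ends[k])
  }
  tObs <- tFrom(colMeans(data))
  clusters <- clusterise(tObs)
  masses <- vapply(clusters, function(ix) sum(tObs[ix]), numeric(1))
  signs <- .withSeed(seed,
    matrix(sample(c(-1, 1), nPerm * nS, replace = TRUE), nPerm, nS))
  permMeans <- (signs %*% data) / nS
  maxMass <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    tp <- tFrom(permMeans[p, ])
    cl <- clusterise(tp)
    maxMass[p] <- if (length(cl))
      max(abs(vapply(cl, function(ix) sum(tp[ix]), numeric(1)))) else 0
  }
  pvals <- vapply(masses, function(m)
    (1 + sum(maxMass >= abs(m))) / (nPerm + 1), numeric(1))
  new("ClusterSet", clusters = clusters, masses = masses, pValues = pvals,
      tObserved = tObs, threshold = threshold, nPerm = as.integer(nPerm))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up procedure controlling the FDR at level \code{q}:
#' adjusted p-values come from \code{stats::p.adjust(method = "BH")} and a
#' hypothesis is rejected when its adjusted p is at most \code{q} (boundary
#' inclusive).
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return list with \code{reject} (logical) and \code{adjusted} (numeric),
#'   both empty for empty input.
#' @export
fdrBh <- function(pValues, q = 0.05) {
  if (!length(pValues)) return(list(reject = logical(0),
                                    adjusted = numeric(0)))
  if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pValues, method = "BH")
  list(reject = adj <= q, adjusted = adj)
}

#' Two-sided paired t-tests, column by column
#'
#' @param a,b subjects x conditions matrices (or vectors) of equal shape,
#'   n >= 2 subjects.
#' @return data.frame with columns \code{comparison}, \code{t}, \code{dof},
#'   \code{p}, \code{degenerate}; zero-variance differences give t = 0,
#'   p = 1 and a degenerate flag instead of an error.
#' @export
pairedTests <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("'a' and 'b' must have equal shape")
  if (nrow(a) < 2) stop("need at least two subjects")
  cols <- colnames(a)
  if (is.null(cols)) cols <- paste0("cond", seq_len(ncol(a)))
  out <- lapply(seq_len(ncol(a)), function(j) {
    d <- a[, j] - b[, j]
    if (stats::sd(d) == 0)
      return(data.frame(comparison = cols[j], t = 0,
                        dof = length(d) - 1, p = 1, degenerate = TRUE))
    tt <- stats::t.test(a[, j], b[, j], paired = TRUE)
    data.frame(comparison = cols[j], t = unname(tt$statistic),
               dof = unname(tt$parameter), p = tt$p.value,
               degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Long-format model-comparison table
#'
#' Assembles per-subject, per-model, per-band mean cross-validated scores and
#' their increments over a base model into the tidy long table that a
#' mixed-model analysis of score differences consumes.
#'
#' @param scoreList nested list: \code{scoreList[[subject]][[model]]} is a
#'   \linkS4class{ScoreTable}.
#' @param baseModel name of the reference model for the increment column.
#' @return data.frame with columns \code{subject}, \code{model}, \code{band},
#'   \code{score}, \code{increment} (score minus the subject's base-model
#'   score in the same band). Missing cells yield NA and a message.
#' @export
modelTable <- function(scoreList, baseModel = "Base") {
  subjects <- names(scoreList)
  if (is.null(subjects)) subjects <- paste0("subj", seq_along(scoreList))
  models <- unique(unlist(lapply(scoreList, names)))
  rows <- list()
  for (s in seq_along(scoreList)) {
    tabs <- scoreList[[s]]
    baseScores <- list()
    if (baseModel %in% names(tabs))
      baseScores[[tabs[[baseModel]]@band]] <- meanScore(tabs[[baseModel]])
    for (m in models) {
      if (!m %in% names(tabs)) {
        message("missing cell: subject ", subjects[s], ", model ", m)
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects[s], model = m, band = NA_character_,
          score = NA_real_, increment = NA_real_)
        next
      }
      st <- tabs[[m]]
      sc <- meanScore(st)
      base <- baseScores[[st@band]]
      rows[[length(rows) + 1]] <- data.frame(
        subject = subjects[s], model = m, band = st@band, score = sc,
        increment = if (is.null(base)) NA_real_ else sc - base)
    }
  }
  do.call(rbind, rows)
}
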