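#' Load a word-event table from TSV
#'
#' Reads and validates a tab-separated event table with a header row,
#' required columns \code{story_id} and \code{onset_s}, and one column per
#' word-level feature. Validation problems (missing columns, non-numeric
#' values, unsorted or duplicated onsets within a story, negative surprisal,
#' entropy or close, depth below 1) are collected and reported together.
#'
#' @param path TSV file path.
#' @return validated data.frame, sorted by story then onset.
#' @export
loadEvents <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateEvents(ev)
}

#' Validate a word-event table
#'
#' @param ev data.frame as described in \code{\link{loadEvents}}.
#' @return the table, sorted by story then onset, or an error itemising
#'   every problem found.
#' @export
validateEvents <- function(ev) {
  probs <- character(0)
  for (col in c("story_id", "onset_s"))
    if (!col %in% names(ev)) probs <- c(probs, paste("missing column", col))
  if (!length(probs)) {
    if (!is.numeric(ev$onset_s)) probs <- c(probs, "onset_s is not numeric")
    featCols <- setdiff(names(ev), c("story_id", "onset_s"))
    for (f in featCols) {
      if (!is.numeric(ev[[f]])) {
        probs <- c(probs, paste("feature", f, "is not numeric")); next
      }
      if (any(!is.finite(ev[[f]])))
        probs <- c(probs, paste("feature", f, "has non-finite values"))
      if (f %in% c("surprisal", "entropy", "close") && any(ev[[f]] < 0))
        probs <- c(probs, paste("feature", f, "has negative values"))
      if (f == "depth" && any(ev[[f]] < 1))
        probs <- c(probs, "feature depth has values below 1")
    }
    if (is.numeric(ev$onset_s)) {
      ev <- ev[order(ev$story_id, ev$onset_s), , drop = FALSE]
      for (sid in unique(ev$story_id)) {
        o <- ev$onset_s[ev$story_id == sid]
        dup <- base::which(diff(o) == 0)
        if (length(dup))
          probs <- c(probs, paste0("duplicated onset ", o[dup[1]],
                                   " s in story '", sid, "' (row ", dup[1] + 1,
                                   " of that story)"))
        if (any(o < 0))
          probs <- c(probs, paste0("negative onset in story '", sid, "'"))
      }
    }
  }
  if (length(probs))
    stop("event-table validation failed:\n  - ",
         paste(probs, collapse = "\n  - "))
  rownames(ev) <- NULL
  ev
}

#' Write a word-event table to TSV
#'
#' @param events data.frame with columns \code{story_id}, \code{onset_s} and
#'   feature columns.
#' @param path output file path.
#' @return \code{path}, invisibly. Values round-trip at full precision
#'   (written with 17 significant digits).
#' @export
writeEvents <- function(events, path) {
  fmt <- events
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]])) fmt[[j]] <- formatC(fmt[[j]], digits = 17,
                                                  format = "g")
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 8/16/32-bit PCM audio.
#' Multichannel files are averaged to mono.
#'
#' @param path WAV file path.
#' @return list with \code{wave} (numeric samples scaled to [-1, 1]) and
#'   \code{fs} (sampling rate in Hz).
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels = sum(as.integer(raw[3:4]) * c(1, 256)),
        fs = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else invisible(readBin(con, "raw", sz))
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt or data chunk")
  if (fmt$audioFormat != 1) stop("only uncompressed PCM supported")
  bytes <- fmt$bits / 8
  n <- length(data) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8" = (as.numeric(readBin(data, "integer", n, 1, signed = FALSE)) -
             128) / 128,
    "16" = as.numeric(readBin(data, "integer", n, 2, signed = TRUE,
                              endian = "little")) / 32768,
    "32" = as.numeric(readBin(data, "integer", n, 4, endian = "little")) /
             2147483648,
    stop("unsupported bit depth: ", fmt$bits))
  if (fmt$nChannels > 1) {
    x <- matrix(x, nrow = fmt$nChannels)
    x <- colMeans(x)
  }
  list(wave = x, fs = fmt$fs)
}

#' Write a mono PCM WAV file
#'
#' @param wave numeric samples in [-1, 1] (clipped otherwise).
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @param bits bit depth (16 only).
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(wave, fs, path, bits = 16) {
  if (bits != 16) stop("only 16-bit output supported")
  x <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}

#' Serialise a recording container
#'
#' Writes a \linkS4class{ContinuousRecording} (signal, sampling rate,
#' channel labels, story boundaries and provenance) to a single portable
#' file via R serialisation.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  saveRDS(list(format = "trfpac-recording", version = 1L,
               signal = rec@signal, fs = rec@fs,
               channelNames = rec@channelNames, stories = rec@stories,
               provenance = rec@provenance), path)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "trfpac-recording"))
    stop("not a recording container: ", path)
  ContinuousRecording(obj$signal, obj$fs, obj$channelNames, obj$stories,
                      obj$provenance)
}
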