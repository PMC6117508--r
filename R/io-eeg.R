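#' Read a multichannel EEG recording
#'
#' Dispatches on file extension: \code{.edf} (European Data Format,
#' including EDF+ annotations) or \code{.vhdr} (BrainVision triplet
#' \code{.vhdr}/\code{.vmrk}/\code{.eeg}). Signals are returned in
#' microvolts, scaled by the format's calibration fields; annotations and
#' markers are mapped into the event table with onsets in seconds from
#' recording start.
#'
#' @param path path to a \code{.edf} or \code{.vhdr} file.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEEG <- function(path) {
  if (!file.exists(path)) stop("EEG file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = readEDF(path),
         vhdr = readBrainVision(path),
         stop("unsupported EEG format '.", ext,
              "'; supported: .edf, .vhdr"))
}

## ---- EDF ------------------------------------------------------------------

edfField <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' @rdname readEEG
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edfField(con, 8L)                      # version
  edfField(con, 80L); edfField(con, 80L) # patient / recording id
  edfField(con, 8L); edfField(con, 8L)   # date / time
  edfField(con, 8L)                      # header bytes
  edfField(con, 44L)                     # reserved ("EDF+C" when EDF+)
  nRec <- as.integer(edfField(con, 8L))
  recDur <- as.numeric(edfField(con, 8L))
  ns <- as.integer(edfField(con, 4L))
  if (!is.finite(ns) || ns < 1L)
    stop("EDF header field 'number of signals' is unreadable in ", path)
  lab <- vapply(seq_len(ns), function(i) edfField(con, 16L), "")
  for (i in seq_len(ns)) edfField(con, 80L)            # transducer
  unit <- vapply(seq_len(ns), function(i) edfField(con, 8L), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) edfField(con, 8L), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) edfField(con, 8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) edfField(con, 8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) edfField(con, 8L), ""))
  for (i in seq_len(ns)) edfField(con, 80L)            # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) edfField(con, 8L), ""))
  for (i in seq_len(ns)) edfField(con, 32L)            # reserved
  if (anyNA(c(nRec, recDur, nsamp)))
    stop("EDF header of ", path, " has unreadable record-count/duration/",
         "samples-per-record fields")

  isAnn <- lab == "EDF Annotations"
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", nRec)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        raw[[i]][[r]] <- readBin(con, "raw", n = 2L * nsamp[i])
      } else {
        raw[[i]][[r]] <- readBin(con, "integer", n = nsamp[i], size = 2L,
                                 signed = TRUE, endian = "little")
      }
    }
  }

  sig <- lapply(which(!isAnn), function(i) {
    x <- unlist(raw[[i]], use.names = FALSE)
    scale <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    phys <- (x - dmin[i]) * scale + pmin_[i]
    u <- tolower(unit[i])
    if (u %in% c("mv")) phys <- phys * 1e3
    if (u %in% c("v")) phys <- phys * 1e6
    phys
  })
  srates <- nsamp[!isAnn] / recDur
  if (length(unique(srates)) > 1L)
    stop("EDF signals with mixed sampling rates are not supported")
  signals <- do.call(rbind, sig)

  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       type = character(0), stringsAsFactors = FALSE)
  if (any(isAnn))
    events <- parseEDFAnnotations(unlist(raw[[which(isAnn)[1L]]],
                                         use.names = FALSE))
  dur <- ncol(signals) / srates[1L]
  events <- events[events$onset <= dur, , drop = FALSE]
  new("EEGRecording", signals = signals, srate = srates[1L],
      channelLabels = lab[!isAnn],
      events = events[order(events$onset), , drop = FALSE],
      reference = "original")
}

## Parse EDF+ time-stamped annotation lists from the raw annotation-channel
## bytes: each TAL is "+onset[<21>duration]<20>text1<20>text2...<20><0>"
## (byte values in angle brackets); the bare record-keeping TAL carries no
## text and is skipped. TALs are NUL-separated, so splitting happens on the
## raw vector before any character conversion.
parseEDFAnnotations <- function(bytes) {
  nulAt <- bytes == as.raw(0L)
  grp <- cumsum(c(TRUE, nulAt[-length(nulAt)]))
  chunks <- split(bytes[!nulAt], grp[!nulAt])
  out <- list()
  for (ck in chunks) {
    if (!length(ck)) next
    chunk <- rawToChar(ck)
    parts <- strsplit(chunk, "\x14", fixed = TRUE)[[1L]]
    if (length(parts) < 2L || !nzchar(parts[2L])) next
    head_ <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1L]]
    onset <- as.numeric(head_[1L])
    durat <- if (length(head_) > 1L) as.numeric(head_[2L]) else 0
    for (txt in parts[-1L])
      if (nzchar(txt))
        out[[length(out) + 1L]] <- data.frame(onset = onset,
                                              duration = durat, type = txt,
                                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

padField <- function(x, n) formatC(substr(x, 1L, n), width = -n)

#' Write an EEGRecording as EDF+
#'
#' Writes a single-data-record EDF+C file with one annotation channel
#' carrying the event table. Signals are quantised to 16 bit over each
#' channel's physical range, so the round trip is exact to about
#' range/65534 microvolts.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param path output \code{.edf} path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(eeg, path) {
  sig <- eeg@signals
  C <- nrow(sig); S <- ncol(sig)
  ev <- eeg@events
  nul <- as.raw(0L)
  annBytes <- c(charToRaw("+0\x14\x14"), nul)
  if (nrow(ev))
    for (i in seq_len(nrow(ev))) {
      durPart <- if (ev$duration[i] > 0)
        sprintf("\x15%.7g", ev$duration[i]) else ""
      annBytes <- c(annBytes,
                    charToRaw(sprintf("+%.7g%s\x14%s\x14", ev$onset[i],
                                      durPart, ev$type[i])), nul)
    }
  annLen <- 2L * ceiling((length(annBytes) + 16L) / 2L)
  annBytes <- c(annBytes, raw(annLen - length(annBytes)))

  pmin_ <- apply(sig, 1L, min); pmax_ <- apply(sig, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  ns <- C + 1L
  recDur <- S / eeg@srate
  headerBytes <- 256L * (ns + 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(padField(x, n), con, nchars = n, eos = NULL)
  wr("0", 8L); wr("synthetic", 80L); wr("synthetic", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(as.character(headerBytes), 8L); wr("EDF+C", 44L)
  wr("1", 8L); wr(sprintf("%.7g", recDur), 8L); wr(as.character(ns), 4L)
  for (l in eeg@channelLabels) wr(l, 16L); wr("EDF Annotations", 16L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(C)) wr("uV", 8L); wr("", 8L)
  for (v in pmin_) wr(sprintf("%.7g", v), 8L); wr("-1", 8L)
  for (v in pmax_) wr(sprintf("%.7g", v), 8L); wr("1", 8L)
  for (i in seq_len(ns)) wr("-32768", 8L)
  for (i in seq_len(ns)) wr("32767", 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(C)) wr(as.character(S), 8L)
  wr(as.character(annLen %/% 2L), 8L)
  for (i in seq_len(ns)) wr("", 32L)
  for (i in seq_len(C)) {
    dig <- round((sig[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 -
                 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
             endian = "little")
  }
  writeBin(annBytes, con)
  invisible(path)
}

## ---- BrainVision ----------------------------------------------------------

bvSection <- function(lines, name) {
  starts <- grep("^\\[", lines)
  i <- grep(paste0("^\\[", name, "\\]$"), lines, ignore.case = TRUE)
  if (!length(i)) return(character(0))
  nxt <- starts[starts > i[1L]]
  end <- if (length(nxt)) nxt[1L] - 1L else length(lines)
  lines[(i[1L] + 1L):end]
}

bvKeyValues <- function(lines) {
  lines <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^;", lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(vapply(kv, function(x) trimws(x[2L]), ""),
                  vapply(kv, function(x) trimws(x[1L]), ""))
}

#' @rdname readEEG
#' @export
readBrainVision <- function(path) {
  hdrLines <- readLines(path, warn = FALSE, encoding = "latin1")
  common <- bvKeyValues(bvSection(hdrLines, "Common Infos"))
  binary <- bvKeyValues(bvSection(hdrLines, "Binary Infos"))
  chan <- bvKeyValues(bvSection(hdrLines, "Channel Infos"))
  dataFile <- file.path(dirname(path), common[["DataFile"]])
  markerFile <- if ("MarkerFile" %in% names(common))
    file.path(dirname(path), common[["MarkerFile"]]) else NA_character_
  if (!file.exists(dataFile))
    stop("BrainVision data file missing: ", dataFile,
         " (named by ", path, ")")
  C <- as.integer(common[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(common[["SamplingInterval"]])
  orient <- toupper(common[["DataOrientation"]])
  fmt <- toupper(binary[["BinaryFormat"]])

  chParts <- lapply(chan[paste0("Ch", seq_len(C))],
                    function(x) strsplit(x, ",", fixed = TRUE)[[1L]])
  labels <- vapply(chParts, `[`, "", 1L)
  resol <- vapply(chParts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1, 0)

  sz <- file.info(dataFile)$size
  con <- file(dataFile, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    x <- readBin(con, "numeric", n = sz %/% 4L, size = 4L,
                 endian = "little")
  } else if (fmt == "INT_16") {
    x <- readBin(con, "integer", n = sz %/% 2L, size = 2L, signed = TRUE,
                 endian = "little")
  } else stop("unsupported BrainVision BinaryFormat: ", fmt)
  S <- length(x) %/% C
  signals <- if (orient == "MULTIPLEXED")
    matrix(x[seq_len(C * S)], nrow = C) else
    t(matrix(x[seq_len(C * S)], ncol = C))
  signals <- signals * resol

  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       type = character(0), stringsAsFactors = FALSE)
  if (!is.na(markerFile)) {
    if (!file.exists(markerFile))
      stop("BrainVision marker file missing: ", markerFile,
           " (named by ", path, ")")
    mk <- bvKeyValues(bvSection(readLines(markerFile, warn = FALSE,
                                          encoding = "latin1"),
                                "Marker Infos"))
    mk <- mk[grepl("^Mk[0-9]+$", names(mk))]
    if (length(mk)) {
      rows <- lapply(mk, function(m) {
        p <- strsplit(m, ",", fixed = TRUE)[[1L]]
        if (toupper(p[1L]) == "NEW SEGMENT") return(NULL)
        data.frame(onset = (as.numeric(p[3L]) - 1) / srate,
                   duration = as.numeric(p[4L]) / srate,
                   type = if (nzchar(trimws(p[2L]))) trimws(p[2L]) else
                     trimws(p[1L]),
                   stringsAsFactors = FALSE)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) events <- do.call(rbind, rows)
    }
  }
  new("EEGRecording", signals = signals, srate = srate,
      channelLabels = unname(labels),
      events = events[order(events$onset), , drop = FALSE],
      reference = "original")
}

#' Write an EEGRecording as a BrainVision triplet
#'
#' Multiplexed IEEE float-32 data file plus text header and marker files.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param path output \code{.vhdr} path; companions take the same stem.
#' @return \code{path}, invisibly.
#' @export
writeBrainVision <- function(eeg, path) {
  stem <- sub("\\.vhdr$", "", basename(path))
  dir_ <- dirname(path)
  dataName <- paste0(stem, ".eeg"); markName <- paste0(stem, ".vmrk")
  C <- nrow(eeg@signals)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", dataName),
           paste0("MarkerFile=", markName),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", C),
           sprintf("SamplingInterval=%.10g", 1e6 / eeg@srate),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(C), eeg@channelLabels))
  writeLines(hdr, file.path(dir_, basename(path)))
  ev <- eeg@events
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", dataName),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,0")
  if (nrow(ev))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,%d,0", seq_len(nrow(ev)) + 1L,
                        ev$type, round(ev$onset * eeg@srate) + 1L,
                        round(ev$duration * eeg@srate)))
  writeLines(mk, file.path(dir_, markName))
  con <- file(file.path(dir_, dataName), "wb")
  writeBin(as.numeric(eeg@signals), con, size = 4L, endian = "little")
  close(con)
  invisible(path)
}
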