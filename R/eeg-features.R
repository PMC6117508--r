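#' Re-reference an EEG recording
#'
#' Subtracts, sample by sample, either the mean of all channels (average
#' reference) or the mean of a named channel set (e.g. Cz, or linked
#' mastoids) from every channel. Re-referencing to the same target is
#' idempotent.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param mode "average", or "channels" with \code{channels} naming the
#'   new reference set.
#' @param channels channel labels of the new reference (mode "channels").
#' @return the re-referenced \linkS4class{EEGRecording}.
#' @export
rereference <- function(eeg, mode = c("average", "channels"),
                        channels = NULL) {
  mode <- match.arg(mode)
  sig <- eeg@signals
  if (mode == "average") {
    ref <- colMeans(sig)
    tag <- "average"
  } else {
    if (is.null(channels) || !length(channels))
      stop("mode 'channels' needs at least one channel label")
    miss <- setdiff(channels, eeg@channelLabels)
    if (length(miss))
      stop("unknown reference channel(s): ", paste(miss, collapse = ", "),
           "; available: ", paste(eeg@channelLabels, collapse = ", "))
    rows <- match(channels, eeg@channelLabels)
    ref <- colMeans(sig[rows, , drop = FALSE])
    tag <- paste(channels, collapse = "+")
  }
  eeg@signals <- sweep(sig, 2L, ref)
  eeg@reference <- tag
  eeg
}

#' Zero-phase filter EEG channels
#'
#' Band/low/high-pass filtering per channel, leaving events and bad blocks
#' untouched. Method "fir" uses a windowed-sinc FIR applied
#' forward-backward (zero phase); method "fft" zeroes out-of-band Fourier
#' coefficients exactly (the ideal filter). \code{low = 0} gives a
#' low-pass, \code{high} at Nyquist a high-pass.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param low,high band edges in Hz within [0, srate/2].
#' @param method "fir" or "fft".
#' @param order FIR order; default about 3 x srate / low edge (or / the
#'   transition-setting edge for low-pass), forced even so the
#'   forward-backward kernel is symmetric.
#' @return the filtered \linkS4class{EEGRecording}.
#' @export
filterEEG <- function(eeg, low, high, method = c("fir", "fft"),
                      order = NULL) {
  method <- match.arg(method)
  nyq <- eeg@srate / 2
  if (low < 0 || high <= low || high > nyq + 1e-9)
    stop("band [", low, ", ", high, "] must satisfy 0 <= low < high <= ",
         "Nyquist (", nyq, " Hz)")
  sig <- eeg@signals
  if (method == "fft") {
    out <- t(idealBandpass(t(sig), low, high, tr = 1 / eeg@srate))
  } else {
    edge <- if (low > 0) low else high
    if (is.null(order)) order <- min(2L * (ncol(sig) %/% 6L) - 2L,
                                     2L * ceiling(1.5 * eeg@srate / edge))
    order <- max(4L, 2L * (order %/% 2L))
    w <- c(low, high) / nyq
    flt <- if (low <= 0) signal::fir1(order, w[2L], type = "low")
           else if (high >= nyq - 1e-9)
             signal::fir1(order, w[1L], type = "high")
           else signal::fir1(order, w, type = "pass")
    out <- t(apply(sig, 1L, function(ch) signal::filtfilt(flt, ch)))
  }
  eeg@signals <- out
  eeg
}

#' Add and delete events programmatically
#'
#' Deletions are applied first (by row index into the current table), then
#' additions; the result is re-sorted by onset. Duplicate events are
#' allowed.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param add data.frame with columns onset, duration, type (optional).
#' @param delete integer row indices to remove (optional).
#' @return the \linkS4class{EEGRecording} with the edited event table.
#' @export
editEvents <- function(eeg, add = NULL, delete = NULL) {
  ev <- eeg@events
  if (!is.null(delete) && length(delete)) {
    delete <- as.integer(delete)
    if (any(delete < 1L) || any(delete > nrow(ev)))
      stop("delete indices out of range 1..", nrow(ev))
    ev <- ev[-delete, , drop = FALSE]
  }
  if (!is.null(add) && nrow(add)) {
    add <- data.frame(onset = as.numeric(add$onset),
                      duration = as.numeric(add$duration),
                      type = as.character(add$type),
                      stringsAsFactors = FALSE)
    ev <- rbind(ev, add)
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  eeg@events <- ev
  validObject(eeg)
  eeg
}

#' Mark bad blocks
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param blocks n x 2 matrix (or 2-vector) of [start_s, end_s) intervals.
#' @return the \linkS4class{EEGRecording} with the blocks appended.
#' @export
markBadBlocks <- function(eeg, blocks) {
  blocks <- matrix(as.numeric(blocks), ncol = 2L)
  eeg@badBlocks <- rbind(eeg@badBlocks, blocks)
  validObject(eeg)
  eeg
}

#' Extract event onsets as a feature series
#'
#' Onsets (seconds) of events whose type is in \code{eventTypes}, each
#' with unit value; events falling inside any bad block are dropped when
#' \code{excludeBad}.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param eventTypes character vector of types to keep; NULL keeps all.
#' @param excludeBad drop events inside bad blocks (default TRUE).
#' @return a \linkS4class{FeatureSeries} of kind "onsets".
#' @export
extractOnsets <- function(eeg, eventTypes = NULL, excludeBad = TRUE) {
  ev <- eeg@events
  if (!is.null(eventTypes)) ev <- ev[ev$type %in% eventTypes, , drop = FALSE]
  if (excludeBad && nrow(ev))
    ev <- ev[!inAnyBlock(ev$onset, ev$onset, eeg@badBlocks), ,
             drop = FALSE]
  new("FeatureSeries", kind = "onsets", times = ev$onset,
      values = rep(1, nrow(ev)), trLocked = FALSE)
}

## One-sided DFT band power of a windowed signal, after the convention
## p_k = 2 |Y_k|^2 / L for interior bins, with DC and (for even L) the
## Nyquist bin undoubled.
windowBandPower <- function(x, srate, band) {
  L <- length(x)
  Y <- stats::fft(x)
  half <- floor(L / 2)
  k <- 0:half
  p <- Mod(Y[k + 1L])^2 / L
  interior <- k > 0L & !(L %% 2L == 0L & k == half)
  p[interior] <- 2 * p[interior]
  f <- k * srate / L
  inBand <- f >= band[1L] - 1e-12 & f <= band[2L] + 1e-12
  if (band[1L] > 0) inBand[1L] <- FALSE
  if (!any(inBand))
    stop("band [", band[1L], ", ", band[2L], "] Hz contains no DFT bin ",
         "at resolution ", srate / L, " Hz; widen the band or the window")
  sum(p[inBand])
}

#' Windowed EEG band power
#'
#' Sliding-window spectral power: per window of L samples the one-sided
#' DFT power 2 |Y_k|^2 / L is summed over the bins whose frequency lies
#' inside the band, then averaged over the selected channels. Windows
#' overlapping a bad block get NA (flagged missing). With
#' \code{window = step = TR} the series is locked to the fMRI time grid,
#' one value per volume.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param band length-2 frequency band in Hz.
#' @param channels labels to average over; NULL = all channels.
#' @param window,step window length and step in seconds.
#' @return a \linkS4class{FeatureSeries} of kind "power"; times are
#'   window starts; \code{trLocked} is set when window == step.
#' @export
extractBandPower <- function(eeg, band, channels = NULL, window, step) {
  if (band[2L] > eeg@srate / 2 + 1e-9)
    stop("band exceeds Nyquist (", eeg@srate / 2, " Hz)")
  rows <- if (is.null(channels)) seq_len(nrow(eeg@signals)) else {
    miss <- setdiff(channels, eeg@channelLabels)
    if (length(miss)) stop("unknown channel(s): ",
                           paste(miss, collapse = ", "))
    match(channels, eeg@channelLabels)
  }
  L <- round(window * eeg@srate)
  stepn <- round(step * eeg@srate)
  S <- ncol(eeg@signals)
  if (L > S) stop("window (", window, " s) exceeds the recording")
  starts <- seq(0L, S - L, by = stepn)
  t0 <- starts / eeg@srate
  bad <- inAnyBlock(t0, t0 + window, eeg@badBlocks)
  vals <- vapply(seq_along(starts), function(i) {
    if (bad[i]) return(NA_real_)
    mean(vapply(rows, function(r)
      windowBandPower(eeg@signals[r, (starts[i] + 1L):(starts[i] + L)],
                      eeg@srate, band), 0))
  }, 0)
  new("FeatureSeries", kind = "power", times = t0, values = vals,
      trLocked = isTRUE(all.equal(window, step)), band = as.numeric(band))
}

#' Event-locked (ERP) amplitudes
#'
#' Per matching event: the epoch \code{epochWindow} (seconds relative to
#' onset) is cut from one channel, the mean over \code{baseline} is
#' subtracted, and the amplitude is the mean — or the signed extremum,
#' mode "peak" — within \code{measureWindow}. Events whose epoch leaves
#' the recording are dropped with a warning; events overlapping a bad
#' block are dropped silently. An externally computed component time
#' series can stand in for a channel via \code{componentSignal}.
#'
#' @param eeg an \linkS4class{EEGRecording}.
#' @param eventType event type to epoch on.
#' @param channel channel label (ignored when \code{componentSignal}
#'   given).
#' @param epochWindow length-2 epoch limits in s relative to onset.
#' @param measureWindow length-2 measurement window in s within the epoch.
#' @param mode "mean" or "peak" (signed extremum).
#' @param baseline length-2 baseline window in s (default c(-0.2, 0)).
#' @param componentSignal optional numeric vector (one sample per EEG
#'   sample) used instead of a recorded channel.
#' @return a \linkS4class{FeatureSeries} of kind "amplitude"; times are
#'   the surviving event onsets.
#' @export
extractERPAmplitudes <- function(eeg, eventType, channel = NULL,
                                 epochWindow, measureWindow,
                                 mode = c("mean", "peak"),
                                 baseline = c(-0.2, 0),
                                 componentSignal = NULL) {
  mode <- match.arg(mode)
  if (any(measureWindow < epochWindow[1L]) ||
      any(measureWindow > epochWindow[2L]))
    stop("measure window must lie within the epoch window")
  x <- if (!is.null(componentSignal)) {
    if (length(componentSignal) != ncol(eeg@signals))
      stop("componentSignal must have one sample per EEG sample")
    as.numeric(componentSignal)
  } else {
    if (is.null(channel)) stop("give a channel label or componentSignal")
    r <- match(channel, eeg@channelLabels)
    if (is.na(r)) stop("unknown channel: ", channel)
    eeg@signals[r, ]
  }
  ev <- eeg@events[eeg@events$type == eventType, , drop = FALSE]
  if (!nrow(ev)) stop("no events of type '", eventType, "'")
  sr <- eeg@srate
  S <- length(x)
  keep <- logical(nrow(ev)); vals <- numeric(nrow(ev))
  dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]
    i0 <- round((on + epochWindow[1L]) * sr)
    i1 <- round((on + epochWindow[2L]) * sr)
    if (i0 < 0L || i1 >= S) { dropped <- dropped + 1L; next }
    if (inAnyBlock(on + epochWindow[1L], on + epochWindow[2L],
                   eeg@badBlocks)) next
    b0 <- round((on + baseline[1L]) * sr); b1 <- round((on + baseline[2L]) * sr)
    b0 <- max(b0, i0); b1 <- min(b1, i1)
    base <- mean(x[(b0 + 1L):(b1 + 1L)])
    m0 <- round((on + measureWindow[1L]) * sr)
    m1 <- round((on + measureWindow[2L]) * sr)
    seg <- x[(m0 + 1L):(m1 + 1L)] - base
    vals[i] <- if (mode == "mean") mean(seg) else seg[which.max(abs(seg))]
    keep[i] <- TRUE
  }
  if (dropped)
    warning(dropped, " event(s) dropped: epoch extends outside recording")
  new("FeatureSeries", kind = "amplitude", times = ev$onset[keep],
      values = vals[keep], trLocked = FALSE)
}

#' Write / read a feature series as TSV
#'
#' Three columns: time_s, value, flag (1 = missing/bad, value empty).
#'
#' @param feature a \linkS4class{FeatureSeries}.
#' @param path TSV path.
#' @return \code{path} / the \linkS4class{FeatureSeries}.
#' @export
writeFeatureSeries <- function(feature, path) {
  utils::write.table(
    data.frame(time_s = feature@times, value = feature@values,
               flag = as.integer(is.na(feature@values))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureSeries
#' @param kind,trLocked,band metadata to restore (TSV stores data only).
#' @export
readFeatureSeries <- function(path, kind = "power", trLocked = FALSE,
                              band = numeric(0)) {
  tab <- utils::read.delim(path)
  new("FeatureSeries", kind = kind, times = as.numeric(tab$time_s),
      values = as.numeric(tab$value), trLocked = trLocked,
      band = as.numeric(band))
}
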