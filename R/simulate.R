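#' Synthetic 4D BOLD volume with known ground truth
#'
#' Generates the study conditions every fMRI pipeline in the package is
#' tested against: AR(1)-plus-white background noise at a grand-mean
#' offset of 1000 (so intensity-based masking and grand-mean
#' normalisation behave as on real data); optional hub clusters whose
#' members share a latent series mixed to hit a target pairwise
#' correlation r (member = sqrt(r) latent + sqrt(1 - r) noise); and
#' optional activated voxels carrying beta times the event train
#' convolved with a single-gamma HRF of the given peak latency, sampled
#' on the TR grid. Identical seeds give bit-identical volumes.
#'
#' @param shape spatial grid, length-3 integer (>= 6 each for
#'   neighbourhood measures).
#' @param T_ number of volumes (default 250, a standard ~8 min run at
#'   TR 2 s).
#' @param tr repetition time in seconds (default 2).
#' @param seed RNG seed.
#' @param hubs list of n x 3 integer matrices of voxel ijk coordinates.
#' @param hubR target pairwise correlation per hub (recycled; < 0.99).
#' @param activation n x 3 integer matrix of activated voxels.
#' @param onsets event times in seconds (used when activation given).
#' @param peak true HRF peak latency in seconds (default 5).
#' @param beta activation amplitude (signal SD is about
#'   beta * sd(regressor); beta = 0 embeds a null).
#' @param ar1 AR(1) coefficient of the background (default 0.3).
#' @param sigma noise SD (default 1).
#' @param offset grand-mean offset (default 1000).
#' @return list with vol (\linkS4class{Volume4D}), mask (full-grid
#'   \linkS4class{BrainMask}) and truth (\linkS4class{SimTruth}).
#' @export
simulateBold <- function(shape = c(8, 8, 8), T_ = 250, tr = 2, seed = 1,
                         hubs = list(), hubR = 0.6,
                         activation = NULL, onsets = numeric(0), peak = 5,
                         beta = 0, ar1 = 0.3, sigma = 1, offset = 1000) {
  if (any(hubR >= 0.99))
    stop("hub correlation targets above 0.99 are not attainable")
  set.seed(seed)
  shape <- as.integer(shape)
  nvox <- prod(shape)
  ar <- function(n) {
    e <- stats::rnorm(n * T_)
    m <- matrix(e, T_, n)
    if (ar1 != 0) m <- apply(m, 2L, function(x)
      as.numeric(stats::filter(x, ar1, method = "recursive")))
    m * sigma * sqrt(1 - ar1^2)
  }
  dat <- ar(nvox)                                    # T x V
  hubR <- rep_len(hubR, max(1L, length(hubs)))
  for (h in seq_along(hubs)) {
    ijk <- hubs[[h]]
    li <- ijk[, 1L] + (ijk[, 2L] - 1L) * shape[1L] +
      (ijk[, 3L] - 1L) * prod(shape[1:2])
    latent <- as.numeric(scale(ar(1L)))
    r <- hubR[h]
    for (v in li)
      dat[, v] <- sigma * (sqrt(r) * latent +
                           sqrt(1 - r) * as.numeric(scale(dat[, v])))
  }
  truthAct <- matrix(integer(0), ncol = 3L)
  if (!is.null(activation) && nrow(activation) && length(onsets)) {
    fs <- new("FeatureSeries", kind = "onsets", times = sort(onsets),
              values = rep(1, length(onsets)), trLocked = FALSE)
    reg <- buildRegressor(fs, hrfKernel("single_gamma", dt = tr / 16,
                                        peak = peak), tr, T_)
    li <- activation[, 1L] + (activation[, 2L] - 1L) * shape[1L] +
      (activation[, 3L] - 1L) * prod(shape[1:2])
    for (v in li) dat[, v] <- dat[, v] + beta * reg
    truthAct <- activation
  }
  dat <- dat + offset
  vol <- new("Volume4D", data = array(t(dat), dim = c(shape, T_)), tr = tr,
             voxelSize = c(3, 3, 3), affine = diag(c(3, 3, 3, 1)),
             spaceTag = "synthetic")
  mask <- new("BrainMask", flags = array(TRUE, shape))
  truth <- new("SimTruth", hubs = hubs, hubR = hubR,
               activation = truthAct, peak = peak, beta = beta,
               onsets = as.numeric(sort(onsets)), ar1 = ar1, sigma = sigma,
               seed = as.integer(seed))
  list(vol = vol, mask = mask, truth = truth)
}

#' Synthetic head-motion parameters
#'
#' Six smooth random walks (cumulative sums of white noise, lightly
#' smoothed) rescaled so each column's maximum absolute excursion equals
#' \code{amplitude}; zero amplitude gives the zero matrix.
#'
#' @param T_ number of time points (>= 3).
#' @param amplitude maximum excursion (mm / rad).
#' @param seed RNG seed.
#' @return a \linkS4class{MotionParams}.
#' @export
simulateMotion <- function(T_, amplitude = 0.2, seed = 1) {
  if (T_ < 3L) stop("need at least 3 time points")
  set.seed(seed)
  m <- vapply(seq_len(6L), function(j) {
    w <- cumsum(stats::rnorm(T_))
    w <- stats::filter(w, rep(1 / 5, 5), sides = 2L)
    w[is.na(w)] <- 0
    mx <- max(abs(w))
    if (mx == 0) numeric(T_) else as.numeric(w) / mx * amplitude
  }, numeric(T_))
  new("MotionParams", series = matrix(m, ncol = 6L))
}

## Default spike template: biphasic 250 ms wave (sharp negative phase
## then slower positive rebound), unit peak.
defaultSpikeTemplate <- function(srate) {
  t_ <- seq(0, 0.25, by = 1 / srate)
  w <- -sin(2 * pi * t_ / 0.1) * exp(-t_ / 0.05) +
    0.4 * sin(pi * pmax(t_ - 0.05, 0) / 0.2) * exp(-(t_ - 0.05) / 0.15)
  w / max(abs(w))
}

#' Synthetic multichannel EEG
#'
#' Pink-ish background noise (white noise with a 1/sqrt(f) spectral tilt)
#' plus optional band-limited oscillations and scaled spike-like events
#' at the given times; the event table carries the true onsets with type
#' "GSWD". Overlapping spikes are allowed.
#'
#' @param channels number of channels or a label vector.
#' @param duration recording length in seconds.
#' @param srate sampling rate in Hz (default 250).
#' @param spikeTimes event onset times in seconds.
#' @param spikeAmplitude spike scale in microvolts (default 80).
#' @param spikeTemplate waveform (default biphasic 250 ms wave).
#' @param bands list of c(low, high, amplitude) oscillation specs.
#' @param noiseAmplitude background scale in microvolts (default 10).
#' @param seed RNG seed.
#' @return an \linkS4class{EEGRecording}.
#' @export
simulateEEG <- function(channels = 4, duration = 60, srate = 250,
                        spikeTimes = numeric(0), spikeAmplitude = 80,
                        spikeTemplate = NULL,
                        bands = list(), noiseAmplitude = 10, seed = 1) {
  set.seed(seed)
  labels <- if (is.character(channels)) channels else
    paste0("Ch", seq_len(channels))
  C <- length(labels)
  S <- round(duration * srate)
  if (length(spikeTimes) && any(spikeTimes < 0 | spikeTimes >= duration))
    stop("spike times must lie within the recording")
  if (is.null(spikeTemplate)) spikeTemplate <- defaultSpikeTemplate(srate)

  ## 1/sqrt(f)-shaped background, per channel
  f <- pmin(0:(S - 1L), S - (0:(S - 1L))) / (S / srate)
  shape <- c(0, 1 / sqrt(f[-1L]))
  sig <- matrix(0, C, S)
  for (ch in seq_len(C)) {
    w <- stats::fft(stats::rnorm(S)) * shape
    x <- Re(stats::fft(w, inverse = TRUE)) / S
    sig[ch, ] <- x / stats::sd(x) * noiseAmplitude
  }
  for (bd in bands) {
    bw <- matrix(0, C, S)
    for (ch in seq_len(C)) {
      x <- idealBandpass(stats::rnorm(S), bd[1L], bd[2L], tr = 1 / srate)
      bw[ch, ] <- x / stats::sd(x) * bd[3L]
    }
    sig <- sig + bw
  }
  if (length(spikeTimes) && spikeAmplitude != 0) {
    for (t0 in spikeTimes) {
      i0 <- round(t0 * srate)
      ii <- i0 + seq_along(spikeTemplate)
      ii <- ii[ii <= S]
      sig[, ii] <- sig[, ii] +
        rep(spikeAmplitude * spikeTemplate[seq_along(ii)],
            each = C)
    }
  }
  ev <- if (length(spikeTimes))
    data.frame(onset = sort(spikeTimes), duration = 0, type = "GSWD",
               stringsAsFactors = FALSE) else
    data.frame(onset = numeric(0), duration = numeric(0),
               type = character(0), stringsAsFactors = FALSE)
  new("EEGRecording", signals = sig, srate = srate, channelLabels = labels,
      events = ev, reference = "original")
}
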