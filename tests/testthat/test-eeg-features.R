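test_that("re-referencing removes the chosen reference exactly", {
  eeg <- simulateEEG(channels = c("Fz", "Cz", "M1", "M2"), duration = 5,
                     srate = 100, seed = 5)
  avg <- rereference(eeg, "average")
  expect_lt(max(abs(colMeans(eegSignals(avg)))), 1e-10)
  expect_equal(referenceTag(avg), "average")

  cz <- rereference(eeg, "channels", channels = "Cz")
  expect_lt(max(abs(eegSignals(cz)[2, ])), 1e-12)

  lm_ <- rereference(eeg, "channels", channels = c("M1", "M2"))
  expect_lt(max(abs(colMeans(eegSignals(lm_)[3:4, ]))), 1e-12)

  expect_error(rereference(eeg, "channels", channels = "Oz"),
               "unknown reference channel")

  ## idempotence and invariance to a common additive offset
  avg2 <- rereference(avg, "average")
  expect_equal(eegSignals(avg2), eegSignals(avg), tolerance = 1e-12)
  shifted <- eeg; shifted@signals <- eeg@signals + 12.5
  expect_equal(eegSignals(rereference(shifted, "average")),
               eegSignals(avg), tolerance = 1e-10)
})

test_that("zero-phase filters pass and attenuate where designed", {
  srate <- 250; dur <- 20
  tt <- seq(0, dur - 1 / srate, by = 1 / srate)
  mk <- function(f) sin(2 * pi * f * tt)
  eeg <- new("EEGRecording",
             signals = rbind(mk(10), mk(50)), srate = srate,
             channelLabels = c("s10", "s50"))
  a10 <- max(abs(eegSignals(eeg)[1, ]))
  ## FFT method: exact
  fft_ <- filterEEG(eeg, 1, 30, "fft")
  expect_lt(abs(max(abs(eegSignals(fft_)[1, ])) / a10 - 1), 1e-6)
  expect_lt(max(abs(eegSignals(fft_)[2, ])), 1e-6)
  ## FIR method: 1% passband, > 40 dB stopband (edges excluded)
  fir_ <- filterEEG(eeg, 1, 30, "fir")
  core <- seq(srate, length(tt) - srate)
  expect_lt(abs(max(abs(eegSignals(fir_)[1, core])) / a10 - 1), 0.01)
  expect_lt(max(abs(eegSignals(fir_)[2, core])), 10^(-40 / 20))
  ## both agree on broadband noise
  set.seed(6)
  noise <- new("EEGRecording", signals = matrix(rnorm(srate * dur),
                                                nrow = 1),
               srate = srate, channelLabels = "n")
  a <- eegSignals(filterEEG(noise, 1, 30, "fir"))[1, core]
  b <- eegSignals(filterEEG(noise, 1, 30, "fft"))[1, core]
  expect_gt(cor(a, b), 0.99)
  expect_error(filterEEG(eeg, 1, 200, "fft"), "Nyquist")
  ## events and bad blocks untouched
  ev <- editEvents(eeg, add = data.frame(onset = 3, duration = 0,
                                         type = "x"))
  ev <- markBadBlocks(ev, c(1, 2))
  out <- filterEEG(ev, 1, 30, "fft")
  expect_equal(eventTable(out), eventTable(ev))
  expect_equal(badBlocks(out), badBlocks(ev))
})

test_that("event editing adds, deletes and keeps the table sorted", {
  eeg <- simulateEEG(channels = 2, duration = 30, srate = 100, seed = 2)
  e1 <- editEvents(eeg, add = data.frame(onset = 12.5, duration = 0,
                                         type = "1001"))
  expect_true(any(eventTable(e1)$onset == 12.5 &
                  eventTable(e1)$type == "1001"))
  e2 <- editEvents(e1, delete = which(eventTable(e1)$type == "1001"))
  expect_equal(eventTable(e2), eventTable(eeg))

  e3 <- editEvents(eeg, add = data.frame(onset = c(20, 5, 11),
                                         duration = 0, type = "t"))
  expect_false(is.unsorted(eventTable(e3)$onset))
  expect_error(editEvents(eeg, delete = 99), "out of range")
})

test_that("onset extraction drops events inside bad blocks", {
  eeg <- simulateEEG(channels = 2, duration = 40, srate = 100,
                     spikeTimes = c(10, 20, 30), seed = 3)
  eeg <- markBadBlocks(eeg, c(15, 25))
  on <- extractOnsets(eeg, "GSWD")
  expect_equal(featureTimes(on), c(10, 30))
  expect_true(all(featureValues(on) == 1))
  onAll <- extractOnsets(eeg, "GSWD", excludeBad = FALSE)
  expect_equal(featureTimes(onAll), c(10, 20, 30))
  expect_equal(length(featureTimes(extractOnsets(eeg, "nope"))), 0L)

  ## brute-force (event, block) scan agrees
  set.seed(9)
  times <- sort(runif(30, 0, 39.9))
  blocks <- cbind(c(3, 17, 33), c(6, 22, 36))
  e2 <- simulateEEG(channels = 1, duration = 40, srate = 100,
                    spikeTimes = times, seed = 9)
  e2@badBlocks <- blocks
  got <- featureTimes(extractOnsets(e2, "GSWD"))
  keep <- vapply(times, function(tm)
    !any(tm >= blocks[, 1] & tm < blocks[, 2]), TRUE)
  expect_equal(got, times[keep])
})

test_that("band power follows the one-sided 2|Y|^2/L convention", {
  srate <- 250; L <- 500; A <- 7
  tt <- (0:(L - 1)) / srate
  eeg <- new("EEGRecording", signals = matrix(A * sin(2 * pi * 10 * tt),
                                              nrow = 1),
             srate = srate, channelLabels = "Cz")
  bp <- extractBandPower(eeg, c(8, 12), window = 2, step = 2)
  expect_lt(abs(featureValues(bp) / (A^2 * L / 2) - 1), 1e-6)

  zero <- new("EEGRecording", signals = matrix(0, 1, L), srate = srate,
              channelLabels = "Cz")
  expect_equal(featureValues(extractBandPower(zero, c(8, 12), window = 2,
                                              step = 2)), 0)

  ## disjoint partition of (0, Nyquist] sums to the total one-sided power
  set.seed(3)
  x <- rnorm(L)
  eegr <- new("EEGRecording", signals = matrix(x, nrow = 1),
              srate = srate, channelLabels = "Cz")
  tot <- sum(Mod(fft(x))^2 / L) - Mod(fft(x)[1])^2 / L
  parts <- vapply(list(c(1e-9, 30.1), c(30.1, 60.3), c(60.3, 125)),
                  function(bd) featureValues(
                    extractBandPower(eegr, bd, window = 2, step = 2)), 0)
  expect_true(all(parts >= 0))
  expect_lt(abs(sum(parts) - tot) / tot, 1e-8)
  expect_error(extractBandPower(eegr, c(10.01, 10.02), window = 2,
                                step = 2), "no DFT bin")
})

test_that("TR-locked band power yields one value per volume and flags
           bad-block windows", {
  tr <- 2; T_ <- 30
  eeg <- simulateEEG(channels = 2, duration = T_ * tr, srate = 250,
                     seed = 4)
  eeg <- markBadBlocks(eeg, c(10, 13))
  bp <- extractBandPower(eeg, c(8, 12), window = tr, step = tr)
  expect_equal(length(featureValues(bp)), T_)
  expect_true(bp@trLocked)
  expect_true(all(is.na(featureValues(bp)[6:7])))   # windows [10,12),[12,14)
  expect_false(anyNA(featureValues(bp)[-(5:7)]))
})

test_that("ERP amplitudes recover planted peaks and account for drops", {
  srate <- 500; dur <- 60
  sig <- numeric(dur * srate)
  onsets <- c(0.1, 5, 15, 25, 45)                  # first epoch leaves start
  for (o in onsets[-1]) sig[round((o + 0.3) * srate) + 1] <- 10
  eeg <- new("EEGRecording", signals = matrix(sig, nrow = 1),
             srate = srate, channelLabels = "Cz",
             events = data.frame(onset = onsets, duration = 0,
                                 type = "stim"))
  expect_warning(
    amp <- extractERPAmplitudes(eeg, "stim", channel = "Cz",
                                epochWindow = c(-0.2, 0.8),
                                measureWindow = c(0.25, 0.35),
                                mode = "peak"),
    "dropped")
  expect_equal(length(featureValues(amp)), 4L)
  expect_equal(featureValues(amp), rep(10, 4), tolerance = 1e-9)

  ## constant channel, mean mode -> all zero after baseline subtraction
  flat <- new("EEGRecording", signals = matrix(3, 1, dur * srate),
              srate = srate, channelLabels = "Cz",
              events = data.frame(onset = onsets[-1], duration = 0,
                                  type = "stim"))
  a2 <- extractERPAmplitudes(flat, "stim", channel = "Cz",
                             epochWindow = c(-0.2, 0.8),
                             measureWindow = c(0.2, 0.4), mode = "mean")
  expect_equal(featureValues(a2), rep(0, 4))

  ## bad-block epochs excluded from the count
  bb <- markBadBlocks(eeg, c(14, 16))
  expect_warning(
    a3 <- extractERPAmplitudes(bb, "stim", channel = "Cz",
                               epochWindow = c(-0.2, 0.8),
                               measureWindow = c(0.25, 0.35),
                               mode = "peak"))
  expect_equal(length(featureValues(a3)), 3L)
})

test_that("filtering commutes with channel selection", {
  eeg <- simulateEEG(channels = 3, duration = 8, srate = 200, seed = 10)
  whole <- filterEEG(eeg, 1, 30, "fft")
  sub <- eeg
  sub@signals <- eeg@signals[2, , drop = FALSE]
  sub@channelLabels <- eeg@channelLabels[2]
  alone <- filterEEG(sub, 1, 30, "fft")
  expect_equal(eegSignals(whole)[2, ], eegSignals(alone)[1, ],
               tolerance = 1e-10)
})
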