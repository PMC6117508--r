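test_that("HRF kernels peak where their parameterisation says", {
  k5 <- hrfKernel("single_gamma", dt = 0.125, peak = 5)
  expect_lt(abs((which.max(kernelSamples(k5)) - 1) * 0.125 - 5), 0.125 + 1e-9)
  peaks <- vapply(c(3, 5, 7, 9), function(p)
    which.max(kernelSamples(hrfKernel("single_gamma", dt = 0.125,
                                      peak = p))), 0L)
  expect_true(all(diff(peaks) > 0))

  spm <- kernelSamples(hrfKernel("spm_canonical", dt = 0.125))
  expect_equal(max(spm), 1)
  expect_lt(min(spm), 0)                       # undershoot
  expect_gt(which.min(spm), which.max(spm))    # lobe order

  gl <- kernelSamples(hrfKernel("glover", dt = 0.125))
  expect_equal(max(abs(gl)), 1)
  expect_error(hrfKernel("single_gamma", dt = 0.125, peak = -1),
               "positive")
  expect_error(hrfKernel("single_gamma", dt = 0.125), "peak")
})

test_that("regressors are impulse responses sampled at volume starts", {
  tr <- 2; nVols <- 16
  k <- hrfKernel("single_gamma", dt = tr / 16, peak = 5)
  r1 <- buildRegressor(onsetFeature(0), k, tr, nVols)
  ref <- kernelSamples(hrfKernel("single_gamma", dt = tr / 16, peak = 5))
  expect_equal(r1, ref[seq(1, by = 16, length.out = nVols)],
               tolerance = 1e-9)

  ## linearity: two onsets = sum of shifted single-onset columns
  r2 <- buildRegressor(onsetFeature(c(0, 6)), k, tr, nVols)
  rB <- buildRegressor(onsetFeature(6), k, tr, nVols)
  expect_equal(r2, r1 + rB, tolerance = 1e-9)

  ## TR-locked constant series plateaus at c * sum(kernel), checked
  ## against a direct microtime convolution coded from the definition
  c_ <- 2.5
  feat <- new("FeatureSeries", kind = "power",
              times = (0:(nVols - 1)) * tr, values = rep(c_, nVols),
              trLocked = TRUE)
  r3 <- buildRegressor(feat, k, tr, nVols)
  dt <- tr / 16
  u <- rep(c_, nVols * 16)
  h <- kernelSamples(hrfKernel("single_gamma", dt = dt, peak = 5))
  direct <- numeric(nVols * 16)
  for (i in seq_along(direct)) {
    j <- seq_len(min(i, length(h)))
    direct[i] <- sum(u[i - j + 1] * h[j])
  }
  expect_equal(r3, direct[seq(1, by = 16, length.out = nVols)],
               tolerance = 1e-8)
  expect_equal(r3[nVols], c_ * sum(h), tolerance = 1e-6)

  expect_warning(z <- buildRegressor(onsetFeature(numeric(0)), k, tr,
                                     nVols), "empty")
  expect_equal(z, numeric(nVols))
  expect_error(buildRegressor(onsetFeature(40), k, tr, nVols), "beyond")
})

test_that("regressors agree with a full-resolution convolution oracle
           for seeded random onset trains", {
  set.seed(42)
  tr <- 2; nVols <- 60
  for (rep_ in 1:3) {
    onsets <- sort(runif(12, 0, (nVols - 10) * tr))
    k <- hrfKernel("spm_canonical", dt = tr / 16)
    got <- buildRegressor(onsetFeature(onsets), k, tr, nVols)
    dt <- tr / 16
    u <- numeric(nVols * 16)
    pos <- onsets / dt + 1e-9
    for (p_ in pos) {
      i0 <- floor(p_); fr <- p_ - i0
      u[i0 + 1] <- u[i0 + 1] + (1 - fr)
      u[i0 + 2] <- u[i0 + 2] + fr
    }
    h <- kernelSamples(hrfKernel("spm_canonical", dt = dt))
    direct <- numeric(length(u))
    for (i in seq_along(u)) {
      j <- seq_len(min(i, length(h)))
      direct[i] <- sum(u[i - j + 1] * h[j])
    }
    expect_equal(got, direct[seq(1, by = 16, length.out = nVols)],
                 tolerance = 1e-8)
  }
})

test_that("doubling the microtime resolution barely moves the regressor", {
  set.seed(7)
  onsets <- sort(runif(10, 0, 80))
  k <- hrfKernel("single_gamma", dt = 0.125, peak = 5)
  r16 <- buildRegressor(onsetFeature(onsets), k, 2, 50, microtimeBins = 16)
  r32 <- buildRegressor(onsetFeature(onsets), k, 2, 50, microtimeBins = 32)
  expect_lt(max(abs(r16 - r32)) / max(abs(r16)), 1e-3)
})

test_that("assembled designs are ordered, labelled and contrasted", {
  T_ <- 40
  set.seed(1)
  interest <- matrix(rnorm(T_), ncol = 1)
  mo <- simulateMotion(T_, 0.3, seed = 1)
  nuis <- buildMotionRegressors(mo, 6)
  drift <- dctDriftBasis(T_, 4, 128)           # 160 s run -> 1 column
  des <- assembleDesign(interest, nuis, drift)
  expect_equal(ncol(designMatrix(des)),
               1 + 6 + ncol(designMatrix(drift)) + 1)
  expect_equal(des@partition[1], "interest")
  expect_equal(des@partition[ncol(designMatrix(des))], "intercept")
  expect_equal(sum(des@contrasts$F_interest), 1)

  bare <- assembleDesign(interest)
  expect_equal(ncol(designMatrix(bare)), 2L)

  tr_ <- designMatrix(linearTrend(T_))
  expect_lt(abs(sum(tr_)), 1e-9)               # orthogonal to intercept
  expect_equal(drop(tr_), seq_len(T_) - mean(seq_len(T_)))

  dup <- matrix(rnorm(2 * T_), ncol = 2,
                dimnames = list(NULL, c("a", "a")))
  expect_error(assembleDesign(dup), "duplicate")
})

test_that("design matrices round-trip through labelled TSV", {
  set.seed(2)
  des <- assembleDesign(matrix(rnorm(30), ncol = 1),
                        linearTrend(30))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeDesignMatrix(des, p)
  back <- readDesignMatrix(p)
  expect_equal(designMatrix(back), designMatrix(des), tolerance = 1e-12)
  expect_identical(back@partition, des@partition)
  expect_identical(designLabels(back), designLabels(des))
})
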