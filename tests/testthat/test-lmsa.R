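test_that("the lagged matrix is a causal shift basis", {
  e <- c(1, 0, 2, 0, 0, 1, 0, 0)
  X <- buildLaggedMatrix(e, tr = 2, nVols = 8, maxLag = 2)
  expect_equal(dim(X), c(8L, 3L))
  expect_equal(X[, 1], e)
  expect_equal(X[, 2], c(0, e[1:7]))
  expect_equal(X[, 3], c(0, 0, e[1:6]))

  ## delta at TR k appears at TR k + l in column l
  d <- numeric(10); d[4] <- 1
  Xd <- buildLaggedMatrix(d, 2, 10, 3)
  for (l in 0:3) expect_equal(which(Xd[, l + 1] == 1), 4 + l)
  expect_error(buildLaggedMatrix(d, 2, 10, 10), "smaller")

  ## X a with a = sampled HRF reproduces the convolution regressor
  tr <- 2; nVols <- 40; L <- 12
  onsets <- (c(3, 11, 25) - 1) * tr          # exactly on volume starts
  fs <- onsetFeature(onsets)
  Xl <- buildLaggedMatrix(fs, tr, nVols, L)
  ## kernel on the lag grid, on the same scale as the microtime kernel
  h <- kernelSamples(hrfKernel("single_gamma", dt = tr / 16,
                               peak = 5))[1 + (0:L) * 16]
  conv <- buildRegressor(fs, hrfKernel("single_gamma", dt = tr / 16,
                                       peak = 5), tr, nVols)
  expect_lt(max(abs(Xl %*% h - conv)), 1e-3)
})

test_that("the first canonical pair matches the normal-equation oracle", {
  set.seed(14)
  for (rep_ in 1:5) {
    X <- matrix(rnorm(60 * 3), 60)
    Y <- matrix(rnorm(60 * 5), 60)
    got <- ccaFirst(X, Y)
    ref <- oracleCCA(X, Y)
    expect_lt(abs(got$rho - ref$rho), 1e-8)
    aN <- got$a / sqrt(sum(got$a^2))
    bN <- got$b / sqrt(sum(got$b^2))
    expect_lt(min(max(abs(aN - ref$a)), max(abs(aN + ref$a))), 1e-8)
    expect_lt(min(max(abs(bN - ref$b)), max(abs(bN + ref$b))), 1e-8)
    ## optimality: rho bounds every single-pair correlation
    expect_gte(got$rho + 1e-12, max(abs(cor(X, Y))))
  }
})

test_that("canonical correlation is invariant under invertible transforms
           and detects perfect coupling", {
  set.seed(15)
  X <- matrix(rnorm(80 * 4), 80)
  Y <- matrix(rnorm(80 * 6), 80)
  base <- ccaFirst(X, Y)$rho
  A <- matrix(rnorm(16), 4); B <- matrix(rnorm(36), 6)
  expect_lt(abs(ccaFirst(X %*% A, Y %*% B)$rho - base), 1e-8)

  w <- rnorm(4)
  Yc <- cbind(X %*% w + 1e-8 * rnorm(80), matrix(rnorm(80 * 2), 80))
  expect_gt(ccaFirst(X, Yc)$rho, 0.999)

  expect_error(ccaFirst(matrix(rnorm(20 * 12), 20),
                        matrix(rnorm(20 * 12), 20)), "T > p \\+ q")
  expect_warning(ccaFirst(cbind(X, X[, 1]), Y), "rank deficient")
})

test_that("the association p-value is calibrated under independence", {
  set.seed(16)
  rej <- mean(replicate(400, {
    ccaFirst(matrix(rnorm(60 * 3), 60),
             matrix(rnorm(60 * 5), 60))$pValue < 0.05
  }))
  ci <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
})

test_that("the t map is zero and unflagged exactly where the gate fails", {
  sim <- simulateBold(shape = c(5, 5, 5), T_ = 120, seed = 17)
  set.seed(17)
  fs <- onsetFeature(sort(runif(20, 0, 200)))
  res <- suppressWarnings(lmsaMap(sim$vol, fs, sim$mask, maxLag = 4))
  evaluated <- !is.na(res@pMap)
  gate <- res@pMap < res@alpha
  expect_true(all(res@tMap[evaluated & !gate] == 0))
  expect_true(all(res@sigMask[evaluated] == gate[evaluated]))
  expect_true(all(res@tMap[evaluated & gate] != 0))
  ## HRF store: only significant voxels, weight sum >= 0, L + 1 lags
  expect_equal(nrow(res@hrfWeights), sum(res@sigMask))
  expect_equal(ncol(res@hrfWeights), 5L)
  if (nrow(res@hrfWeights))
    expect_true(all(rowSums(res@hrfWeights) >= 0))
  ## non-significant voxel yields an empty flagged kernel
  ns <- which(evaluated & !gate)[1]
  if (!is.na(ns)) {
    h <- estimatedHRF(res, ns)
    expect_equal(nrow(h), 0L)
    expect_match(attr(h, "flag"), "not significant")
  }
})

test_that("degenerate LMSA (lag 0, self neighbourhood) equals the GLM t", {
  set.seed(21)
  T_ <- 120; tr <- 2
  fs <- onsetFeature(sort(runif(20, 0, T_ * tr - 30)))
  sh <- c(3, 3, 1)
  vol <- randomVolume(sh, T_, seed = 21)
  mask <- fullMask(sh)
  res <- suppressWarnings(lmsaMap(vol, fs, mask, maxLag = 0,
                                  alpha = 1 + 1e-9, neighborhood = 1))
  e <- featureToTRSeries(fs, tr, T_)
  sm <- fitGLM(globalMeanNormalize(vol, mask),
               assembleDesign(matrix(e, ncol = 1)), mask, c(1, 0))
  expect_lt(max(abs(res@tMap - statValues(sm))), 1e-8)
})

test_that("LMSA recovers a planted hemodynamic response", {
  hits <- 0; cors <- numeric(0)
  for (seed in 1:15) {
    act <- as.matrix(expand.grid(2:4, 2:4, 2:4))
    run <- activationRun(seed = seed, shape = c(5, 5, 5), block = act,
                         peak = 5)
    fl <- array(FALSE, c(5, 5, 5)); fl[2:4, 2:4, 2:4] <- TRUE
    res <- suppressWarnings(lmsaMap(run$sim$vol, run$feature,
                                    new("BrainMask", flags = fl),
                                    maxLag = 6))
    h <- estimatedHRF(res, c(3, 3, 3))
    if (!nrow(h)) next
    if (abs(h$lag_s[which.max(h$weight)] - 5) <= 2) hits <- hits + 1
    trueH <- kernelSamples(hrfKernel("single_gamma", dt = 2, peak = 5))[1:7]
    cors <- c(cors, cor(h$weight, trueH))
  }
  expect_gte(hits / 15, 0.8)
  expect_gt(median(cors), 0.8)
})
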