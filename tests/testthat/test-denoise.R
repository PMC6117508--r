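test_that("motion expansion schemes have the documented block structure", {
  set.seed(10)
  mo <- new("MotionParams", series = matrix(rnorm(60), 10, 6))
  for (s in c(6L, 12L, 24L, 36L))
    expect_equal(ncol(designMatrix(buildMotionRegressors(mo, s))), s)

  ## derivative of a ramp is (0, 1, 1, ...)
  ramp <- new("MotionParams",
              series = cbind(0:9, matrix(0, 10, 5)))
  d12 <- designMatrix(buildMotionRegressors(ramp, 12))
  expect_equal(d12[, 7], c(0, rep(1, 9)))

  ## lag columns are shifts with leading zeros; squares elementwise
  d24 <- buildMotionRegressors(mo, 24)
  M <- designMatrix(d24)
  R <- motionSeries(mo)
  expect_equal(M[, 7:12], R^2)
  expect_equal(M[2:10, 13:18], R[1:9, ], ignore_attr = TRUE)
  expect_equal(M[1, 13:24], rep(0, 12))
  expect_equal(designLabels(d24)[c(1, 7, 13, 19)],
               c("x", "x_sq", "x_lag1", "x_sq_lag1"))

  d36 <- designMatrix(buildMotionRegressors(mo, 36))
  expect_equal(d36[3:10, 25:30], R[1:8, ], ignore_attr = TRUE)
  expect_equal(d36[1:2, 25:36], matrix(0, 2, 12), ignore_attr = TRUE)

  zero <- new("MotionParams", series = matrix(0, 10, 6))
  expect_true(all(designMatrix(buildMotionRegressors(zero, 36)) == 0))
  short <- new("MotionParams", series = matrix(rnorm(12), 2, 6))
  expect_error(buildMotionRegressors(short, 36), "lag-2")
  expect_error(buildMotionRegressors(mo, 18), "6, 12, 24, 36")
})

test_that("tissue means are in-mask spatial means", {
  vol <- randomVolume(c(4, 4, 4), 12, seed = 3, offset = 0)
  one <- array(FALSE, c(4, 4, 4)); one[2, 3, 1] <- TRUE
  m1 <- new("BrainMask", flags = one)
  expect_equal(drop(extractTissueMeans(vol, m1)), vol@data[2, 3, 1, ])

  const <- toyVolume(array(7, c(4, 4, 4, 5)))
  expect_equal(drop(extractTissueMeans(const, m1)), rep(7, 5))

  ## two disjoint masks covering the grid: count-weighted mean = global
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  b <- !a
  mm <- extractTissueMeans(vol, list(new("BrainMask", flags = a),
                                     new("BrainMask", flags = b)))
  w <- c(sum(a), sum(b)) / 64
  expect_equal(drop(mm %*% w), rowMeans(t(matrix(vol@data, 64, 12))))
})

test_that("nuisance regression leaves residuals orthogonal to the design", {
  vol <- randomVolume(c(4, 4, 4), 40, seed = 13)
  mask <- fullMask(c(4, 4, 4))
  mo <- simulateMotion(40, 0.5, seed = 13)
  des <- buildMotionRegressors(mo, 24)
  clean <- regressNuisance(vol, des, mask)
  S <- t(matrix(clean@data, 64, 40))
  S <- sweep(S, 2, colMeans(S))
  X <- designMatrix(des)
  for (j in seq_len(ncol(X)))
    expect_lt(max(abs(cor(X[, j], S))), 1e-8)

  ## a voxel equal to a design column becomes constant
  vol2 <- vol
  vol2@data[1, 1, 1, ] <- X[, 3]
  clean2 <- regressNuisance(vol2, des, mask)
  expect_lt(sd(clean2@data[1, 1, 1, ]), 1e-10)
  expect_equal(mean(clean2@data[1, 1, 1, ]), mean(X[, 3]))

  ## out-of-mask voxels untouched
  holey <- array(TRUE, c(4, 4, 4)); holey[4, 4, 4] <- FALSE
  clean3 <- regressNuisance(vol, des, new("BrainMask", flags = holey))
  expect_identical(clean3@data[4, 4, 4, ], vol@data[4, 4, 4, ])
})

test_that("a planted signal survives nuisance removal", {
  set.seed(13)
  T_ <- 80
  mo <- simulateMotion(T_, 1, seed = 13)
  motion1 <- motionSeries(mo)[, 1]
  s <- as.numeric(stats::residuals(lm(rnorm(T_) ~ motionSeries(mo))))
  dat <- array(rnorm(27 * T_), c(3, 3, 3, T_))
  dat[2, 2, 2, ] <- s + 0.5 * motion1
  vol <- toyVolume(dat)
  clean <- regressNuisance(vol, buildMotionRegressors(mo, 6),
                           fullMask(c(3, 3, 3)))
  expect_gt(cor(clean@data[2, 2, 2, ], s), 0.999)
})

test_that("rank-deficient designs fall back to the pseudoinverse", {
  vol <- randomVolume(c(3, 3, 1), 20, seed = 5)
  X <- cbind(a = rnorm(20), b = 0, c = 0)
  nd <- new("NuisanceDesign", matrix = X, labels = c("a", "b", "c"),
            schemeTag = "custom")
  expect_warning(regressNuisance(vol, nd, fullMask(c(3, 3, 1))),
                 "rank deficient")
})

test_that("the ideal bandpass is exact in pass and stop bands", {
  tr <- 2; n <- 250
  t_ <- (0:(n - 1)) * tr
  pass <- sin(2 * pi * 0.04 * t_)          # bin 20 of a 500 s record
  stopb <- sin(2 * pi * 0.2 * t_)
  y <- idealBandpass(pass, 0.01, 0.08, tr = tr)
  expect_lt(abs(max(abs(y)) / max(abs(pass)) - 1), 1e-6)
  expect_lt(max(abs(idealBandpass(stopb, 0.01, 0.08, tr = tr))), 1e-6)
  expect_lt(max(abs(idealBandpass(rep(3, n), 0.01, 0.08, tr = tr))), 1e-12)
  expect_lt(max(abs(idealBandpass(y, 0.01, 0.08, tr = tr) - y)), 1e-10)
  expect_error(idealBandpass(pass, 0.01, 0.3, tr = tr), "Nyquist")

  ## disjoint bands covering (0, Nyquist] reconstruct the demeaned signal
  set.seed(6)
  x <- rnorm(n)
  edges <- c(0, 0.0501, 0.1001, 0.1801, 0.25)
  recon <- Reduce(`+`, lapply(seq_len(4), function(i)
    idealBandpass(x, edges[i] + 1e-6, edges[i + 1], tr = tr)))
  expect_lt(max(abs(recon - (x - mean(x)))), 1e-8)
})

test_that("bandpassing a volume preserves voxel means when asked", {
  vol <- randomVolume(c(3, 3, 3), 60, seed = 9)
  mask <- fullMask(c(3, 3, 3))
  f <- idealBandpass(vol, 0.01, 0.08, mask = mask)
  expect_equal(apply(f@data, 1:3, mean), apply(vol@data, 1:3, mean),
               tolerance = 1e-10)
  f0 <- idealBandpass(vol, 0.01, 0.08, mask = mask, preserveMean = FALSE)
  expect_lt(max(abs(apply(f0@data, 1:3, mean))), 1e-10)
})

test_that("the DCT drift basis has the standard column count and is orthonormal", {
  b <- dctDriftBasis(180, 2)               # 360 s run, 128 s cutoff
  expect_equal(ncol(designMatrix(b)), 4L)
  expect_equal(ncol(designMatrix(dctDriftBasis(50, 2))), 0L)  # 100 s run
  M <- designMatrix(b)
  G <- crossprod(M)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  expect_equal(drop(diag(G)), rep(1, 4), tolerance = 1e-10)
})

test_that("global mean normalisation scales the grand mean to 100", {
  mask <- fullMask(c(3, 3, 3))
  const <- toyVolume(array(50, c(3, 3, 3, 5)))
  expect_equal(range(globalMeanNormalize(const, mask)@data), c(100, 100))

  vol <- randomVolume(c(3, 3, 3), 10, seed = 2)
  n1 <- globalMeanNormalize(vol, mask)
  expect_lt(abs(mean(n1@data) - 100), 1e-9)
  vol2 <- vol; vol2@data <- vol2@data * 3.7
  expect_equal(globalMeanNormalize(vol2, mask)@data, n1@data)

  zero <- toyVolume(array(c(1, -1), c(2, 1, 1, 4)))
  expect_error(globalMeanNormalize(zero, fullMask(c(2, 1, 1))), "zero")
})
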