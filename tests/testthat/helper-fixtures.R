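## Shared fixtures and independent oracles. Everything here is built in
## code at test time; the oracle implementations deliberately use a
## different algorithmic route than the package (full correlation matrix
## plus grid dilation for FCD, closed-form normal equations for OLS and
## CCA) so agreement is evidence, not tautology.

toyVolume <- function(arr, tr = 2) new("Volume4D", data = arr, tr = tr)

fullMask <- function(shape) new("BrainMask", flags = array(TRUE, shape))

randomVolume <- function(shape, T_, seed, offset = 1000) {
  set.seed(seed)
  toyVolume(array(stats::rnorm(prod(shape) * T_), dim = c(shape, T_)) +
              offset)
}

## zero-padded 3D array shift by (dx, dy, dz)
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- intersect(seq_len(d[1]) + dx, seq_len(d[1]))
  sy <- intersect(seq_len(d[2]) + dy, seq_len(d[2]))
  sz <- intersect(seq_len(d[3]) + dz, seq_len(d[3]))
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz, drop = FALSE]
  out
}

oracleOffsets <- function(conn) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(g))
  lim <- c("6" = 1, "18" = 2, "26" = 3)[[as.character(conn)]]
  g[s > 0 & s <= lim, , drop = FALSE]
}

## Brute-force FCD: full correlation matrix for gFCD; for lFCD a
## morphological grid dilation (grow the seed cluster by the connectivity
## structuring element, intersect with the seed-suprathreshold set, until
## the fixed point).
oracleFCD <- function(vol, mask, threshold, conn) {
  d <- dim(vol@data)
  flags <- mask@flags
  idx <- which(flags)
  V <- length(idx)
  M <- matrix(vol@data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  R <- suppressWarnings(stats::cor(t(M)))
  R[!is.finite(R)] <- 0
  g <- vapply(seq_len(V), function(i) sum(R[i, -i] > threshold), 0)
  off <- oracleOffsets(conn)
  l <- integer(V)
  for (i in seq_len(V)) {
    if (all(R[i, ] == 0)) next       # zero-variance seed
    ok <- array(FALSE, d[1:3])
    ok[idx] <- R[i, ] > threshold
    ok[idx[i]] <- TRUE
    cl <- array(FALSE, d[1:3])
    cl[idx[i]] <- TRUE
    repeat {
      grown <- cl
      for (r in seq_len(nrow(off)))
        grown <- grown | shift3d(cl, off[r, 1], off[r, 2], off[r, 3])
      grown <- grown & ok
      if (identical(grown, cl)) break
      cl <- grown
    }
    l[i] <- sum(cl) - 1L
  }
  list(gfcd = g, lfcd = l)
}

## Closed-form OLS t statistic, coded from the normal equations.
oracleTStat <- function(X, y, cvec) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  drop(t(cvec) %*% b) / sqrt(s2 * drop(t(cvec) %*% XtXi %*% cvec))
}

## CCA by eigendecomposition of the normal equations
## Sxx^-1 Sxy Syy^-1 Syx.
oracleCCA <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  E <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  ev <- eigen(E)
  a <- Re(ev$vectors[, 1L])
  rho <- sqrt(Re(ev$values[1L]))
  b <- drop(solve(Syy) %*% t(Sxy) %*% a)
  list(rho = rho, a = a / sqrt(sum(a^2)), b = b / sqrt(sum(b^2)))
}

## onset feature series helper
onsetFeature <- function(times) {
  new("FeatureSeries", kind = "onsets", times = sort(times),
      values = rep(1, length(times)), trLocked = FALSE)
}

## mask of disjoint 3x3x3 cubes with one-voxel gaps: with
## minNeighbors = 27 only the cube centres are evaluated, and their
## neighbourhoods do not overlap, so voxelwise significance tests are
## independent and a binomial reference is valid.
disjointCubeMask <- function(nCubes) {
  dimn <- 4L * nCubes - 1L
  fl <- array(FALSE, rep(dimn, 3L))
  ctr <- seq(2L, by = 4L, length.out = nCubes)
  for (i in ctr) for (j in ctr) for (k in ctr)
    fl[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)] <- TRUE
  new("BrainMask", flags = fl)
}

## simulated run with planted activation at given SNR (signal sd equals
## noise sd when snr = 1)
activationRun <- function(seed, shape, block, peak, snr = 1, T_ = 250,
                          tr = 2, nEvents = 35, ar1 = 0.3) {
  set.seed(seed)
  onsets <- sort(stats::runif(nEvents, 0, T_ * tr - 30))
  fs <- onsetFeature(onsets)
  reg <- buildRegressor(fs, hrfKernel("single_gamma", dt = tr / 16,
                                      peak = peak), tr, T_)
  beta <- snr / stats::sd(reg)
  sim <- simulateBold(shape = shape, T_ = T_, tr = tr, seed = seed,
                      activation = block, onsets = onsets, peak = peak,
                      beta = beta, ar1 = ar1)
  list(sim = sim, feature = fs, onsets = onsets, beta = beta)
}
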