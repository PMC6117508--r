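## Internal helpers shared across modules.

## T x V matrix of in-mask voxel time series; columns follow the linear
## (column-major) order of which(mask).
maskSeries <- function(vol, mask) {
  d <- dim(vol@data)
  idx <- which(mask@flags)
  m <- matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4L])
  t(m[idx, , drop = FALSE])
}

## Write a T x V series matrix back into a 4D array at in-mask positions.
putMaskSeries <- function(vol, mask, series) {
  d <- dim(vol@data)
  idx <- which(mask@flags)
  m <- matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4L])
  m[idx, ] <- t(series)
  vol@data <- array(m, dim = d)
  vol
}

checkSameGrid <- function(vol, mask) {
  if (!all(dim(vol@data)[1:3] == dim(mask@flags)))
    stop("mask dimensions ", paste(dim(mask@flags), collapse = "x"),
         " do not match volume grid ",
         paste(dim(vol@data)[1:3], collapse = "x"))
  invisible(TRUE)
}

requireTimeSeries <- function(vol, minT = 2L) {
  if (dim(vol@data)[4L] < minT)
    stop("operation requires a time series with at least ", minT,
         " volumes; this volume has ", dim(vol@data)[4L])
  invisible(TRUE)
}

## Neighbourhood offsets for 6/18/26 connectivity (origin excluded).
connectivityOffsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  keep <- s > 0L & s <= switch(as.character(connectivity),
                               "6" = 1L, "18" = 2L, "26" = 3L)
  g[keep, , drop = FALSE]
}

## Adjacency list over in-mask voxels: for the k-th in-mask voxel, integer
## indices (into the in-mask ordering) of its in-mask neighbours.
maskAdjacency <- function(mask, connectivity = 26L) {
  d <- dim(mask@flags)
  idx <- which(mask@flags)
  ord <- array(NA_integer_, dim = d)
  ord[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  off <- connectivityOffsets(connectivity)
  lapply(seq_along(idx), function(k) {
    nb <- sweep(off, 2L, ijk[k, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    v <- ord[nb[ok, , drop = FALSE]]
    v[!is.na(v)]
  })
}

## Column-standardise a T x V matrix to zero mean, unit sum of squares;
## zero-variance columns become all-zero (reported via attribute).
standardizeColumns <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  ss <- sqrt(colSums(x^2))
  zero <- ss < .Machine$double.eps^0.5 * nrow(x)
  ss[zero] <- 1
  out <- sweep(x, 2L, ss, `/`)
  attr(out, "zeroVariance") <- zero
  out
}

## Does [a0, a1) (or the instant a0 when a1 <= a0) intersect any half-open
## [start, end) interval row of blocks?
inAnyBlock <- function(a0, a1, blocks) {
  if (!nrow(blocks)) return(rep(FALSE, length(a0)))
  out <- logical(length(a0))
  for (i in seq_len(nrow(blocks))) {
    s <- blocks[i, 1L]; e <- blocks[i, 2L]
    out <- out | (pmax(a1, a0) > s & a0 < e)
  }
  out
}

## Least-squares solve robust to rank deficiency; returns coefficients and
## the rank. Warns with the offending columns when rank-deficient.
robustLS <- function(X, Y, labels = colnames(X)) {
  qrX <- qr(X)
  r <- qrX$rank
  if (r < ncol(X)) {
    dropped <- if (is.null(labels)) qrX$pivot[(r + 1L):ncol(X)] else
      labels[qrX$pivot[(r + 1L):ncol(X)]]
    warning("design is rank deficient; using pseudoinverse (dependent: ",
            paste(dropped, collapse = ", "), ")")
    B <- MASS::ginv(X) %*% Y
  } else {
    B <- qr.coef(qrX, Y)
  }
  list(coef = B, rank = r)
}

nearestName <- function(key, valid) {
  d <- utils::adist(key, valid, ignore.case = TRUE)
  valid[which.min(d)]
}
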