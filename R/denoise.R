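#' Expand motion parameters into a confound scheme
#'
#' Builds the standard motion-confound expansions from the 6 rigid-body
#' series R = [X, Y, Z, pitch, yaw, roll]:
#' \describe{
#'   \item{6}{[R]}
#'   \item{12}{[R, dR], dR the backward temporal difference (first row 0)}
#'   \item{24}{[R, R^2, R_{t-1}, R^2_{t-1}], lagged blocks zero-padded}
#'   \item{36}{the 24 block plus [R_{t-2}, R^2_{t-2}]}
#' }
#' Squares are elementwise; lagging shifts rows down with leading zeros.
#'
#' @param motion a \linkS4class{MotionParams}.
#' @param scheme 6, 12, 24 or 36.
#' @return a \linkS4class{NuisanceDesign} with exactly \code{scheme}
#'   columns, labelled by block.
#' @export
buildMotionRegressors <- function(motion, scheme = 24) {
  scheme <- as.integer(scheme)
  if (!scheme %in% c(6L, 12L, 24L, 36L))
    stop("scheme must be one of 6, 12, 24, 36")
  R <- motion@series
  T_ <- nrow(R)
  if (scheme == 36L && T_ < 3L)
    stop("scheme 36 uses lag-2 columns and needs at least 3 time points")
  base <- c("x", "y", "z", "pitch", "yaw", "roll")
  lag <- function(m, k) {
    out <- matrix(0, nrow(m), ncol(m))
    if (k < nrow(m)) out[(k + 1L):nrow(m), ] <- m[1L:(nrow(m) - k), ]
    out
  }
  blocks <- list(R); labels <- base
  if (scheme == 12L) {
    dR <- rbind(0, diff(R))
    blocks <- c(blocks, list(dR)); labels <- c(labels, paste0("d", base))
  } else if (scheme >= 24L) {
    blocks <- c(blocks, list(R^2, lag(R, 1L), lag(R^2, 1L)))
    labels <- c(labels, paste0(base, "_sq"), paste0(base, "_lag1"),
                paste0(base, "_sq_lag1"))
    if (scheme == 36L) {
      blocks <- c(blocks, list(lag(R, 2L), lag(R^2, 2L)))
      labels <- c(labels, paste0(base, "_lag2"), paste0(base, "_sq_lag2"))
    }
  }
  new("NuisanceDesign", matrix = do.call(cbind, blocks), labels = labels,
      schemeTag = as.character(scheme))
}

#' Mean tissue time courses
#'
#' Spatial mean of the in-mask voxels at each time point, one series per
#' mask — the usual white-matter / CSF confound regressors.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param masks a \linkS4class{BrainMask} or list of them.
#' @return a T x n matrix, one column per mask.
#' @export
extractTissueMeans <- function(vol, masks) {
  if (is(masks, "BrainMask")) masks <- list(masks)
  out <- vapply(masks, function(m) {
    checkSameGrid(vol, m)
    rowMeans(maskSeries(vol, m))
  }, numeric(dim(vol@data)[4L]))
  matrix(out, ncol = length(masks))
}

#' Regress confounds out of a 4D volume
#'
#' Per in-mask voxel, ordinary least-squares residuals against the
#' nuisance design (an intercept is appended if absent), with the voxel's
#' temporal mean added back so later mean-based normalisation still works.
#' Out-of-mask voxels are untouched. Rank-deficient designs proceed via
#' pseudoinverse with a warning naming the dependent columns.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param design a \linkS4class{NuisanceDesign} (or T x P matrix).
#' @param mask a \linkS4class{BrainMask}.
#' @return the cleaned \linkS4class{Volume4D}.
#' @export
regressNuisance <- function(vol, design, mask) {
  requireTimeSeries(vol)
  checkSameGrid(vol, mask)
  X <- if (is(design, "NuisanceDesign")) design@matrix else as.matrix(design)
  labels <- if (is(design, "NuisanceDesign")) design@labels else
    colnames(X)
  if (nrow(X) != dim(vol@data)[4L])
    stop("design has ", nrow(X), " rows but volume has ",
         dim(vol@data)[4L], " time points")
  hasIntercept <- any(apply(X, 2L, function(col)
    stats::sd(col) < .Machine$double.eps^0.5 && any(col != 0)))
  if (!hasIntercept) {
    X <- cbind(X, 1)
    labels <- c(labels, "intercept")
  }
  Y <- maskSeries(vol, mask)
  mu <- colMeans(Y)
  fit <- robustLS(X, Y, labels)
  resid <- Y - X %*% fit$coef
  resid <- sweep(resid, 2L, mu, `+`)
  putMaskSeries(vol, mask, resid)
}

## Core ideal-filter mask on an n-point DFT grid: keep |f| in
## [low, high]; DC kept only when low == 0.
idealFreqKeep <- function(n, low, high, tr) {
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) / (n * tr)
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  if (low > 0) keep[1L] <- FALSE
  keep
}

#' Ideal (frequency-domain) bandpass filter
#'
#' Zeroes every discrete-Fourier coefficient whose frequency lies outside
#' [\code{low}, \code{high}] Hz and returns the real part of the inverse
#' transform. The DC component is removed unless \code{low = 0}, so the
#' default resting-state band (0.01-0.08 Hz) returns zero-mean series;
#' when filtering a \linkS4class{Volume4D} the voxel temporal mean is
#' added back (disable with \code{preserveMean = FALSE}). The filter is a
#' projection, hence exactly idempotent.
#'
#' @param x a numeric vector/matrix (time x series) or a
#'   \linkS4class{Volume4D}.
#' @param low,high band edges in Hz; \code{high} must not exceed the
#'   Nyquist frequency 1/(2 tr).
#' @param tr sampling interval in seconds (taken from the volume when
#'   filtering one).
#' @param mask required when filtering a volume.
#' @param preserveMean re-add the voxel temporal mean (volumes only).
#' @return object of the same shape, filtered.
#' @export
idealBandpass <- function(x, low = 0.01, high = 0.08, tr = NULL,
                          mask = NULL, preserveMean = TRUE) {
  if (is(x, "Volume4D")) {
    requireTimeSeries(x)
    if (is.null(mask)) stop("a mask is required when filtering a volume")
    checkSameGrid(x, mask)
    Y <- maskSeries(x, mask)
    mu <- colMeans(Y)
    Yf <- idealBandpass(Y, low, high, tr = x@tr)
    if (preserveMean) Yf <- sweep(Yf, 2L, mu, `+`)
    return(putMaskSeries(x, mask, Yf))
  }
  if (is.null(tr)) stop("tr is required when filtering plain series")
  nyq <- 1 / (2 * tr)
  if (low < 0 || high <= low)
    stop("need 0 <= low < high; got [", low, ", ", high, "]")
  if (high > nyq + 1e-12)
    stop("high edge ", high, " Hz exceeds the Nyquist frequency ", nyq,
         " Hz at tr = ", tr, " s")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(X)
  keep <- idealFreqKeep(n, low, high, tr)
  F_ <- stats::mvfft(X)
  F_[!keep, ] <- 0
  out <- Re(stats::mvfft(F_, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Discrete-cosine drift basis
#'
#' High-pass drift regressors: the unit-normalised DCT-II columns whose
#' period exceeds \code{cutoff} seconds (the constant excluded). The
#' column count is \code{floor(2 T tr / cutoff) - 1}, possibly zero for
#' short runs.
#'
#' @param T_ number of time points.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds (default 128).
#' @return a \linkS4class{NuisanceDesign} (possibly with zero columns).
#' @export
dctDriftBasis <- function(T_, tr, cutoff = 128) {
  K <- max(0L, as.integer(floor(2 * T_ * tr / cutoff)) - 1L)
  t_ <- 0:(T_ - 1L)
  cols <- if (K > 0L)
    vapply(seq_len(K), function(k)
      sqrt(2 / T_) * cos(pi * (2 * t_ + 1) * k / (2 * T_)),
      numeric(T_)) else matrix(numeric(0), nrow = T_, ncol = 0L)
  new("NuisanceDesign", matrix = matrix(cols, nrow = T_),
      labels = if (K > 0L) paste0("dct", seq_len(K)) else character(0),
      schemeTag = "custom")
}

#' Scale a volume to grand mean 100
#'
#' Multiplies every value by 100 / (grand mean over mask and time), the
#' conventional pre-GLM normalisation, so the in-mask grand mean of the
#' output is exactly 100.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param mask a \linkS4class{BrainMask}.
#' @return the scaled \linkS4class{Volume4D}.
#' @export
globalMeanNormalize <- function(vol, mask) {
  checkSameGrid(vol, mask)
  gm <- mean(maskSeries(vol, mask))
  if (!is.finite(gm) || abs(gm) < .Machine$double.eps)
    stop("global mean is zero (or not finite); cannot normalise")
  vol@data <- vol@data * (100 / gm)
  vol
}

#' Linear-trend confound column
#'
#' Centred time index (t - mean(t)), orthogonal to the intercept.
#'
#' @param T_ number of time points.
#' @return a \linkS4class{NuisanceDesign} with one column.
#' @export
linearTrend <- function(T_) {
  t_ <- seq_len(T_) - (T_ + 1) / 2
  new("NuisanceDesign", matrix = matrix(t_, ncol = 1L), labels = "trend",
      schemeTag = "custom")
}

#' Column-bind nuisance designs
#'
#' @param ... \linkS4class{NuisanceDesign} objects or plain matrices with
#'   column names.
#' @return one combined \linkS4class{NuisanceDesign}.
#' @export
bindNuisance <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  mats <- lapply(parts, function(p)
    if (is(p, "NuisanceDesign")) p@matrix else as.matrix(p))
  labs <- unlist(lapply(parts, function(p)
    if (is(p, "NuisanceDesign")) p@labels else colnames(as.matrix(p))))
  new("NuisanceDesign", matrix = do.call(cbind, mats), labels = labs,
      schemeTag = "custom")
}
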