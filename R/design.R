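#' Convolve an EEG feature series into an fMRI regressor
#'
#' The feature is painted onto a microtime grid of resolution
#' tr / \code{microtimeBins}: onset features become unit impulses scaled
#' by their values; TR-locked series become per-TR boxcars (missing NA
#' values linearly interpolated — zero is a meaningful power, so gaps are
#' never zero-filled). The grid is convolved with the HRF resampled to
#' the same resolution and read out at each volume's first microtime bin
#' (volume start).
#'
#' @param feature a \linkS4class{FeatureSeries}.
#' @param hrf an \linkS4class{HRFKernel} (its \code{dt} is ignored; the
#'   model is resampled at tr / microtimeBins).
#' @param tr repetition time in seconds.
#' @param nVols number of volumes.
#' @param microtimeBins microtime bins per TR (default 16).
#' @return numeric vector of length \code{nVols}.
#' @export
buildRegressor <- function(feature, hrf, tr, nVols, microtimeBins = 16L) {
  dt <- tr / microtimeBins
  hs <- resampleKernel(hrf, dt)
  nBins <- nVols * microtimeBins
  u <- numeric(nBins)
  if (!length(feature@times)) {
    warning("empty feature series; returning a zero regressor")
  } else if (any(feature@times >= nVols * tr)) {
    stop("feature times extend beyond the run (", nVols * tr, " s)")
  } else if (feature@trLocked) {
    vals <- feature@values
    if (anyNA(vals)) {
      ok <- !is.na(vals)
      if (sum(ok) < 2L) stop("too few non-missing TR-locked values")
      vals <- stats::approx(which(ok), vals[ok], xout = seq_along(vals),
                            rule = 2L)$y
    }
    startBin <- floor(feature@times / dt + 1e-9)
    for (i in seq_along(startBin)) {
      b <- startBin[i] + seq_len(microtimeBins)
      b <- b[b <= nBins]
      u[b] <- u[b] + vals[i]
    }
  } else {
    ## fractional bin placement: an onset between bins splits its weight
    ## linearly, so the regressor converges as the grid is refined
    pos <- feature@times / dt + 1e-9
    i0 <- floor(pos)
    frac <- pos - i0
    for (i in seq_along(pos)) {
      u[i0[i] + 1L] <- u[i0[i] + 1L] + feature@values[i] * (1 - frac[i])
      if (frac[i] > 0 && i0[i] + 2L <= nBins)
        u[i0[i] + 2L] <- u[i0[i] + 2L] + feature@values[i] * frac[i]
    }
  }
  conv <- convolveCausal(u, hs)
  conv[seq(1L, nBins, by = microtimeBins)]
}

## Resample an HRF model at a new dt (regenerate, keeping the model).
resampleKernel <- function(hrf, dt) {
  if (abs(hrf@dt - dt) < 1e-12) return(hrf@samples)
  k <- hrfKernel(hrf@modelTag, dt = dt,
                 peak = if (hrf@modelTag == "single_gamma") hrf@peak else
                   NULL,
                 duration = hrf@duration)
  k@samples
}

## Causal discrete convolution truncated to length(x).
convolveCausal <- function(x, h) {
  n <- length(x)
  out <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  out
}

#' Assemble a partitioned GLM design matrix
#'
#' Columns are ordered [interest | nuisance | drift | intercept]. Default
#' contrasts: one t-contrast per interest column and one F-contrast
#' spanning all interest columns.
#'
#' @param interest numeric matrix (or vector) of regressors of interest;
#'   column names become labels (default interest1, interest2, ...).
#' @param nuisance optional \linkS4class{NuisanceDesign}.
#' @param drift optional \linkS4class{NuisanceDesign} (e.g. from
#'   \code{\link{dctDriftBasis}}).
#' @param addIntercept include an intercept column (default TRUE; the
#'   design class requires one).
#' @return a \linkS4class{DesignMatrix}.
#' @export
assembleDesign <- function(interest, nuisance = NULL, drift = NULL,
                           addIntercept = TRUE) {
  interest <- as.matrix(interest)
  ilabs <- colnames(interest)
  if (is.null(ilabs)) ilabs <- paste0("interest", seq_len(ncol(interest)))
  mats <- list(interest); labs <- ilabs
  part <- rep("interest", ncol(interest))
  for (blk in list(list(nuisance, "nuisance"), list(drift, "drift"))) {
    nd <- blk[[1L]]
    if (!is.null(nd) && ncol(nd@matrix)) {
      if (nrow(nd@matrix) != nrow(interest))
        stop("all design blocks must have equal row counts")
      mats <- c(mats, list(nd@matrix)); labs <- c(labs, nd@labels)
      part <- c(part, rep(blk[[2L]], ncol(nd@matrix)))
    }
  }
  if (!addIntercept)
    stop("the design must contain an intercept")
  mats <- c(mats, list(matrix(1, nrow(interest), 1L)))
  labs <- c(labs, "intercept"); part <- c(part, "intercept")
  X <- do.call(cbind, mats)
  if (anyDuplicated(labs))
    stop("duplicate design labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  P <- ncol(X)
  contrasts <- list()
  for (j in seq_len(ncol(interest))) {
    cv <- numeric(P); cv[j] <- 1
    contrasts[[paste0("t_", ilabs[j])]] <- cv
  }
  Fm <- matrix(0, ncol(interest), P)
  Fm[cbind(seq_len(ncol(interest)), seq_len(ncol(interest)))] <- 1
  contrasts[["F_interest"]] <- Fm
  new("DesignMatrix", matrix = X, labels = labs, partition = part,
      contrasts = contrasts)
}

#' Write / read a design matrix as labelled TSV
#'
#' The partition is stored in a second header line prefixed with "#".
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param path TSV path.
#' @return \code{path} / the \linkS4class{DesignMatrix}.
#' @export
writeDesignMatrix <- function(design, path) {
  con <- file(path, "w")
  writeLines(paste0("#partition\t", paste(design@partition,
                                          collapse = "\t")), con)
  utils::write.table(
    stats::setNames(as.data.frame(design@matrix), design@labels),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeDesignMatrix
#' @export
readDesignMatrix <- function(path) {
  lines <- readLines(path)
  part <- strsplit(sub("^#partition\t", "", lines[1L]), "\t")[[1L]]
  tab <- utils::read.delim(textConnection(lines[-1L]), check.names = FALSE)
  X <- as.matrix(tab)
  labs <- colnames(X); dimnames(X) <- NULL
  ilabs <- labs[part == "interest"]
  P <- ncol(X)
  contrasts <- list()
  for (j in which(part == "interest")) {
    cv <- numeric(P); cv[j] <- 1
    contrasts[[paste0("t_", labs[j])]] <- cv
  }
  Fm <- matrix(0, length(ilabs), P)
  Fm[cbind(seq_along(ilabs), which(part == "interest"))] <- 1
  contrasts[["F_interest"]] <- Fm
  new("DesignMatrix", matrix = X, labels = labs, partition = part,
      contrasts = contrasts)
}
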