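#' Read a 4D (or 3D) BOLD image
#'
#' Reads NIfTI-1 (\code{.nii}/\code{.nii.gz}) or NIfTI-pair/Analyze
#' (\code{.img}/\code{.hdr}) images into a \linkS4class{Volume4D}. The
#' repetition time is taken from the header time step (\code{pixdim[4]} in
#' seconds) unless \code{tr} is supplied, which always wins: scanner
#' export headers are frequently wrong. Analyze-style pairs have no
#' reliable time-step field, so for \code{.img}/\code{.hdr} inputs an
#' explicit \code{tr} is required. 3D files are read with \code{t = 1};
#' time-series operations reject such volumes.
#'
#' @param path image file path.
#' @param tr optional repetition time override in seconds.
#' @param spaceTag free-text space label stored with the volume.
#' @return a \linkS4class{Volume4D}.
#' @export
readVolume4D <- function(path, tr = NULL, spaceTag = "native") {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e)
                    stop("cannot read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L)
    stop("image must be 3D or 4D, found ", length(d), " dimensions")
  isAnalyzePair <- grepl("\\.(img|hdr)$", path, ignore.case = TRUE)
  headerTr <- hdr$pixdim[5L]
  if (is.null(tr)) {
    if (isAnalyzePair)
      stop("Analyze/NIfTI-pair images carry no reliable TR; ",
           "pass tr= explicitly")
    if (!is.finite(headerTr) || headerTr <= 0)
      stop("header time step (pixdim[4] = ", headerTr,
           ") is not a usable TR; pass tr= explicitly")
    tr <- headerTr
  }
  vx <- abs(hdr$pixdim[2:4])
  vx[vx == 0] <- 1
  aff <- tryCatch(unclass(RNifti::xform(img))[, , drop = FALSE],
                  error = function(e) diag(4))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4L, 4L)
  new("Volume4D", data = array(as.numeric(img), dim = d), tr = as.numeric(tr),
      voxelSize = as.numeric(vx), affine = aff, spaceTag = spaceTag)
}

## Internal: NIfTI header carrying grid, spacing, TR and affine.
niftiRef <- function(dims, voxelSize, tr, affine) {
  nd <- length(dims)
  RNifti::niftiHeader(list(
    dim = c(nd, dims, rep(1L, 7L - nd)),
    pixdim = c(-1, voxelSize, tr, 0, 0, 0),
    sform_code = 2L, qform_code = 0L,
    srow_x = affine[1L, ], srow_y = affine[2L, ], srow_z = affine[3L, ]))
}

#' Write a 3D map as NIfTI-1
#'
#' Writes a statistic or measure map next to a reference affine so it
#' overlays the source volume. NA values are stored as NaN and survive the
#' round trip.
#'
#' @param map numeric 3D array.
#' @param referenceAffine 4x4 voxel-to-world matrix (or a
#'   \linkS4class{Volume4D} whose affine and spacing are reused).
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @param voxelSize voxel edge lengths in mm (ignored when a Volume4D is
#'   given as reference).
#' @return \code{path}, invisibly.
#' @export
writeVolume3D <- function(map, referenceAffine, path, voxelSize = c(3, 3, 3)) {
  if (is(referenceAffine, "Volume4D")) {
    voxelSize <- referenceAffine@voxelSize
    referenceAffine <- referenceAffine@affine
  }
  if (length(dim(map)) != 3L)
    stop("map must be a 3D array, found ", length(dim(map)), " dimensions")
  ref <- niftiRef(dim(map), voxelSize, 0, referenceAffine)
  RNifti::writeNifti(RNifti::asNifti(map, reference = ref), path,
                     datatype = "double")
  invisible(path)
}

#' Write a Volume4D as NIfTI-1
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
writeVolume4D <- function(vol, path) {
  ref <- niftiRef(dim(vol@data), vol@voxelSize, vol@tr, vol@affine)
  RNifti::writeNifti(RNifti::asNifti(vol@data, reference = ref), path,
                     datatype = "double")
  invisible(path)
}

#' Read realignment motion parameters
#'
#' Strictly the 6-column whitespace-delimited numeric text written by
#' realignment tools ("rp" files): columns
#' [X, Y, Z, pitch, yaw, roll] in mm and radians, no header line.
#'
#' @param path text file path.
#' @return a \linkS4class{MotionParams}.
#' @export
readMotionParams <- function(path) {
  if (!file.exists(path)) stop("motion file not found: ", path)
  m <- tryCatch(as.matrix(utils::read.table(path, header = FALSE,
                                            colClasses = "numeric")),
                error = function(e)
                  stop("motion file '", path, "' is not plain 6-column ",
                       "numeric text (no headers accepted): ",
                       conditionMessage(e), call. = FALSE))
  if (ncol(m) != 6L)
    stop("motion file must have exactly 6 columns, found ", ncol(m))
  dimnames(m) <- NULL
  new("MotionParams", series = m)
}

#' Write motion parameters as rp-style text
#'
#' @param motion a \linkS4class{MotionParams}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMotionParams <- function(motion, path) {
  utils::write.table(format(motion@series, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BIDS-style event table
#'
#' Tab-separated with columns \code{onset}, \code{duration},
#' \code{trial_type} (header required); onset/duration in seconds.
#'
#' @param path TSV file path.
#' @return data.frame with columns onset, duration, type, sorted by onset.
#' @export
readEventTable <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(tab)))
    stop("event table must have columns onset, duration, trial_type; ",
         "found: ", paste(names(tab), collapse = ", "))
  out <- data.frame(onset = as.numeric(tab$onset),
                    duration = as.numeric(tab$duration),
                    type = as.character(tab$trial_type),
                    stringsAsFactors = FALSE)
  out[order(out$onset), , drop = FALSE]
}

#' Write a BIDS-style event table
#'
#' @param events data.frame with columns onset, duration, type.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEventTable <- function(events, path) {
  utils::write.table(
    data.frame(onset = events$onset, duration = events$duration,
               trial_type = events$type),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate a whole-brain mask from signal intensity
#'
#' A voxel is in the mask iff its temporal mean exceeds \code{fraction}
#' times the maximum temporal mean over the grid. The default 0.2 works
#' for BOLD images whose brain voxels sit far above the air background.
#' Higher fractions always give subset masks.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param fraction threshold fraction in (0, 1).
#' @return a \linkS4class{BrainMask}.
#' @export
autoBrainMask <- function(vol, fraction = 0.2) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  d <- dim(vol@data)
  mu <- rowMeans(matrix(vol@data, nrow = prod(d[1:3]), ncol = d[4L]))
  flags <- array(mu > fraction * max(mu), dim = d[1:3])
  if (!any(flags))
    stop("auto mask is empty at fraction ", fraction,
         "; try a lower fraction")
  new("BrainMask", flags = flags)
}
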