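#' Accessors for package containers
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param object a package object.
#' @param ... passed to methods.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setMethod("volData", "Volume4D", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setMethod("trSeconds", "Volume4D", function(object) object@tr)

#' @rdname accessors
#' @export
setGeneric("volAffine", function(object) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setMethod("volAffine", "Volume4D", function(object) object@affine)

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setMethod("nVolumes", "Volume4D", function(object) dim(object@data)[4L])

#' @rdname accessors
#' @export
setGeneric("maskFlags", function(object) standardGeneric("maskFlags"))
#' @rdname accessors
#' @export
setMethod("maskFlags", "BrainMask", function(object) object@flags)

#' @rdname accessors
#' @export
setGeneric("maskCount", function(object) standardGeneric("maskCount"))
#' @rdname accessors
#' @export
setMethod("maskCount", "BrainMask", function(object) sum(object@flags))

#' @rdname accessors
#' @export
setGeneric("motionSeries", function(object) standardGeneric("motionSeries"))
#' @rdname accessors
#' @export
setMethod("motionSeries", "MotionParams", function(object) object@series)

#' @rdname accessors
#' @export
setGeneric("eegSignals", function(object) standardGeneric("eegSignals"))
#' @rdname accessors
#' @export
setMethod("eegSignals", "EEGRecording", function(object) object@signals)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@srate)

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setMethod("eventTable", "EEGRecording", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("badBlocks", function(object) standardGeneric("badBlocks"))
#' @rdname accessors
#' @export
setMethod("badBlocks", "EEGRecording", function(object) object@badBlocks)

#' @rdname accessors
#' @export
setGeneric("referenceTag", function(object) standardGeneric("referenceTag"))
#' @rdname accessors
#' @export
setMethod("referenceTag", "EEGRecording", function(object) object@reference)

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setMethod("designMatrix", "NuisanceDesign", function(object) object@matrix)
#' @rdname accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@matrix)

#' @rdname accessors
#' @export
setGeneric("designLabels", function(object) standardGeneric("designLabels"))
#' @rdname accessors
#' @export
setMethod("designLabels", "NuisanceDesign", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("designLabels", "DesignMatrix", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("featureTimes", function(object) standardGeneric("featureTimes"))
#' @rdname accessors
#' @export
setMethod("featureTimes", "FeatureSeries", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureSeries", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("kernelSamples", function(object) standardGeneric("kernelSamples"))
#' @rdname accessors
#' @export
setMethod("kernelSamples", "HRFKernel", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("statValues", function(object) standardGeneric("statValues"))
#' @rdname accessors
#' @export
setMethod("statValues", "StatMap", function(object) object@stat)

#' Extract one FCD map
#'
#' @param object an \code{FCDMaps} object.
#' @param measure "lfcd", "gfcd" or "lrfcd".
#' @param threshold one of the thresholds the maps were computed at.
#' @param normalized return the global-mean-normalised variant?
#' @return a 3D array (NA outside the mask).
#' @export
setGeneric("fcdMap",
  function(object, measure, threshold, normalized = FALSE)
    standardGeneric("fcdMap"))

#' @rdname fcdMap
#' @export
setMethod("fcdMap", "FCDMaps",
  function(object, measure, threshold, normalized = FALSE) {
    measure <- match.arg(measure, c("lfcd", "gfcd", "lrfcd"))
    i <- which(abs(object@thresholds - threshold) < 1e-12)
    if (length(i) != 1L)
      stop("threshold ", threshold, " not among computed thresholds (",
           paste(object@thresholds, collapse = ", "), ")")
    object@maps[[i]][[if (normalized) paste0("n", measure) else measure]]
  })

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume4D %dx%dx%d, %d volumes, TR = %g s, space '%s'\n",
              d[1], d[2], d[3], d[4], object@tr, object@spaceTag))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@flags)
  cat(sprintf("BrainMask %dx%dx%d, %d in-mask voxels\n",
              d[1], d[2], d[3], sum(object@flags)))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(paste0("EEGRecording: %d channels x %d samples @ %g Hz ",
                     "(%.1f s), %d events, %d bad blocks, reference: %s\n"),
              nrow(object@signals), ncol(object@signals), object@srate,
              ncol(object@signals) / object@srate, nrow(object@events),
              nrow(object@badBlocks), object@reference))
})

setMethod("show", "NuisanceDesign", function(object) {
  cat(sprintf("NuisanceDesign %d x %d (scheme %s): %s\n",
              nrow(object@matrix), ncol(object@matrix), object@schemeTag,
              paste(utils::head(object@labels, 8L), collapse = ", ")))
})

setMethod("show", "FCDMaps", function(object) {
  cat(sprintf("FCDMaps: thresholds [%s], connectivity %d, %d voxels\n",
              paste(object@thresholds, collapse = ", "),
              object@connectivity, maskCount(object@mask)))
})

setMethod("show", "FOCAMap", function(object) {
  v <- object@raw[!is.na(object@raw)]
  cat(sprintf("FOCAMap (%s): %d voxels, mean %.3f, range [%.3f, %.3f]\n",
              object@combinerTag, length(v), mean(v), min(v), max(v)))
})

setMethod("show", "HRFKernel", function(object) {
  cat(sprintf("HRFKernel '%s', peak %.2f s, dt %.4g s, support %g s\n",
              object@modelTag, object@peak, object@dt, object@duration))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix %d x %d (%d interest, %d nuisance, %d drift)\n",
              nrow(object@matrix), ncol(object@matrix),
              sum(object@partition == "interest"),
              sum(object@partition == "nuisance"),
              sum(object@partition == "drift")))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap (%s), dof = (%g, %g), max = %.3f\n", object@kind,
              object@dof[1], object@dof[2],
              suppressWarnings(max(object@stat, na.rm = TRUE))))
})

setMethod("show", "GLM2Result", function(object) {
  cat(sprintf("GLM2Result: peaks [%s] s, max T = %.3f\n",
              paste(object@peaks, collapse = ", "),
              suppressWarnings(max(object@maxT, na.rm = TRUE))))
})

setMethod("show", "LMSAResult", function(object) {
  cat(sprintf("LMSAResult: %d significant voxels (alpha = %g), lags 0..%d\n",
              sum(object@sigMask, na.rm = TRUE), object@alpha,
              max(object@lags)))
})
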