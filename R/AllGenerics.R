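#' Accessors for lungwater objects
#'
#' \code{volData} returns the raw array of a volume-like object;
#' \code{spacing} its voxel spacing in mm; \code{rightLung}/\code{leftLung}
#' the per-lung logical masks; \code{lungMask} their union;
#' \code{lungVolume} the segmented lung volume in liters (voxel count times
#' voxel volume); \code{lwdValues} the percent-density array of an LWD map.
#'
#' @param x a lungwater object.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("rightLung", function(x) standardGeneric("rightLung"))
#' @rdname accessors
#' @export
setGeneric("leftLung", function(x) standardGeneric("leftLung"))
#' @rdname accessors
#' @export
setGeneric("lungMask", function(x) standardGeneric("lungMask"))
#' @rdname accessors
#' @export
setGeneric("lungVolume", function(x) standardGeneric("lungVolume"))
#' @rdname accessors
#' @export
setGeneric("lwdValues", function(x) standardGeneric("lwdValues"))

#' @rdname accessors
setMethod("volData", "MRIVolume", function(x) x@data)
#' @rdname accessors
setMethod("volData", "LabelMask", function(x) x@data)
#' @rdname accessors
setMethod("volData", "NormalizationMap", function(x) x@field)
#' @rdname accessors
setMethod("spacing", "MRIVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "LabelMask", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "LungSegmentation", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "LWDMap", function(x) x@spacing)
#' @rdname accessors
setMethod("rightLung", "LungSegmentation", function(x) x@right)
#' @rdname accessors
setMethod("leftLung", "LungSegmentation", function(x) x@left)
#' @rdname accessors
setMethod("lungMask", "LungSegmentation", function(x) x@right | x@left)
#' @rdname accessors
setMethod("lungVolume", "LungSegmentation", function(x) {
  (sum(x@right) + sum(x@left)) * prod(x@spacing) / 1e6
})
#' @rdname accessors
setMethod("lwdValues", "LWDMap", function(x) x@values)

setMethod("show", "MRIVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRIVolume: %d x %d x %d voxels (AP x SI x RL), %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  tb <- table(object@data)
  cat(sprintf("LabelMask: %d x %d x %d voxels; labels: %s\n", d[1], d[2],
              d[3], paste(names(tb), collapse = ", ")))
})

setMethod("show", "LungSegmentation", function(object) {
  cat(sprintf("LungSegmentation: right %d voxels, left %d voxels, total %.2f L\n",
              sum(object@right), sum(object@left), lungVolume(object)))
})

setMethod("show", "LiverROI", function(object) {
  cat(sprintf("LiverROI: slice %d, center (row %.2f, col %.2f), radius %.2f mm\n",
              object@slice, object@centerRow, object@centerCol,
              object@radiusMM))
  cat(sprintf("  %d member voxels (%d pre-exclusion); mean signal %s\n",
              nrow(object@members), object@preExclusionCount,
              ifelse(is.na(object@meanSignal), "not measured",
                     sprintf("%.4g", object@meanSignal))))
})

setMethod("show", "NormalizationMap", function(object) {
  cat(sprintf("NormalizationMap: lambda = %.4g, field range [%.3g, %.3g]\n",
              object@lambda, min(object@field), max(object@field)))
})

setMethod("show", "LWDMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("LWDMap: %d lung voxels, mean %.1f%% (hepatic reference %.0f%%, liver mean %.4g)\n",
              length(v), mean(v), object@hepaticWD, object@liverMean))
})

setMethod("show", "RegionalLWD", function(object) {
  cat(sprintf("RegionalLWD: global %.1f%% | anterior %.1f%%, mid %.1f%%, posterior %.1f%%\n",
              object@global, object@anterior, object@mid, object@posterior))
  cat(sprintf("  right %.1f%%, left %.1f%%; lung volume %.2f L\n",
              object@right, object@left, object@lungVolumeL))
})

setMethod("show", "VialLayout", function(object) {
  cat(sprintf("VialLayout: %d vials (%s%%), radius %.1f mm, reference vial %d\n",
              nrow(object@centers),
              paste(object@concentration, collapse = ", "),
              object@radiusMM, object@reference))
})

setMethod("show", "ThoraxTruth", function(object) {
  cat(sprintf("ThoraxTruth: %s, grid %s at %.2f mm, regional means %s%%\n",
              object@posture, paste(object@dim, collapse = "x"),
              object@spacing[1],
              paste(object@regionalMeans, collapse = "/")))
})
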