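#' @include AllClasses.R
NULL

#' Accessors for dtcmorph objects
#'
#' Accessor generics for the core classes: specimen identity, pixel rasters,
#' physical calibration, provenance, masks and Sholl profiles. Slots are never
#' accessed directly by user code.
#'
#' @param x a dtcmorph object.
#' @return the corresponding component.
#' @name accessors
#' @aliases specimenId planes pixels pixelSizeXY zStep bitDepth provenance
#'   mask thresholdValue thresholdMethod radiiUm counts shollCenter
#'   pathPoints bandWidthPx marks distancesUm featureCounts distalAnchor
#'   nucleusMark
NULL

#' @rdname accessors
#' @export
setGeneric("specimenId", function(x) standardGeneric("specimenId"))
#' @rdname accessors
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeXY", function(x) standardGeneric("pixelSizeXY"))
#' @rdname accessors
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("mask", function(x) standardGeneric("mask"))
#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
#' @rdname accessors
#' @export
setGeneric("thresholdMethod", function(x) standardGeneric("thresholdMethod"))
#' @rdname accessors
#' @export
setGeneric("radiiUm", function(x) standardGeneric("radiiUm"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("shollCenter", function(x) standardGeneric("shollCenter"))
#' @rdname accessors
#' @export
setGeneric("pathPoints", function(x) standardGeneric("pathPoints"))
#' @rdname accessors
#' @export
setGeneric("bandWidthPx", function(x) standardGeneric("bandWidthPx"))
#' @rdname accessors
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))
#' @rdname accessors
#' @export
setGeneric("distancesUm", function(x) standardGeneric("distancesUm"))
#' @rdname accessors
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))
#' @rdname accessors
#' @export
setGeneric("distalAnchor", function(x) standardGeneric("distalAnchor"))
#' @rdname accessors
#' @export
setGeneric("nucleusMark", function(x) standardGeneric("nucleusMark"))

#' Write an image to disk as TIFF
#'
#' @param x the object to write.
#' @param path destination TIFF path (parent directory must exist).
#' @param ... method-specific arguments.
#' @export
setGeneric("writeImage", function(x, path, ...) standardGeneric("writeImage"))

setMethod("specimenId", "CalibratedStack", function(x) x@specimenId)
setMethod("specimenId", "ProjectedImage", function(x) x@specimenId)
setMethod("specimenId", "MarkupRecord", function(x) x@specimenId)
setMethod("planes", "CalibratedStack", function(x) x@planes)
setMethod("pixels", "ProjectedImage", function(x) x@pixels)
setMethod("pixelSizeXY", "CalibratedStack", function(x) x@pixelSizeXY)
setMethod("pixelSizeXY", "ProjectedImage", function(x) x@pixelSizeXY)
setMethod("pixelSizeXY", "BinaryImage", function(x) x@pixelSizeXY)
setMethod("pixelSizeXY", "MarkupRecord", function(x) x@pixelSizeXY)
setMethod("pixelSizeXY", "ShollProfile", function(x) x@pixelSizeXY)
setMethod("zStep", "CalibratedStack", function(x) x@zStep)
setMethod("bitDepth", "CalibratedStack", function(x) x@bitDepth)
setMethod("provenance", "ProjectedImage", function(x) x@provenance)
setMethod("mask", "BinaryImage", function(x) x@mask)
setMethod("thresholdValue", "BinaryImage", function(x) x@thresholdValue)
setMethod("thresholdMethod", "BinaryImage", function(x) x@thresholdMethod)
setMethod("radiiUm", "ShollProfile", function(x) x@radiiUm)
setMethod("counts", "ShollProfile", function(x) x@counts)
setMethod("shollCenter", "ShollProfile", function(x) x@center)
setMethod("pathPoints", "CurvePath", function(x) x@points)
setMethod("bandWidthPx", "CurvePath", function(x) x@bandWidthPx)
setMethod("marks", "MarkupRecord", function(x) x@marks)
setMethod("distancesUm", "MarkupRecord", function(x) x@distanceUm)
setMethod("featureCounts", "MarkupRecord", function(x) x@counts)
setMethod("distalAnchor", "MarkupRecord", function(x) x@distalAnchor)
setMethod("nucleusMark", "MarkupRecord", function(x) x@nucleus)

setMethod("show", "CalibratedStack", function(object) {
  d <- dim(object@planes[[1]])
  cat(sprintf(
    "CalibratedStack '%s': %d plane(s) of %d x %d px (%d-bit)\n",
    object@specimenId, length(object@planes), d[2], d[1], object@bitDepth))
  cat(sprintf("  calibration: %.4g um/px, z step %.4g um\n",
              object@pixelSizeXY, object@zStep))
})

setMethod("show", "ProjectedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("%s '%s': %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              class(object), object@specimenId, d[2], d[1],
              object@pixelSizeXY, min(object@pixels), max(object@pixels)))
  if (length(object@provenance))
    cat("  provenance:", paste(vapply(object@provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
})

setMethod("show", "CurvePath", function(object) {
  cat(sprintf("CurvePath: %d control points, band width %d px\n",
              nrow(object@points), object@bandWidthPx))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryImage: %d x %d px, %s threshold = %.4g, %.2f%% foreground\n",
              d[2], d[1], object@thresholdMethod, object@thresholdValue,
              100 * mean(object@mask)))
})

setMethod("show", "ShollProfile", function(object) {
  cat(sprintf("ShollProfile: center (%.1f, %.1f) px, %d radii every %.3g um\n",
              object@center[1], object@center[2], length(object@radiiUm),
              object@stepUm))
  if (length(object@counts))
    cat(sprintf("  max %d intersections; extent %.3g um\n",
                max(object@counts),
                if (any(object@counts > 0))
                  max(object@radiiUm[object@counts > 0]) else 0))
})

setMethod("show", "MarkupRecord", function(object) {
  cat(sprintf("MarkupRecord '%s': %d mark(s), origin x = %.2f px\n",
              object@specimenId, nrow(object@marks),
              object@distalAnchor@center[1] - object@distalAnchor@radius))
  nz <- object@counts[object@counts > 0]
  if (length(nz))
    cat("  counts:", paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
})
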