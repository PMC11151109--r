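#' @import methods
NULL

#' CalibratedStack: an ordered Z-series with physical calibration
#'
#' Ordered Z planes of one specimen, each a 2D non-negative integer raster,
#' together with the XY pixel size and Z step in micrometres. All coordinates
#' in this package are 0-based \code{(x, y)} with x rightward, y downward and
#' pixel centers at integer coordinates; a pixel at \code{(x, y)} is stored at
#' \code{planes[[k]][y + 1, x + 1]}.
#'
#' @slot specimenId character token derived from the source filename stem.
#' @slot planes list of integer matrices, identical dimensions, page order.
#' @slot pixelSizeXY micrometres per pixel (isotropic, > 0).
#' @slot zStep micrometres between consecutive planes (> 0).
#' @slot bitDepth bits per sample (8 or 16); every intensity must be
#'   at most \code{2^bitDepth - 1}.
#' @export
setClass("CalibratedStack",
  representation(
    specimenId = "character",
    planes = "list",
    pixelSizeXY = "numeric",
    zStep = "numeric",
    bitDepth = "integer"
  )
)

setValidity("CalibratedStack", function(object) {
  msg <- character()
  if (length(object@planes) < 1L) msg <- c(msg, "stack must have >= 1 plane")
  dims <- lapply(object@planes, dim)
  if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "all planes must share identical height x width")
  if (length(object@pixelSizeXY) != 1L || !is.finite(object@pixelSizeXY) ||
      object@pixelSizeXY <= 0)
    msg <- c(msg, "pixelSizeXY must be a positive scalar (um/px)")
  if (length(object@zStep) != 1L || !is.finite(object@zStep) || object@zStep <= 0)
    msg <- c(msg, "zStep must be a positive scalar (um)")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  mx <- max(vapply(object@planes, function(p) max(p, 0L), numeric(1)))
  mn <- min(vapply(object@planes, function(p) min(p, 0L), numeric(1)))
  if (mn < 0) msg <- c(msg, "intensities must be non-negative")
  if (mx > 2^object@bitDepth - 1)
    msg <- c(msg, sprintf("intensity %g exceeds 2^%d - 1", mx, object@bitDepth))
  if (length(msg)) msg else TRUE
})

#' ProjectedImage: a single calibrated 2D image with provenance
#'
#' A 2D non-negative real raster plus an append-only record of the processing
#' steps that produced it (projection, background subtraction, gamma, rescale,
#' straightening path hash, crop box). Replaying the provenance against the
#' same source stack reproduces the pixel content.
#'
#' @slot specimenId character specimen token.
#' @slot pixels numeric matrix, finite and >= 0; row = y + 1, col = x + 1.
#' @slot pixelSizeXY micrometres per pixel.
#' @slot provenance list of named processing-step descriptors, append-only.
#' @export
setClass("ProjectedImage",
  representation(
    specimenId = "character",
    pixels = "matrix",
    pixelSizeXY = "numeric",
    provenance = "list"
  )
)

setValidity("ProjectedImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  else if (any(object@pixels < 0)) msg <- c(msg, "pixels must be >= 0")
  if (length(object@pixelSizeXY) != 1L || object@pixelSizeXY <= 0)
    msg <- c(msg, "pixelSizeXY must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' StraightenedImage: a fixed-box straightened image
#'
#' A \linkS4class{ProjectedImage} whose pixel content has been resampled along
#' a curved path (distal end at column 0) and cropped to the batch's fixed box
#' so that every specimen shares identical geometry.
#'
#' @slot sourcePathHash character digest of the resampled straightening path,
#'   linking the image back to the path that produced it.
#' @export
setClass("StraightenedImage",
  contains = "ProjectedImage",
  representation(sourcePathHash = "character")
)

#' CurvePath: control points of the straightening path
#'
#' Ordered control points of the curved straightening path, first point at the
#' distal end (the direction is trusted, not inferred), plus the odd width in
#' pixels of the band sampled along the path's normals.
#'
#' @slot points n x 2 numeric matrix of (x, y) pixel coordinates, n >= 2,
#'   consecutive points distinct.
#' @slot bandWidthPx odd integer >= 3, width of the sampled band.
#' @export
setClass("CurvePath",
  representation(points = "matrix", bandWidthPx = "integer")
)

setValidity("CurvePath", function(object) {
  msg <- character()
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 2L)
    msg <- c(msg, "points must be an n x 2 numeric matrix with n >= 2")
  else {
    d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(d == 0)) msg <- c(msg, "consecutive control points must be distinct")
  }
  w <- object@bandWidthPx
  if (length(w) != 1L || w < 3L || w %% 2L == 0L)
    msg <- c(msg, "bandWidthPx must be an odd integer >= 3")
  if (length(msg)) msg else TRUE
})

#' CircleMark: a circular anchor annotation
#'
#' A user-placed circle: either the large distal anchor tangent to the distal
#' end of the gonad, or the smaller circle around the nucleus.
#'
#' @slot role one of \code{"distal_anchor"} or \code{"nucleus"}.
#' @slot center numeric length-2 (x, y) pixel coordinates of the center.
#' @slot radius radius in pixels, > 0.
#' @export
setClass("CircleMark",
  representation(role = "character", center = "numeric", radius = "numeric")
)

setValidity("CircleMark", function(object) {
  msg <- character()
  if (!(object@role %in% c("distal_anchor", "nucleus")))
    msg <- c(msg, "role must be 'distal_anchor' or 'nucleus'")
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be finite (x, y)")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be > 0")
  if (length(msg)) msg else TRUE
})

setClassUnion("CircleMarkOrNULL", c("CircleMark", "NULL"))

#' Default feature-mark vocabulary
#'
#' The configurable slate of morphological feature types that can be marked on
#' a straightened DTC image: branchpoints, puncta, disconnected fragments,
#' process endpoints, the nucleus center, the distal origin, and a free
#' "other" slot.
#' @export
DEFAULT_VOCABULARY <- c("branchpoint", "punctum", "fragment",
                        "process_endpoint", "nucleus_center",
                        "distal_origin", "other")

#' MarkupRecord: per-specimen feature markup and derived measurements
#'
#' A per-specimen set of typed feature marks together with the distal anchor
#' circle (which defines the distal origin on the X axis), the optional
#' nucleus circle, and derived quantities: the signed distance of every mark
#' from the distal origin along X in micrometres, and per-type counts. The
#' derived values are pure functions of the stored marks; recomputation
#' reproduces them (enforced by validity).
#'
#' @slot specimenId character specimen token.
#' @slot pixelSizeXY micrometres per pixel.
#' @slot distalAnchor \linkS4class{CircleMark} with role \code{distal_anchor}.
#' @slot nucleus \linkS4class{CircleMark} with role \code{nucleus}, or NULL.
#' @slot marks data.frame with columns \code{feature_type}, \code{x},
#'   \code{y} (pixel coordinates).
#' @slot vocabulary allowed feature types.
#' @slot distanceUm numeric, per-mark signed distance from the distal origin
#'   in micrometres (positive = proximal, i.e. rightward).
#' @slot counts named integer, per-type mark counts over the vocabulary.
#' @export
setClass("MarkupRecord",
  representation(
    specimenId = "character",
    pixelSizeXY = "numeric",
    distalAnchor = "CircleMark",
    nucleus = "CircleMarkOrNULL",
    marks = "data.frame",
    vocabulary = "character",
    distanceUm = "numeric",
    counts = "integer"
  )
)

setValidity("MarkupRecord", function(object) {
  msg <- character()
  if (object@distalAnchor@role != "distal_anchor")
    msg <- c(msg, "distalAnchor must have role 'distal_anchor'")
  if (!is.null(object@nucleus) && object@nucleus@role != "nucleus")
    msg <- c(msg, "nucleus circle must have role 'nucleus'")
  m <- object@marks
  if (!all(c("feature_type", "x", "y") %in% names(m)))
    msg <- c(msg, "marks needs columns feature_type, x, y")
  else {
    if (!all(m$feature_type %in% object@vocabulary))
      msg <- c(msg, "all feature types must be in the vocabulary")
    ox <- object@distalAnchor@center[1] - object@distalAnchor@radius
    expected <- (m$x - ox) * object@pixelSizeXY
    if (length(expected) != length(object@distanceUm) ||
        (length(expected) && max(abs(expected - object@distanceUm)) > 1e-9))
      msg <- c(msg, "distanceUm must equal (x - origin_x) * pixelSizeXY")
    tab <- table(factor(m$feature_type, levels = object@vocabulary))
    if (!identical(as.integer(tab), unname(object@counts)))
      msg <- c(msg, "counts must equal multiset sizes of marks by type")
    org <- m$feature_type == "distal_origin"
    if (any(org) && any(abs(object@distanceUm[org]) > 1e-9))
      msg <- c(msg, "distance of the distal origin itself must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' BinaryImage: a thresholded mask ready for Sholl analysis
#'
#' @slot mask logical matrix, same dimensions as the source image;
#'   TRUE = foreground (pixel strictly above the threshold).
#' @slot pixelSizeXY micrometres per pixel.
#' @slot thresholdValue the applied intensity cutoff.
#' @slot thresholdMethod token, e.g. \code{"otsu"} or \code{"fixed"}.
#' @export
setClass("BinaryImage",
  representation(
    mask = "matrix",
    pixelSizeXY = "numeric",
    thresholdValue = "numeric",
    thresholdMethod = "character"
  )
)

setValidity("BinaryImage", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@pixelSizeXY) != 1L || object@pixelSizeXY <= 0)
    msg <- c(msg, "pixelSizeXY must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' ShollProfile: intersection counts per concentric radius
#'
#' The Sholl profile of a binary image about a user-defined center: for each
#' radius \code{i * stepUm} the number of maximal connected foreground runs
#' along the sampled circle (a fully-foreground circle counts as 1).
#'
#' @slot center numeric (x, y) pixel coordinates of the center point.
#' @slot stepUm radius spacing in micrometres (default 1).
#' @slot radiiUm ordered radii \code{i * stepUm}, i = 1..K.
#' @slot counts non-negative integer intersections per radius,
#'   \code{length(counts) == length(radiiUm)}.
#' @slot pixelSizeXY micrometres per pixel of the source mask.
#' @export
setClass("ShollProfile",
  representation(
    center = "numeric",
    stepUm = "numeric",
    radiiUm = "numeric",
    counts = "integer",
    pixelSizeXY = "numeric"
  )
)

setValidity("ShollProfile", function(object) {
  msg <- character()
  if (length(object@radiiUm) != length(object@counts))
    msg <- c(msg, "counts and radiiUm must have equal length")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (length(object@stepUm) != 1L || object@stepUm <= 0)
    msg <- c(msg, "stepUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' SynthParams: parameters of the synthetic DTC generator
#'
#' Scene and acquisition parameters for \code{\link{generateDtcStack}}. The
#' defaults emulate the acquisition regime the pipeline is designed for:
#' 0.2167 um pixels, 0.5 um Z steps, a bright cell body (peak ~50000 of the
#' 16-bit range) and dim thin processes (~150), i.e. intensities spanning
#' orders of magnitude without saturation.
#'
#' @slot width,height image size in pixels.
#' @slot pixelSizeXY micrometres per pixel (default 0.2167).
#' @slot zPlanes number of Z planes; \code{zStep} micrometres between them.
#' @slot centerline m x 2 control points of the gonad centerline, distal
#'   first.
#' @slot layout \code{"gonad"} (curved arm with branches, puncta, fragments)
#'   or \code{"rays"} (straight rays radiating from the body centroid, for
#'   Sholl benchmarking).
#' @slot bodyAmplitude,bodySigmaPx peak intensity and Gaussian sigma of the
#'   cell body.
#' @slot processAmplitude,processWidthPx intensity and width (>= 2 px) of the
#'   thin processes; \code{bodyAmplitude / processAmplitude} must be >= 50.
#' @slot nBranches,branchPositionsUm,branchLengthPx branching processes along
#'   the centerline; positions are arc-length micrometres from the distal tip.
#' @slot nPuncta,punctaAmplitude,punctaSigmaPx small bright spots.
#' @slot nFragments,fragmentAmplitude disconnected short segments.
#' @slot nRays,rayLengthPx ray layout geometry.
#' @slot backgroundLevel,noiseSd additive background and Gaussian noise;
#'   \code{bodyAmplitude + backgroundLevel + 5 * noiseSd} must stay below
#'   2^16 (no saturation).
#' @slot seed integer RNG seed; a fixed seed makes the stack fully
#'   reproducible.
#' @export
setClass("SynthParams",
  representation(
    width = "integer", height = "integer",
    pixelSizeXY = "numeric", zPlanes = "integer", zStep = "numeric",
    centerline = "matrix", layout = "character",
    bodyAmplitude = "numeric", bodySigmaPx = "numeric",
    processAmplitude = "numeric", processWidthPx = "numeric",
    nBranches = "integer", branchPositionsUm = "numeric",
    branchLengthPx = "numeric",
    nPuncta = "integer", punctaAmplitude = "numeric", punctaSigmaPx = "numeric",
    nFragments = "integer", fragmentAmplitude = "numeric",
    nRays = "integer", rayLengthPx = "numeric",
    backgroundLevel = "numeric", noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SynthParams", function(object) {
  msg <- character()
  if (object@bodyAmplitude / object@processAmplitude < 50)
    msg <- c(msg, "bodyAmplitude / processAmplitude must be >= 50")
  amps <- c(object@bodyAmplitude, object@processAmplitude,
            object@punctaAmplitude, object@fragmentAmplitude)
  if (any(amps >= 2^16)) msg <- c(msg, "all amplitudes must be < 2^16")
  if (object@bodyAmplitude + object@backgroundLevel + 5 * object@noiseSd >= 2^16)
    msg <- c(msg, "bodyAmplitude + backgroundLevel + 5*noiseSd would saturate 16 bits")
  if (object@processWidthPx < 2)
    msg <- c(msg, "processWidthPx must be >= 2 (thinner structures alias)")
  if (!(object@layout %in% c("gonad", "rays")))
    msg <- c(msg, "layout must be 'gonad' or 'rays'")
  if (object@pixelSizeXY <= 0 || object@zStep <= 0)
    msg <- c(msg, "calibration must be positive")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: coordinates of every rendered synthetic feature
#'
#' All geometric truth is stored in pixels and, where a position along the
#' gonad axis is meaningful, also as arc-length micrometres from the distal
#' tip, so unit errors surface loudly in recovery tests.
#'
#' @slot centerline dense m x 2 centerline points (px), distal first.
#' @slot distalTip (x, y) px of the distal tip (centerline start).
#' @slot bodyCentroid (x, y) px of the cell-body centroid.
#' @slot branchpoints data.frame x, y, arc_um.
#' @slot puncta data.frame x, y, arc_um.
#' @slot fragments data.frame x0, y0, x1, y1, mid_x, mid_y.
#' @slot endpoints data.frame x, y (terminal tips of branch processes).
#' @slot pixelSizeXY micrometres per pixel.
#' @export
setClass("GroundTruth",
  representation(
    centerline = "matrix",
    distalTip = "numeric",
    bodyCentroid = "numeric",
    branchpoints = "data.frame",
    puncta = "data.frame",
    fragments = "data.frame",
    endpoints = "data.frame",
    pixelSizeXY = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  bp <- object@branchpoints
  if (nrow(bp) && max(abs(bp$arc_um)) > 0) {
    # um positions must be consistent with pixel coordinates along the
    # centerline: arc in px times pixelSizeXY
    if (any(bp$arc_um < 0)) msg <- c(msg, "arc_um must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
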