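#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Maximum projection of a Z-stack
#'
#' Collapses the Z-series to 2D: each output pixel is the maximum of that
#' pixel across all planes. Calibration is copied and the projection is
#' recorded in the provenance.
#'
#' @param stack a \linkS4class{CalibratedStack} with >= 1 plane.
#' @return a \linkS4class{ProjectedImage}.
#' @export
maxProject <- function(stack) {
  stopifnot(is(stack, "CalibratedStack"))
  if (length(stack@planes) < 1L)
    dtcStop("dtcError_emptyStack", "stack has no planes")
  acc <- stack@planes[[1]] * 1.0
  for (p in stack@planes[-1L]) acc <- pmax(acc, p)
  new("ProjectedImage", specimenId = stack@specimenId, pixels = acc,
      pixelSizeXY = stack@pixelSizeXY,
      provenance = list(provStep("max_project",
                                 n_planes = length(stack@planes))))
}

#' Background estimate from the darkest pixels
#'
#' The background is the mean intensity of the darkest
#' \code{ceiling(backgroundFraction * N)} pixels. Ties at the cutoff
#' intensity are resolved by taking all pixels at that intensity into the
#' mean, so the estimate depends only on the intensity histogram, never on
#' pixel order.
#'
#' @param image a \linkS4class{ProjectedImage} or numeric matrix.
#' @param backgroundFraction fraction of darkest pixels used
#'   (default 0.001, i.e. the darkest 0.1 percent).
#' @return a non-negative scalar.
#' @export
estimateBackground <- function(image, backgroundFraction = 0.001) {
  px <- if (is(image, "ProjectedImage")) image@pixels else image
  stopifnot(length(px) > 0, backgroundFraction > 0, backgroundFraction < 0.5)
  k <- ceiling(backgroundFraction * length(px))
  v <- sort(as.vector(px), partial = k)
  cutoff <- v[k]
  mean(px[px <= cutoff])
}

#' Contrast-optimized maximum projection
#'
#' Produces a projection whose brightness range is comparable across
#' specimens even when the fluorescent dynamic range spans orders of
#' magnitude (dim thin processes next to a bright cell body). The pipeline
#' is: maximum projection, subtraction of the darkest-pixel background
#' estimate (clamped at 0), normalization to [0, 1] by the post-subtraction
#' maximum, gamma transformation \eqn{v \mapsto v^\gamma}, and rescaling to
#' \code{[0, outputMax]}. With \code{gamma < 1} dim structures are brightened
#' relative to bright ones while order is preserved (the map is monotone).
#' For any non-constant input the output minimum is exactly 0 and the
#' maximum exactly \code{outputMax}. Every step and its numeric parameters
#' are recorded in the provenance.
#'
#' @param stack a \linkS4class{CalibratedStack}.
#' @param gamma positive exponent (default 0.5).
#' @param backgroundFraction darkest-pixel fraction for the background
#'   estimate (default 0.001).
#' @param outputMax display ceiling of the rescale (default 65535).
#' @return a \linkS4class{ProjectedImage}.
#' @examples
#' s <- generateDtcStack(synthParams(seed = 1))$stack
#' opt <- optimizeImage(s)
#' range(pixels(opt))
#' @export
optimizeImage <- function(stack, gamma = 0.5, backgroundFraction = 0.001,
                          outputMax = 65535) {
  stopifnot(gamma > 0, outputMax > 0,
            backgroundFraction > 0, backgroundFraction < 0.5)
  img <- maxProject(stack)
  bg <- estimateBackground(img, backgroundFraction)
  v <- pmax(img@pixels - bg, 0)
  img <- appendProvenance(img, provStep("subtract_background",
                                        background = bg,
                                        fraction = backgroundFraction))
  mx <- max(v)
  if (mx <= 0)
    dtcStop("dtcError_constantImage",
            "image is constant after background subtraction; normalization undefined")
  v <- (v / mx)^gamma * outputMax
  img@pixels <- v
  img <- appendProvenance(img, provStep("normalize", max_in = mx))
  img <- appendProvenance(img, provStep("gamma", gamma = gamma))
  img <- appendProvenance(img, provStep("rescale", output_max = outputMax))
  validObject(img)
  img
}
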