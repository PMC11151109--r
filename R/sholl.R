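#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Threshold an image into a binary mask
#'
#' Foreground is every pixel strictly above the threshold. With
#' \code{method = "otsu"} the cutoff maximizes the between-class variance of
#' the intensity histogram (computed by \code{EBImage::otsu} over the full
#' 16-bit range); \code{method = "fixed"} applies a user-supplied cutoff.
#' Method and value are recorded on the result.
#'
#' @param image a \linkS4class{ProjectedImage},
#'   \linkS4class{StraightenedImage} or numeric matrix.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param fixedValue cutoff for \code{method = "fixed"}.
#' @param pixelSizeXY calibration when \code{image} is a bare matrix.
#' @return a \linkS4class{BinaryImage}.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), fixedValue = NULL,
                     pixelSizeXY = NULL) {
  method <- match.arg(method)
  px <- if (is(image, "ProjectedImage")) image@pixels else image
  if (is.null(pixelSizeXY))
    pixelSizeXY <- if (is(image, "ProjectedImage")) image@pixelSizeXY else 1
  if (method == "otsu") {
    if (max(px) == min(px))
      dtcStop("dtcError_constantImage",
              "Otsu thresholding is undefined for a constant image")
    th <- EBImage::otsu(EBImage::Image(px / 65535), range = c(0, 1),
                        levels = 65536L) * 65535
  } else {
    if (is.null(fixedValue))
      dtcStop("dtcError_missingThreshold",
              "method 'fixed' requires fixedValue")
    th <- as.numeric(fixedValue)
  }
  new("BinaryImage", mask = px > th, pixelSizeXY = as.numeric(pixelSizeXY),
      thresholdValue = th, thresholdMethod = method)
}

# run count along a closed circle of logical samples: number of maximal
# connected TRUE runs, merging across the 0/2pi seam; all-TRUE counts as 1
countCircularRuns <- function(fg) {
  n <- length(fg)
  if (!any(fg)) return(0L)
  if (all(fg)) return(1L)
  sum(fg & !fg[c(n, seq_len(n - 1L))])
}

# foreground lookup along one circle: nearest-neighbor mask sampling at
# angular increments giving arc steps <= arcStepPx
circleSamples <- function(msk, cx, cy, rPx, arcStepPx = 0.5) {
  n <- max(8L, ceiling(2 * pi * rPx / arcStepPx))
  th <- (seq_len(n) - 1L) * (2 * pi / n)
  xi <- round(cx + rPx * cos(th))
  yi <- round(cy + rPx * sin(th))
  inside <- xi >= 0 & xi <= ncol(msk) - 1 & yi >= 0 & yi <= nrow(msk) - 1
  fg <- logical(n)
  fg[inside] <- msk[cbind(yi[inside] + 1, xi[inside] + 1)]
  fg
}

#' Sholl intersection profile of a binary image
#'
#' Counts, for each concentric radius \code{i * stepUm} about a user-defined
#' center point, the number of intersections of the circle with foreground:
#' each maximal connected run of foreground samples along the closed circle
#' is one intersection (runs crossing the seam are merged; a fully
#' foreground circle counts as 1). Circles are sampled with nearest-neighbor
#' mask lookup at angular increments giving arc steps of at most
#' \code{arcStepPx} (default 0.5 px), which does not alias for foreground
#' structures at least 2 px wide.
#'
#' @param binary a \linkS4class{BinaryImage}.
#' @param center (x, y) pixel coordinates of the center; must lie inside the
#'   image.
#' @param stepUm radius spacing in micrometres (default 1, i.e. radii every
#'   1 um starting at 1 um; radius 0 is degenerate and excluded).
#' @param maxRadiusUm largest radius; defaults to the distance from the
#'   center to the farthest image corner.
#' @param arcStepPx maximal arc length between successive circle samples.
#' @return a \linkS4class{ShollProfile}.
#' @examples
#' m <- matrix(FALSE, 41, 41); m[21, 21:41] <- TRUE  # one ray
#' b <- new("BinaryImage", mask = m, pixelSizeXY = 1,
#'          thresholdValue = 0, thresholdMethod = "fixed")
#' counts(shollProfile(b, center = c(20, 20), stepUm = 2, maxRadiusUm = 18))
#' @export
shollProfile <- function(binary, center, stepUm = 1.0, maxRadiusUm = NULL,
                         arcStepPx = 0.5) {
  stopifnot(is(binary, "BinaryImage"))
  if (stepUm <= 0)
    dtcStop("dtcError_badStep", "stepUm must be > 0")
  msk <- binary@mask
  h <- nrow(msk); w <- ncol(msk)
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    dtcStop("dtcError_centerOutside",
            "center (%.1f, %.1f) lies outside the %d x %d image", cx, cy, w, h)
  pxSize <- binary@pixelSizeXY
  if (is.null(maxRadiusUm)) {
    corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
    maxRadiusUm <- max(sqrt((corners[, 1] - cx)^2 + (corners[, 2] - cy)^2)) *
      pxSize
  }
  k <- floor(maxRadiusUm / stepUm + 1e-9)
  radii <- seq_len(k) * stepUm
  cnt <- vapply(radii, function(r) {
    countCircularRuns(circleSamples(msk, cx, cy, r / pxSize, arcStepPx))
  }, integer(1))
  new("ShollProfile", center = as.numeric(center), stepUm = stepUm,
      radiiUm = radii, counts = cnt, pixelSizeXY = pxSize)
}

#' Summary statistics of a Sholl profile
#'
#' @param profile a nonempty \linkS4class{ShollProfile}.
#' @return a list: \code{maxCount}, \code{radiusAtMaxUm} (smallest radius
#'   attaining the maximum; 0 when all counts are 0), \code{sumCounts}, and
#'   \code{extentUm} (last radius with a positive count; 0 if none). The
#'   summary is invariant under trailing zero radii.
#' @export
profileSummary <- function(profile) {
  stopifnot(is(profile, "ShollProfile"))
  if (!length(profile@counts))
    dtcStop("dtcError_emptyProfile", "profile has no radii")
  cnt <- profile@counts; rad <- profile@radiiUm
  mx <- max(cnt)
  list(
    maxCount = as.integer(mx),
    radiusAtMaxUm = if (mx > 0) rad[which.max(cnt)] else 0,
    sumCounts = as.integer(sum(cnt)),
    extentUm = if (any(cnt > 0)) max(rad[cnt > 0]) else 0
  )
}
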