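#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a CurvePath
#'
#' The first control point is the distal end by contract (mirroring the
#' draw-direction rule for straightening: distal ends up at the left); the
#' direction is trusted, never inferred.
#'
#' @param points n x 2 numeric matrix (or list of (x, y) pairs) of 0-based
#'   pixel coordinates, n >= 2, first point distal.
#' @param bandWidthPx odd integer >= 3: width of the band sampled along the
#'   path normals.
#' @return a \linkS4class{CurvePath}.
#' @export
curvePath <- function(points, bandWidthPx = 121L) {
  if (is.list(points)) points <- do.call(rbind, lapply(points, as.numeric))
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  new("CurvePath", points = points, bandWidthPx = as.integer(bandWidthPx))
}

#' Read a straightening path from JSON
#'
#' Format: \code{\{"points": [[x, y], ...], "band_width_px": int\}}.
#' @param path JSON file.
#' @return a \linkS4class{CurvePath}.
#' @export
readCurvePath <- function(path) {
  if (!file.exists(path))
    dtcStop("dtcError_missingFile", "path file does not exist: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  curvePath(j$points, j$band_width_px %||% 121L)
}

#' Write a straightening path to JSON
#' @param path a \linkS4class{CurvePath}.
#' @param file destination JSON file.
#' @export
writeCurvePath <- function(path, file) {
  jsonlite::write_json(
    list(points = unname(apply(path@points, 1, as.numeric, simplify = FALSE)),
         band_width_px = path@bandWidthPx),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

# cubic-spline (chord-length parameterized) evaluators for a control polygon;
# straight interpolation when only 2 points
pathSplines <- function(points) {
  n <- nrow(points)
  if (n == 2L) {
    p0 <- points[1, ]; d <- points[2, ] - points[1, ]
    len <- sqrt(sum(d^2)); u <- d / len
    list(
      eval = function(s) cbind(p0[1] + s * u[1], p0[2] + s * u[2]),
      deriv = function(s) cbind(rep(u[1], length(s)), rep(u[2], length(s))),
      chordLength = len, linear = TRUE)
  } else {
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
    t <- c(0, cumsum(seg))
    fx <- stats::splinefun(t, points[, 1], method = "natural")
    fy <- stats::splinefun(t, points[, 2], method = "natural")
    list(
      eval = function(s) cbind(fx(s), fy(s)),
      deriv = function(s) cbind(fx(s, deriv = 1), fy(s, deriv = 1)),
      chordLength = t[n], linear = FALSE)
  }
}

#' Resample a curved path at uniform arc-length spacing
#'
#' Realizes the segmented-line path as a smooth curve: a natural cubic spline
#' through the control points with chord-length parameterization (straight
#' interpolation for 2 points), resampled at points \code{spacingPx} apart in
#' arc length. Order and endpoints are preserved: the first output point is
#' the first (distal) control point and the last output point lies within
#' \code{spacingPx} of the final control point.
#'
#' @param path a \linkS4class{CurvePath}.
#' @param spacingPx positive arc-length spacing in pixels (default 1).
#' @return a list with \code{points} (m x 2), unit \code{tangents} (m x 2),
#'   \code{arc} (arc length of each point, px) and \code{totalLength}.
#' @examples
#' rp <- resamplePath(curvePath(rbind(c(0, 5), c(100, 5))), spacingPx = 1)
#' nrow(rp$points)  # 101
#' @export
resamplePath <- function(path, spacingPx = 1) {
  stopifnot(is(path, "CurvePath"), spacingPx > 0)
  sp <- pathSplines(path@points)
  if (sp$linear) {
    L <- sp$chordLength
    if (L < spacingPx)
      dtcStop("dtcError_degeneratePath",
              "path length %.3g px is shorter than the spacing %.3g px", L,
              spacingPx)
    s <- seq(0, by = spacingPx, length.out = floor(L / spacingPx) + 1)
    tg <- sp$deriv(s)
    return(list(points = sp$eval(s), tangents = tg, arc = s, totalLength = L))
  }
  # dense evaluation for the arc-length reparameterization
  nDense <- max(1000L, ceiling(sp$chordLength * 20))
  td <- seq(0, sp$chordLength, length.out = nDense)
  pd <- sp$eval(td)
  seg <- sqrt(rowSums((pd[-1, , drop = FALSE] - pd[-nDense, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[nDense]
  if (L < spacingPx)
    dtcStop("dtcError_degeneratePath",
            "path length %.3g px is shorter than the spacing %.3g px", L,
            spacingPx)
  s <- seq(0, by = spacingPx, length.out = floor(L / spacingPx) + 1)
  ts <- stats::approx(cum, td, xout = s, ties = "ordered")$y
  pts <- sp$eval(ts)
  tg <- sp$deriv(ts)
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg, arc = s, totalLength = L)
}

#' Straighten an image along a curved path
#'
#' Resamples the image along the path so the curve becomes the horizontal
#' axis: output column \code{j} is the bilinear interpolation of the image
#' along the unit normal of the resampled path at its \code{j}-th point, at
#' offsets \code{-(w-1)/2 ... +(w-1)/2} where \code{w} is the band width.
#' Column 0 corresponds to the path's first (distal) point, so distal is
#' left. Samples falling outside the image are 0-filled and flagged via the
#' \code{"clipped"} attribute.
#'
#' Along a straight horizontal path the result equals the axis-aligned crop
#' of the band, bit-exactly.
#'
#' @param image a \linkS4class{ProjectedImage} or numeric matrix.
#' @param path a \linkS4class{CurvePath}.
#' @param spacingPx arc-length sampling step (default 1 px).
#' @return numeric matrix with \code{bandWidthPx} rows, one column per
#'   resampled path point; attribute \code{"clipped"} counts out-of-bounds
#'   samples and attribute \code{"pathHash"} identifies the resampled path.
#' @export
straightenImage <- function(image, path, spacingPx = 1) {
  px <- if (is(image, "ProjectedImage")) image@pixels else image
  stopifnot(is(path, "CurvePath"))
  rp <- resamplePath(path, spacingPx)
  w <- path@bandWidthPx
  off <- seq.int(-(w - 1L) / 2L, (w - 1L) / 2L)
  # normal = tangent rotated +90 degrees in the y-down frame, so that for a
  # left-to-right path the band rows run top to bottom like the source image
  nx <- -rp$tangents[, 2]; ny <- rp$tangents[, 1]
  m <- nrow(rp$points)
  X <- outer(off, rp$points[, 1] + 0, function(o, x) x) +
    outer(off, nx, `*`)
  Y <- outer(off, rp$points[, 2] + 0, function(o, y) y) +
    outer(off, ny, `*`)
  vals <- bilinearSample(px, as.vector(X), as.vector(Y), fill = 0)
  out <- matrix(vals, nrow = w, ncol = m)
  h <- nrow(px); wd <- ncol(px)
  clipped <- sum(X < 0 | X > wd - 1 | Y < 0 | Y > h - 1)
  attr(out, "clipped") <- clipped
  attr(out, "pathHash") <- contentHash(rp$points)
  out
}

#' Crop or pad a straightened band to the batch's fixed box
#'
#' All specimens of a batch share identical output dimensions so that
#' montages line up and X-axis distances are comparable. Content is
#' left-anchored (the distal end is preserved) and right-padded with 0 or
#' truncated to \code{boxLengthPx}; vertically the output is centered on the
#' band's center row, padding or truncating symmetrically (one extra row at
#' the bottom when the difference is odd).
#'
#' @param straightened numeric matrix from \code{\link{straightenImage}}.
#' @param boxLengthPx,boxHeightPx positive box dimensions
#'   (defaults 550 x 120 px, about 119 x 26 um at 0.2167 um/px).
#' @param specimenId,pixelSizeXY metadata for the returned object.
#' @return a \linkS4class{StraightenedImage} of exactly
#'   \code{boxHeightPx x boxLengthPx}.
#' @export
cropFixedBox <- function(straightened, boxLengthPx = 550L, boxHeightPx = 120L,
                         specimenId = "specimen", pixelSizeXY = 1) {
  stopifnot(boxLengthPx > 0, boxHeightPx > 0)
  h <- nrow(straightened); w <- ncol(straightened)
  out <- matrix(0, nrow = boxHeightPx, ncol = boxLengthPx)
  nc <- min(w, boxLengthPx)
  # vertical alignment: center of the band maps to the center of the box
  top <- floor((boxHeightPx - h) / 2)           # offset of band row 1 in box
  srcRows <- seq_len(h)
  dstRows <- srcRows + top
  keep <- dstRows >= 1 & dstRows <= boxHeightPx
  out[dstRows[keep], seq_len(nc)] <- straightened[srcRows[keep], seq_len(nc)]
  hash <- attr(straightened, "pathHash") %||% ""
  img <- new("StraightenedImage", specimenId = specimenId,
             pixels = out, pixelSizeXY = pixelSizeXY,
             provenance = list(provStep("straighten", path_hash = hash),
                               provStep("crop_fixed_box",
                                        box_length_px = boxLengthPx,
                                        box_height_px = boxHeightPx)),
             sourcePathHash = hash)
  img
}
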