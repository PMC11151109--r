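#' @include AllClasses.R AllGenerics.R utils.R straighten.R markup.R
NULL

#' Construct synthetic-generator parameters
#'
#' Defaults emulate the acquisition regime the pipeline targets: 0.2167
#' um/px, 0.5 um Z steps, a bright cell body at ~50000 of the 16-bit range
#' next to thin processes at ~150 (intensities spanning orders of
#' magnitude without saturation), additive Gaussian noise in the low-noise
#' EMCCD regime. See \linkS4class{SynthParams} for slot semantics.
#'
#' @param width,height canvas size in pixels.
#' @param pixelSizeXY,zPlanes,zStep physical calibration.
#' @param centerline m x 2 control points of the gonad centerline (distal
#'   first); the default is a gently curved arm spanning the canvas.
#' @param layout \code{"gonad"} or \code{"rays"}.
#' @param bodyAmplitude,bodySigmaPx cell-body peak and width.
#' @param processAmplitude,processWidthPx process intensity and width.
#' @param nBranches,branchPositionsUm,branchLengthPx branch geometry;
#'   positions default to evenly spaced arc positions between 8 and 40 um.
#' @param nPuncta,punctaAmplitude,punctaSigmaPx puncta.
#' @param nFragments,fragmentAmplitude disconnected fragments.
#' @param nRays,rayLengthPx geometry of the \code{"rays"} layout.
#' @param backgroundLevel,noiseSd additive background and noise.
#' @param seed RNG seed.
#' @return a validated \linkS4class{SynthParams}.
#' @export
synthParams <- function(width = 420L, height = 180L,
                        pixelSizeXY = 0.2167, zPlanes = 7L, zStep = 0.5,
                        centerline = rbind(c(40, 60), c(140, 85),
                                           c(240, 105), c(340, 95)),
                        layout = "gonad",
                        bodyAmplitude = 50000, bodySigmaPx = 6,
                        processAmplitude = 150, processWidthPx = 3,
                        nBranches = 3L, branchPositionsUm = NULL,
                        branchLengthPx = 25,
                        nPuncta = 4L, punctaAmplitude = 8000,
                        punctaSigmaPx = 1.2,
                        nFragments = 2L, fragmentAmplitude = 300,
                        nRays = 5L, rayLengthPx = 60,
                        backgroundLevel = 100, noiseSd = 20,
                        seed = 1L) {
  if (is.null(branchPositionsUm))
    branchPositionsUm <- if (nBranches > 0)
      seq(8, 40, length.out = nBranches) else numeric()
  new("SynthParams",
      width = as.integer(width), height = as.integer(height),
      pixelSizeXY = pixelSizeXY, zPlanes = as.integer(zPlanes), zStep = zStep,
      centerline = matrix(as.numeric(centerline), ncol = 2), layout = layout,
      bodyAmplitude = bodyAmplitude, bodySigmaPx = bodySigmaPx,
      processAmplitude = processAmplitude, processWidthPx = processWidthPx,
      nBranches = as.integer(nBranches),
      branchPositionsUm = as.numeric(branchPositionsUm),
      branchLengthPx = branchLengthPx,
      nPuncta = as.integer(nPuncta), punctaAmplitude = punctaAmplitude,
      punctaSigmaPx = punctaSigmaPx,
      nFragments = as.integer(nFragments),
      fragmentAmplitude = fragmentAmplitude,
      nRays = as.integer(nRays), rayLengthPx = rayLengthPx,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# stamp a flat-intensity disc (max-composited) at each point of a polyline
stampTube <- function(canvas, pts, radius, amp) {
  r <- ceiling(radius)
  dd <- expand.grid(dx = -r:r, dy = -r:r)
  dd <- dd[dd$dx^2 + dd$dy^2 <= radius^2 + 1e-9, ]
  h <- nrow(canvas); w <- ncol(canvas)
  xs <- round(rep(pts[, 1], each = nrow(dd)) + dd$dx)
  ys <- round(rep(pts[, 2], each = nrow(dd)) + dd$dy)
  ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
  idx <- unique(cbind(ys[ok] + 1, xs[ok] + 1))
  canvas[idx] <- pmax(canvas[idx], amp)
  canvas
}

# additive isotropic Gaussian spot
stampGaussian <- function(canvas, cx, cy, sigma, amp) {
  r <- ceiling(4 * sigma)
  x0 <- max(0, round(cx) - r); x1 <- min(ncol(canvas) - 1, round(cx) + r)
  y0 <- max(0, round(cy) - r); y1 <- min(nrow(canvas) - 1, round(cy) + r)
  xs <- x0:x1; ys <- y0:y1
  g <- amp * outer(exp(-((ys - cy)^2) / (2 * sigma^2)),
                   exp(-((xs - cx)^2) / (2 * sigma^2)))
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + g
  canvas
}

#' Generate a synthetic calibrated DTC stack with ground truth
#'
#' Renders, in floating point and then quantized to 16 bits, a scene
#' emulating a fluorescently marked distal tip cell: a faint curved tube
#' (the gonad-arm process skeleton), a bright Gaussian cell body near the
#' distal tip, >= 2 px-wide processes branching at prescribed arc positions,
#' puncta as small Gaussian spots on the centerline, disconnected fragment
#' segments offset from the arm, a Gaussian axial intensity profile across
#' the Z planes, additive background and seeded Gaussian noise. No pixel
#' saturates (guarded by the parameter validity). The \code{"rays"} layout
#' instead renders straight rays radiating from the body centroid, the
#' geometry used to benchmark Sholl counting.
#'
#' With a fixed seed the output is bit-identical across runs (base R
#' Mersenne-Twister; all randomness flows through the seed).
#'
#' @param params a \linkS4class{SynthParams}.
#' @return list with \code{stack} (\linkS4class{CalibratedStack}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' out <- generateDtcStack(synthParams(seed = 7))
#' out$stack
#' head(out$truth@branchpoints)
#' @export
generateDtcStack <- function(params) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(params@seed)

  w <- params@width; h <- params@height
  canvas <- matrix(0, h, w)
  pxSize <- params@pixelSizeXY
  tubeR <- params@processWidthPx / 2

  emptyDf <- function(...) {
    cols <- list(...)
    as.data.frame(stats::setNames(rep(list(numeric()), length(cols)),
                                  unlist(cols)))
  }
  branchDf <- emptyDf("x", "y", "arc_um")
  punctaDf <- emptyDf("x", "y", "arc_um")
  fragDf <- emptyDf("x0", "y0", "x1", "y1", "mid_x", "mid_y")
  endDf <- emptyDf("x", "y")

  if (params@layout == "gonad") {
    spacing <- 0.5
    rp <- resamplePath(curvePath(params@centerline, 3L), spacingPx = spacing)
    dense <- rp$points
    distalTip <- dense[1, ]
    canvas <- stampTube(canvas, dense, tubeR, params@processAmplitude)
    bodyIdx <- min(nrow(dense), round(5 / spacing) + 1)
    bodyCentroid <- dense[bodyIdx, ]
    canvas <- stampGaussian(canvas, bodyCentroid[1], bodyCentroid[2],
                            params@bodySigmaPx, params@bodyAmplitude)

    lenUm <- rp$totalLength * pxSize
    side <- 1
    for (posUm in params@branchPositionsUm) {
      if (posUm <= 0 || posUm >= lenUm) next
      i <- round(posUm / pxSize / spacing) + 1
      base <- dense[i, ]
      arcUm <- rp$arc[i] * pxSize
      tg <- rp$tangents[i, ]
      nrm <- c(-tg[2], tg[1]) * side
      ang <- stats::runif(1, -0.3, 0.3)
      dir <- c(cos(ang) * nrm[1] - sin(ang) * nrm[2],
               sin(ang) * nrm[1] + cos(ang) * nrm[2])
      tEnd <- base + dir * params@branchLengthPx
      bpts <- cbind(seq(base[1], tEnd[1], length.out = 60),
                    seq(base[2], tEnd[2], length.out = 60))
      canvas <- stampTube(canvas, bpts, tubeR, params@processAmplitude)
      branchDf <- rbind(branchDf,
                        data.frame(x = base[1], y = base[2], arc_um = arcUm))
      endDf <- rbind(endDf, data.frame(x = tEnd[1], y = tEnd[2]))
      side <- -side
    }

    if (params@nPuncta > 0) {
      arcs <- sort(stats::runif(params@nPuncta, 3, lenUm * 0.9))
      for (aUm in arcs) {
        i <- round(aUm / pxSize / spacing) + 1
        p <- dense[i, ]
        canvas <- stampGaussian(canvas, p[1], p[2], params@punctaSigmaPx,
                                params@punctaAmplitude)
        punctaDf <- rbind(punctaDf,
                          data.frame(x = p[1], y = p[2],
                                     arc_um = rp$arc[i] * pxSize))
      }
    }

    if (params@nFragments > 0) {
      arcs <- stats::runif(params@nFragments, 5, lenUm * 0.95)
      for (aUm in arcs) {
        i <- round(aUm / pxSize / spacing) + 1
        tg <- rp$tangents[i, ]
        nrm <- c(-tg[2], tg[1]) * sample(c(-1, 1), 1)
        offset <- params@processWidthPx + params@branchLengthPx +
          stats::runif(1, 4, 10)
        base <- dense[i, ] + nrm * offset
        fEnd <- base + tg * 8
        fpts <- cbind(seq(base[1], fEnd[1], length.out = 20),
                      seq(base[2], fEnd[2], length.out = 20))
        canvas <- stampTube(canvas, fpts, tubeR, params@fragmentAmplitude)
        fragDf <- rbind(fragDf,
                        data.frame(x0 = base[1], y0 = base[2],
                                   x1 = fEnd[1], y1 = fEnd[2],
                                   mid_x = (base[1] + fEnd[1]) / 2,
                                   mid_y = (base[2] + fEnd[2]) / 2))
      }
    }
    centerline <- dense
  } else {  # rays
    bodyCentroid <- c((w - 1) / 2, (h - 1) / 2)
    distalTip <- bodyCentroid
    angles <- 2 * pi * (seq_len(params@nRays) - 1) / params@nRays + 0.13
    for (a in angles) {
      tEnd <- bodyCentroid + c(cos(a), sin(a)) * params@rayLengthPx
      bpts <- cbind(seq(bodyCentroid[1], tEnd[1], length.out = 200),
                    seq(bodyCentroid[2], tEnd[2], length.out = 200))
      canvas <- stampTube(canvas, bpts, tubeR, params@processAmplitude)
      endDf <- rbind(endDf, data.frame(x = tEnd[1], y = tEnd[2]))
    }
    canvas <- stampGaussian(canvas, bodyCentroid[1], bodyCentroid[2],
                            params@bodySigmaPx, params@bodyAmplitude)
    centerline <- rbind(bodyCentroid, bodyCentroid + c(params@rayLengthPx, 0))
  }

  # Gaussian axial profile across Z, peak weight 1 at the central plane
  zc <- (params@zPlanes + 1) / 2
  sigZ <- max(1, params@zPlanes / 4)
  zw <- exp(-0.5 * ((seq_len(params@zPlanes) - zc) / sigZ)^2)
  zw <- zw / max(zw)
  planes <- lapply(zw, function(wk) {
    p <- canvas * wk + params@backgroundLevel
    if (params@noiseSd > 0)
      p <- p + stats::rnorm(length(p), 0, params@noiseSd)
    p <- round(pmin(pmax(p, 0), 65535))
    storage.mode(p) <- "integer"
    p
  })

  stack <- new("CalibratedStack",
               specimenId = sprintf("synth%03d", params@seed),
               planes = planes, pixelSizeXY = pxSize, zStep = params@zStep,
               bitDepth = 16L)
  truth <- new("GroundTruth",
               centerline = centerline, distalTip = as.numeric(distalTip),
               bodyCentroid = as.numeric(bodyCentroid),
               branchpoints = branchDf, puncta = punctaDf,
               fragments = fragDf, endpoints = endDf,
               pixelSizeXY = pxSize)
  list(stack = stack, truth = truth)
}

#' Render a perfect user markup from ground truth
#'
#' Simulates an idealized annotator: emits the markup module's annotation
#' structure with marks at ground-truth coordinates and a distal anchor
#' circle tangent at the distal tip (center at tip + (radius, 0)), so the
#' anchor's leftmost point equals the ground-truth tip x exactly. Mark
#' coordinates are rounded to integer pixels (clicks land on pixels) unless
#' \code{roundPx = FALSE}.
#'
#' In the \code{"straightened"} frame positions are expressed in the
#' coordinate system of the image straightened along the ground-truth
#' centerline: x = arc-length position in pixels from the distal tip, y =
#' the band's center row. Only on-centerline features (branchpoints,
#' puncta) are emitted in that frame.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param frame \code{"original"} (source-image pixel coordinates) or
#'   \code{"straightened"}.
#' @param anchorRadiusPx radius of the distal anchor circle.
#' @param bandWidthPx band width of the straightening (center row of the
#'   straightened frame), used only for \code{frame = "straightened"}.
#' @param roundPx round mark coordinates to integer pixels.
#' @return an annotation list (see \code{\link{readAnnotations}}); write it
#'   with \code{\link{writeAnnotations}}.
#' @export
renderAnnotations <- function(truth, frame = c("original", "straightened"),
                              anchorRadiusPx = 15, bandWidthPx = 121L,
                              roundPx = TRUE) {
  stopifnot(is(truth, "GroundTruth"))
  frame <- match.arg(frame)
  rnd <- if (roundPx) round else identity
  pxSize <- truth@pixelSizeXY
  if (frame == "original") {
    anchor <- circleMark("distal_anchor",
                         truth@distalTip + c(anchorRadiusPx, 0),
                         anchorRadiusPx)
    marks <- rbind(
      if (nrow(truth@branchpoints))
        data.frame(feature_type = "branchpoint",
                   x = rnd(truth@branchpoints$x), y = rnd(truth@branchpoints$y)),
      if (nrow(truth@puncta))
        data.frame(feature_type = "punctum",
                   x = rnd(truth@puncta$x), y = rnd(truth@puncta$y)),
      if (nrow(truth@fragments))
        data.frame(feature_type = "fragment",
                   x = rnd(truth@fragments$mid_x), y = rnd(truth@fragments$mid_y)),
      if (nrow(truth@endpoints))
        data.frame(feature_type = "process_endpoint",
                   x = rnd(truth@endpoints$x), y = rnd(truth@endpoints$y)))
  } else {
    ctr <- (bandWidthPx - 1) / 2
    anchor <- circleMark("distal_anchor", c(anchorRadiusPx, ctr),
                         anchorRadiusPx)
    marks <- rbind(
      if (nrow(truth@branchpoints))
        data.frame(feature_type = "branchpoint",
                   x = rnd(truth@branchpoints$arc_um / pxSize), y = ctr),
      if (nrow(truth@puncta))
        data.frame(feature_type = "punctum",
                   x = rnd(truth@puncta$arc_um / pxSize), y = ctr))
  }
  if (is.null(marks))
    marks <- data.frame(feature_type = character(), x = numeric(),
                        y = numeric())
  list(distal_anchor = anchor, nucleus = NULL, marks = marks)
}
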