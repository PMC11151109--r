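# Fixture builders and independent oracles. Everything here is written
# independently of the package internals it checks.

# random 16-bit stack
randomStack <- function(nPlanes = 3, h = 40, w = 60, seed = 1,
                        pixelSize = 0.2167, zStep = 0.5) {
  set.seed(seed)
  planes <- lapply(seq_len(nPlanes), function(i) {
    m <- matrix(sample.int(65536L, h * w, replace = TRUE) - 1L, h, w)
    m
  })
  new("CalibratedStack", specimenId = sprintf("rnd%02d", seed),
      planes = planes, pixelSizeXY = pixelSize, zStep = zStep,
      bitDepth = 16L)
}

binImage <- function(m, pixelSize = 1) {
  new("BinaryImage", mask = m, pixelSizeXY = pixelSize,
      thresholdValue = 0, thresholdMethod = "fixed")
}

# stamp discs of radius hw at each point of a dense polyline (independent of
# the package's renderer)
stampMask <- function(mask, pts, hw) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(hw)
  for (i in seq_len(nrow(pts))) {
    xs <- max(0, floor(pts[i, 1] - r)):min(w - 1, ceiling(pts[i, 1] + r))
    ys <- max(0, floor(pts[i, 2] - r)):min(h - 1, ceiling(pts[i, 2] + r))
    for (x in xs) for (y in ys)
      if ((x - pts[i, 1])^2 + (y - pts[i, 2])^2 <= hw^2)
        mask[y + 1, x + 1] <- TRUE
  }
  mask
}

# k rays from a center with a minimum circular angular gap, >= 2 px wide
rayMask <- function(size, center, angles, len, hw = 1.25) {
  mask <- matrix(FALSE, size, size)
  for (a in angles) {
    t <- seq(0, len, by = 0.25)
    pts <- cbind(center[1] + t * cos(a), center[2] + t * sin(a))
    mask <- stampMask(mask, pts, hw)
  }
  mask
}

randomAngles <- function(k, minGap) {
  repeat {
    a <- sort(runif(k, 0, 2 * pi))
    gaps <- diff(c(a, a[1] + 2 * pi))
    if (min(gaps) >= minGap) return(a)
  }
}

# solid annulus sector (a full annulus when the span is 2*pi)
annulusMask <- function(size, center, r1, r2, a1 = 0, a2 = 2 * pi) {
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), size), size, size)
  d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  th <- atan2(ys - center[2], xs - center[1]) %% (2 * pi)
  inAng <- if (a2 - a1 >= 2 * pi - 1e-9) TRUE
           else (th - a1) %% (2 * pi) <= (a2 - a1)
  d >= r1 & d <= r2 & inAng
}

# independent Sholl oracle: counts maximal TRUE runs on the closed circle,
# sampled at a fixed (finer) arc step, written without reference to the
# package implementation
oracleShollCount <- function(mask, center, rPx, arcStep = 0.05) {
  n <- max(16L, ceiling(2 * pi * rPx / arcStep))
  th <- 2 * pi * (0:(n - 1)) / n
  x <- round(center[1] + rPx * cos(th))
  y <- round(center[2] + rPx * sin(th))
  ok <- x >= 0 & x < ncol(mask) & y >= 0 & y < nrow(mask)
  fg <- rep(FALSE, n)
  fg[ok] <- mask[cbind(y[ok] + 1, x[ok] + 1)]
  if (!any(fg)) return(0L)
  if (all(fg)) return(1L)
  # rotate so the sequence starts at a gap, then count runs linearly
  first0 <- which(!fg)[1]
  fg <- fg[c(first0:n, seq_len(first0 - 1))]
  r <- rle(fg)
  sum(r$values)
}

# random Sholl fixture on a 151x151 grid centered at (75, 75), designed so
# every foreground run and gap along the tested circles (radii 2..36) is at
# least 2 px wide: either an annulus sector with radial band [25, 35] (all
# even test radii are >= 1 px from the band edges, i.e. beyond the 0.71 px
# rounding reach), or 1..5 rays with angular gaps >= 0.8 rad over a central
# body disc of radius 7 that keeps sub-gap radii fully foreground
randomShollFixture <- function(sector = FALSE) {
  if (sector) {
    a1 <- runif(1, 0, 2 * pi)
    annulusMask(151, c(75, 75), 25, 35, a1, a1 + runif(1, 0.8, 2))
  } else {
    k <- sample(1:5, 1)
    rayMask(151, c(75, 75), randomAngles(k, minGap = 0.8),
            len = runif(1, 40, 55)) |
      annulusMask(151, c(75, 75), 0, 7)
  }
}

# build a small synthetic batch on disk: stack + straightening path +
# straightened-frame annotations per specimen
makeBatch <- function(dir, seeds) {
  for (seed in seeds) {
    out <- generateDtcStack(synthParams(seed = seed))
    stem <- specimenId(out$stack)
    writeImage(out$stack, file.path(dir, paste0(stem, ".tif")))
    ctrl <- out$truth@centerline[
      round(seq(1, nrow(out$truth@centerline), length.out = 8)), ]
    writeCurvePath(curvePath(ctrl, bandWidthPx = 61L),
                   file.path(dir, paste0(stem, ".path.json")))
    writeAnnotations(
      renderAnnotations(out$truth, frame = "straightened", bandWidthPx = 61L),
      file.path(dir, paste0(stem, ".ann.json")))
  }
}

batchConfig <- function(dir, outDir) {
  list(inputs = file.path(dir, sprintf("synth%03d.tif", 1:3)),
       outDir = outDir,
       stages = c("optimize", "straighten", "markup", "sholl"),
       straighten = list(boxLengthPx = 360L, boxHeightPx = 61L),
       sholl = list(center = c(10, 30), stepUm = 1, maxRadiusUm = 20))
}

# exhaustive Otsu oracle: threshold maximizing between-class variance over
# every candidate cutoff
oracleOtsu <- function(px) {
  cand <- sort(unique(round(as.vector(px))))
  best <- -Inf; bestT <- cand[1]
  v <- as.vector(px)
  for (t in cand[-length(cand)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    wb <- length(lo) / length(v); wf <- 1 - wb
    s <- wb * wf * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; bestT <- t }
  }
  bestT
}

# 90-degree clockwise rotation in the y-down pixel frame:
# (x, y) -> (h - 1 - y, x); matrix form below matches that mapping
rotateImage90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
rotatePoints90 <- function(pts, h) cbind(h - 1 - pts[, 2], pts[, 1])
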