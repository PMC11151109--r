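test_that("a fixed seed reproduces the stack bit-identically", {
  a <- generateDtcStack(synthParams(seed = 7))
  b <- generateDtcStack(synthParams(seed = 7))
  expect_identical(planes(a$stack), planes(b$stack))
  expect_identical(a$truth@branchpoints, b$truth@branchpoints)
  c <- generateDtcStack(synthParams(seed = 8))
  expect_false(identical(planes(a$stack), planes(c$stack)))
})

test_that("saturating parameter combinations are rejected, valid ones never saturate", {
  expect_error(synthParams(bodyAmplitude = 65000, backgroundLevel = 400,
                           noiseSd = 100),
               regexp = "saturate")
  expect_error(synthParams(processAmplitude = 2000))  # ratio < 50
  out <- generateDtcStack(synthParams(seed = 3))
  expect_lt(max(vapply(planes(out$stack), max, 0L)), 65535L)
})

test_that("the noise-free unbranched cell peaks at the body centroid", {
  p <- synthParams(seed = 5, noiseSd = 0, nBranches = 0, nPuncta = 0,
                   nFragments = 0)
  out <- generateDtcStack(p)
  proj <- pixels(maxProject(out$stack))
  peak <- which(proj == max(proj), arr.ind = TRUE)[1, ]
  ctr <- out$truth@bodyCentroid
  expect_lt(abs(peak[["col"]] - 1 - ctr[1]), 1.5)
  expect_lt(abs(peak[["row"]] - 1 - ctr[2]), 1.5)
})

test_that("ground-truth coordinates lie on rendered foreground", {
  out <- generateDtcStack(synthParams(seed = 11, noiseSd = 0))
  proj <- pixels(maxProject(out$stack))
  bg <- 100
  onFg <- function(x, y) proj[round(y) + 1, round(x) + 1] > bg + 50
  tr <- out$truth
  for (i in seq_len(nrow(tr@branchpoints)))
    expect_true(onFg(tr@branchpoints$x[i], tr@branchpoints$y[i]))
  for (i in seq_len(nrow(tr@puncta)))
    expect_true(onFg(tr@puncta$x[i], tr@puncta$y[i]))
  for (i in seq_len(nrow(tr@fragments)))
    expect_true(onFg(tr@fragments$mid_x[i], tr@fragments$mid_y[i]))
  # um positions consistent with px coordinates: arc in px * pixel size
  expect_true(all(tr@branchpoints$arc_um <=
                    nrow(tr@centerline) * 0.5 * tr@pixelSizeXY + 1e-9))
})

test_that("intensities span orders of magnitude and gamma compresses them as derived", {
  p <- synthParams(seed = 13, noiseSd = 0, nPuncta = 0, nFragments = 0)
  out <- generateDtcStack(p)
  proj <- pixels(maxProject(out$stack))
  tr <- out$truth
  # probe a mid-arm process pixel and the body peak, before optimization
  i <- round(nrow(tr@centerline) * 0.7)
  procRaw <- proj[round(tr@centerline[i, 2]) + 1, round(tr@centerline[i, 1]) + 1]
  bodyRaw <- max(proj)
  expect_lt((procRaw - 100) / (bodyRaw - 100), 0.01)  # processes < 1% of body
  # after optimization the dim processes are lifted to the closed-form level
  opt <- pixels(optimizeImage(out$stack))
  procOpt <- opt[round(tr@centerline[i, 2]) + 1, round(tr@centerline[i, 1]) + 1]
  closedForm <- sqrt((procRaw - 100) / (bodyRaw - 100)) * 65535
  expect_equal(procOpt, closedForm, tolerance = 0.02)
  # relative visibility boost of the gamma transform
  expect_gt((procOpt / 65535) / ((procRaw - 100) / (bodyRaw - 100)), 5)
})

test_that("rendered annotations mirror the ground truth", {
  out <- generateDtcStack(synthParams(seed = 21))
  ann <- renderAnnotations(out$truth)
  expect_identical(sum(ann$marks$feature_type == "branchpoint"),
                   nrow(out$truth@branchpoints))
  expect_identical(sum(ann$marks$feature_type == "punctum"),
                   nrow(out$truth@puncta))
  # anchor tangent at the tip: leftmost point equals the tip x exactly
  expect_equal(ann$distal_anchor@center[1] - ann$distal_anchor@radius,
               out$truth@distalTip[1])
})

test_that("the ray layout links the generator to Sholl counting", {
  p <- synthParams(seed = 9, layout = "rays", nRays = 5, rayLengthPx = 60,
                   noiseSd = 0, width = 220, height = 220)
  out <- generateDtcStack(p)
  proj <- pixels(maxProject(out$stack))
  bin <- binarize(proj, method = "fixed", fixedValue = 150,
                  pixelSizeXY = pixelSizeXY(out$stack))
  ctr <- out$truth@bodyCentroid
  prof <- shollProfile(bin, center = ctr, stepUm = 1,
                       maxRadiusUm = 55 * pixelSizeXY(out$stack))
  midUm <- radiiUm(prof) >= 25 * pixelSizeXY(out$stack)
  expect_true(all(counts(prof)[midUm] == 5L))
})
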