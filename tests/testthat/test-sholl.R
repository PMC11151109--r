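test_that("fixed thresholding marks exactly the pixels above the cutoff", {
  m <- matrix(c(0, 100), 10, 10)
  b <- binarize(m, method = "fixed", fixedValue = 0)
  expect_identical(mask(b), m > 0)
  expect_identical(thresholdValue(b), 0)
  # threshold above the maximum -> empty mask
  set.seed(2)
  noise <- matrix(rnorm(400, 50, 5), 20, 20)
  expect_false(any(mask(binarize(noise, method = "fixed", fixedValue = 100))))
})

test_that("otsu threshold separates a two-Gaussian histogram and matches the exhaustive oracle", {
  set.seed(77)
  px <- matrix(round(c(rnorm(3000, 200, 40), rnorm(1000, 5000, 300))), 40, 100)
  px[px < 0] <- 0
  th <- thresholdValue(binarize(px, method = "otsu"))
  expect_gt(th, 200)
  expect_lt(th, 5000)
  oracle <- oracleOtsu(px)
  # same separation of the two populations as the exhaustive search
  expect_identical(px > th, px > oracle)
  expect_error(binarize(matrix(3, 5, 5), method = "otsu"),
               class = "dtcError_constantImage")
  expect_error(binarize(px, method = "fixed"),
               class = "dtcError_missingThreshold")
})

test_that("an empty mask yields all-zero counts", {
  b <- binImage(matrix(FALSE, 50, 50))
  p <- shollProfile(b, center = c(25, 25), stepUm = 1, maxRadiusUm = 20)
  expect_true(all(counts(p) == 0L))
  expect_length(radiiUm(p), 20L)
})

test_that("a single ray counts 1 inside its length and 0 beyond", {
  set.seed(51)
  mask <- rayMask(121, c(60, 60), angles = 0.7, len = 40)
  p <- shollProfile(binImage(mask), center = c(60, 60), stepUm = 1,
                    maxRadiusUm = 55)
  cnt <- counts(p)
  expect_true(all(cnt[5:38] == 1L))
  expect_true(all(cnt[44:55] == 0L))
})

test_that("k disjoint rays count k at mid radii and counts superpose", {
  set.seed(52)
  for (k in c(2, 5)) {
    ang <- randomAngles(k, minGap = 0.8)
    mask <- rayMask(151, c(75, 75), ang, len = 55)
    p <- shollProfile(binImage(mask), center = c(75, 75), stepUm = 1,
                      maxRadiusUm = 50)
    expect_true(all(counts(p)[15:50] == k),
                label = sprintf("k = %d rays at mid radii", k))
  }
  # superposition: disjoint ray sets add
  a1 <- c(0.3, 2.2); a2 <- c(1.2, 3.6, 5.0)
  m1 <- rayMask(151, c(75, 75), a1, len = 55)
  m2 <- rayMask(151, c(75, 75), a2, len = 55)
  c1 <- counts(shollProfile(binImage(m1), c(75, 75), 1, 50))
  c2 <- counts(shollProfile(binImage(m2), c(75, 75), 1, 50))
  c12 <- counts(shollProfile(binImage(m1 | m2), c(75, 75), 1, 50))
  mid <- 15:50
  expect_identical(c12[mid], c1[mid] + c2[mid])
})

test_that("a foreground annulus counts exactly 1 across its radii", {
  mask <- annulusMask(121, c(60, 60), 15, 25)
  p <- shollProfile(binImage(mask), center = c(60, 60), stepUm = 1,
                    maxRadiusUm = 40)
  expect_true(all(counts(p)[16:24] == 1L))
  expect_true(all(counts(p)[c(1:13, 28:40)] == 0L))
})

test_that("standard sampling equals a 10x finer independent oracle on random fixtures", {
  set.seed(1234)
  for (i in 1:12) {
    mask <- randomShollFixture(i %% 3 == 0)
    p <- shollProfile(binImage(mask), center = c(75, 75), stepUm = 2,
                      maxRadiusUm = 36)
    oracle <- vapply(radiiUm(p), function(r)
      oracleShollCount(mask, c(75, 75), r), integer(1))
    expect_identical(counts(p), oracle)
  }
})

test_that("counts are invariant under lossless 90-degree rotation", {
  set.seed(53)
  mask <- rayMask(151, c(70, 80), randomAngles(4, 0.8), len = 50)
  p1 <- counts(shollProfile(binImage(mask), c(70, 80), 1, 45))
  maskR <- rotateImage90(mask)
  ctrR <- rotatePoints90(rbind(c(70, 80)), nrow(mask))[1, ]
  p2 <- counts(shollProfile(binImage(maskR), ctrR, 1, 45))
  # radii where every run and gap is >= 2 px wide (transversal crossings);
  # smaller circles probe the rounded ray-origin cap at sub-sample scale
  expect_identical(p1[8:45], p2[8:45])
  expect_identical(p1[1:3], p2[1:3])  # fully inside the origin cap
})

test_that("counts vanish beyond the farthest foreground pixel", {
  set.seed(54)
  mask <- rayMask(151, c(75, 75), c(1.1, 4.0), len = 30)
  idx <- which(mask, arr.ind = TRUE)
  maxDist <- max(sqrt((idx[, 2] - 1 - 75)^2 + (idx[, 1] - 1 - 75)^2))
  p <- shollProfile(binImage(mask), c(75, 75), stepUm = 1, maxRadiusUm = 70)
  # nearest-neighbor lookup can round a sample onto a foreground pixel up to
  # half a pixel diagonal away, so the reach ends at maxDist + sqrt(2)/2
  beyond <- radiiUm(p) > maxDist + sqrt(2) / 2
  expect_true(all(counts(p)[beyond] == 0L))
})

test_that("degenerate inputs are named failures", {
  b <- binImage(matrix(TRUE, 10, 10))
  expect_error(shollProfile(b, c(50, 50)), class = "dtcError_centerOutside")
  expect_error(shollProfile(b, c(5, 5), stepUm = 0),
               class = "dtcError_badStep")
})

test_that("profile summaries scan counts correctly and ignore trailing zeros", {
  mk <- function(cnt, step = 1)
    new("ShollProfile", center = c(0, 0), stepUm = step,
        radiiUm = seq_along(cnt) * step, counts = as.integer(cnt),
        pixelSizeXY = 1)
  s <- profileSummary(mk(c(1, 3, 2, 0)))
  expect_identical(s$maxCount, 3L)
  expect_equal(s$radiusAtMaxUm, 2)
  expect_identical(s$sumCounts, 6L)
  expect_equal(s$extentUm, 3)
  z <- profileSummary(mk(c(0, 0, 0)))
  expect_identical(z$maxCount, 0L)
  expect_equal(z$extentUm, 0)
  expect_identical(profileSummary(mk(c(1, 3, 2, 0, 0, 0)))[c(1, 2, 4)],
                   s[c(1, 2, 4)])
})

test_that("sholl profiles round-trip through CSV exactly", {
  dir <- withr::local_tempdir()
  set.seed(55)
  mask <- rayMask(121, c(60, 60), randomAngles(3, 0.8), len = 40)
  p <- shollProfile(binImage(mask, pixelSize = 0.2167), c(60, 60),
                    stepUm = 1, maxRadiusUm = 12)
  f <- file.path(dir, "prof.csv")
  writeShollProfile(p, f)
  r <- readShollProfile(f)
  expect_identical(counts(r), counts(p))
  expect_equal(radiiUm(r), radiiUm(p))
  expect_equal(shollCenter(r), shollCenter(p))
  expect_equal(pixelSizeXY(r), 0.2167)
})
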