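test_that("maximum projection matches an exhaustive per-pixel loop", {
  s <- randomStack(nPlanes = 3, h = 25, w = 30, seed = 11)
  got <- pixels(maxProject(s))
  expected <- matrix(0, 25, 30)
  for (i in 1:25) for (j in 1:30)
    expected[i, j] <- max(vapply(planes(s), function(p) p[i, j], 0L))
  expect_equal(got, expected, ignore_attr = TRUE)
  # projection dominates every plane
  for (p in planes(s)) expect_true(all(got >= p))
})

test_that("projection of identical planes is that plane", {
  p <- planes(randomStack(1, seed = 3))[[1]]
  s <- new("CalibratedStack", specimenId = "k", planes = list(p, p, p, p),
           pixelSizeXY = 1, zStep = 1, bitDepth = 16L)
  expect_equal(pixels(maxProject(s)), p * 1.0, ignore_attr = TRUE)
})

test_that("background estimate equals the darkest-fraction mean with tie handling", {
  # constant image
  expect_equal(estimateBackground(matrix(7, 10, 10), 0.001), 7)
  # 99.9% zeros, 0.1% bright
  m <- matrix(0, 100, 100)
  m[sample.int(1e4, 10)] <- 1000
  expect_equal(estimateBackground(m, 0.001), 0)
  # two-value image, cutoff lands inside the lower population
  m2 <- matrix(c(rep(10, 5000), rep(1000, 5000)), 100, 100)
  expect_equal(estimateBackground(m2, 0.25), 10)
})

test_that("background estimator matches a sort-based oracle on random images", {
  set.seed(42)
  for (i in 1:100) {
    nr <- sample(c(1, 2, 5, 10), 1); nc <- sample(10:40, 1)
    vals <- sample.int(200L, nr * nc, replace = TRUE) - 1L
    m <- matrix(vals, nrow = nr)
    frac <- runif(1, 0.001, 0.4)
    v <- sort(as.vector(m))
    k <- ceiling(frac * length(v))
    oracle <- mean(v[v <= v[k]])
    expect_equal(estimateBackground(m, frac), oracle)
  }
})

test_that("gamma 1 with zero background is a pure linear rescale", {
  p <- matrix(c(0L, sample.int(60000L, 398, replace = TRUE), 60000L), 20, 20)
  p[1] <- 0L  # guarantee enough zeros that the darkest-fraction mean is 0
  s <- new("CalibratedStack", specimenId = "lin", planes = list(p),
           pixelSizeXY = 1, zStep = 1, bitDepth = 16L)
  out <- pixels(optimizeImage(s, gamma = 1, backgroundFraction = 0.001))
  expect_equal(out, p / max(p) * 65535, ignore_attr = TRUE)
})

test_that("gamma 0.5 maps normalized 0.25 to half the output ceiling exactly", {
  p <- matrix(0L, 10, 10); p[5, 5] <- 4000L; p[5, 6] <- 1000L
  s <- new("CalibratedStack", specimenId = "g", planes = list(p),
           pixelSizeXY = 1, zStep = 1, bitDepth = 16L)
  out <- pixels(optimizeImage(s, gamma = 0.5))
  expect_equal(out[5, 6], 0.5 * 65535)
  expect_equal(out[5, 5], 65535)
})

test_that("output range is exactly [0, outputMax] for non-constant inputs", {
  for (seed in 1:5) {
    s <- randomStack(nPlanes = 2, seed = seed)
    for (outputMax in c(255, 65535)) {
      out <- pixels(optimizeImage(s, outputMax = outputMax))
      expect_identical(min(out), 0)
      expect_identical(max(out), outputMax)
    }
  }
})

test_that("optimization is monotone and gamma < 1 compresses ratios", {
  s <- randomStack(nPlanes = 3, seed = 21)
  pre <- pixels(maxProject(s))
  post <- pixels(optimizeImage(s, gamma = 0.5))
  o <- order(pre)
  expect_true(all(diff(post[o]) >= 0))
  # ratio compression on two positive normalized values
  i <- which(pre == max(pre))[1]; j <- which(pre > 0 & pre < max(pre))[1]
  expect_gte(pre[i] / pre[j], post[i] / post[j])
})

test_that("constant-after-subtraction input is a named failure", {
  p <- matrix(5L, 8, 8)
  s <- new("CalibratedStack", specimenId = "c", planes = list(p),
           pixelSizeXY = 1, zStep = 1, bitDepth = 16L)
  expect_error(optimizeImage(s), class = "dtcError_constantImage")
})

test_that("two-population image lands at the closed-form intensity ratio", {
  # dim processes ~100, bright body ~50000, zero background
  p <- matrix(0L, 50, 50)
  p[20, 1:30] <- 100L
  p[35, 1:30] <- 50000L
  s <- new("CalibratedStack", specimenId = "2pop", planes = list(p),
           pixelSizeXY = 1, zStep = 1, bitDepth = 16L)
  out <- pixels(optimizeImage(s, gamma = 0.5))
  ratio <- out[35, 5] / out[20, 5]
  expect_equal(ratio, sqrt(50000 / 100), tolerance = 1e-9)  # ~22.36
})
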