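test_that("the distal origin is the leftmost point of the anchor circle", {
  expect_equal(distalOriginX(circleMark("distal_anchor", c(100, 60), 40)), 60)
  expect_error(distalOriginX(circleMark("nucleus", c(100, 60), 40)),
               class = "dtcError_wrongRole")
  expect_error(circleMark("distal_anchor", c(10, 10), 0))  # radius > 0 invariant
})

test_that("mark distances are signed X-axis distances in micrometres", {
  expect_equal(markDistanceUm(60, 60, 0.2167), 0)
  expect_equal(markDistanceUm(160, 60, 0.2167), 21.67)
  expect_lt(markDistanceUm(40, 60, 0.2167), 0)
  # y is excluded by contract: distance depends only on x
  rec <- markupRecord("s", 0.5, circleMark("distal_anchor", c(20, 50), 10),
                      marks = data.frame(feature_type = c("punctum", "punctum"),
                                         x = c(30, 30), y = c(0, 110)))
  expect_equal(distancesUm(rec), c(10, 10))
})

test_that("measure-all-markups emits detail rows and per-type counts", {
  anchor <- circleMark("distal_anchor", c(50, 60), 40)
  mk <- data.frame(
    feature_type = c("branchpoint", "punctum", "branchpoint", "punctum",
                     "branchpoint"),
    x = c(60, 80, 100, 120, 140), y = rep(60, 5))
  rec <- markupRecord("worm07", 0.2167, anchor, marks = mk)
  tab <- measureAllMarkups(rec)
  detail <- tab[!is.na(tab$x_px) & tab$feature_type != "distal_origin", ]
  expect_identical(nrow(detail), 5L)
  cnt <- featureCounts(rec)
  expect_identical(cnt[["branchpoint"]], 3L)
  expect_identical(cnt[["punctum"]], 2L)
  expect_identical(cnt[["fragment"]], 0L)
  # summary rows carry the counts in the index column
  summ <- tab[is.na(tab$x_px), ]
  expect_identical(summ$index[summ$feature_type == "branchpoint"], 3L)
  # indices number marks within their type
  expect_identical(detail$index[detail$feature_type == "branchpoint"], 1:3)
  # empty record: only the origin row and zero-count summary rows
  tab0 <- measureAllMarkups(markupRecord("empty", 1, anchor))
  expect_identical(sum(!is.na(tab0$x_px)), 1L)  # the distal origin itself
  expect_true(all(tab0$index[is.na(tab0$x_px)] == 0L))
  expect_identical(tab0$distance_um[tab0$feature_type == "distal_origin" &
                                      !is.na(tab0$x_px)], 0)
})

test_that("distances are translation-covariant and scale with pixel size", {
  set.seed(31)
  mk <- data.frame(feature_type = sample(c("branchpoint", "punctum"), 8,
                                         replace = TRUE),
                   x = runif(8, 0, 300), y = runif(8, 0, 100))
  anchor <- circleMark("distal_anchor", c(40, 50), 25)
  rec <- markupRecord("t", 0.2167, anchor, marks = mk)
  dx <- 37.5
  shifted <- markupRecord("t", 0.2167,
                          circleMark("distal_anchor", c(40 + dx, 50), 25),
                          marks = transform(mk, x = x + dx))
  expect_equal(distancesUm(shifted), distancesUm(rec))
  doubled <- markupRecord("t", 2 * 0.2167, anchor, marks = mk)
  expect_equal(distancesUm(doubled), 2 * distancesUm(rec))
  # counts are permutation-invariant
  perm <- markupRecord("t", 0.2167, anchor, marks = mk[sample(8), ])
  expect_identical(featureCounts(perm), featureCounts(rec))
})

test_that("markup records round-trip through the TSV to 4 decimals", {
  dir <- withr::local_tempdir()
  anchor <- circleMark("distal_anchor", c(52.3456, 60.1), 40.25)
  nuc <- circleMark("nucleus", c(110.5, 58.75), 7.5)
  mk <- data.frame(feature_type = c("branchpoint", "punctum", "fragment"),
                   x = c(60.12345, 123.9876, 201.5),
                   y = c(61.5, 55.5555, 63))
  rec <- markupRecord("worm42", 0.2167, anchor, marks = mk, nucleus = nuc)
  tab <- measureAllMarkups(rec, outDir = dir)
  path <- attr(tab, "path")
  expect_identical(basename(path), "worm42.markup.tsv")
  back <- readMarkupTable(path)
  expect_identical(specimenId(back), "worm42")
  expect_equal(pixelSizeXY(back), 0.2167)
  expect_equal(distalAnchor(back)@center, anchor@center, tolerance = 1e-4)
  expect_equal(nucleusMark(back)@radius, 7.5, tolerance = 1e-4)
  m0 <- marks(rec); m1 <- marks(back)
  expect_identical(m1$feature_type, m0$feature_type)
  expect_equal(m1$x, m0$x, tolerance = 1e-4)
  expect_equal(m1$y, m0$y, tolerance = 1e-4)
  expect_equal(distancesUm(back), distancesUm(rec), tolerance = 2e-4)
  expect_identical(featureCounts(back), featureCounts(rec))
  # the nucleus center was logged as a mark
  expect_identical(featureCounts(back)[["nucleus_center"]], 1L)
})

test_that("unknown feature types are rejected against the vocabulary", {
  anchor <- circleMark("distal_anchor", c(40, 50), 25)
  expect_error(
    markupRecord("v", 1, anchor,
                 marks = data.frame(feature_type = "soma", x = 1, y = 1)),
    class = "dtcError_unknownFeature")
  # but a custom vocabulary admits it
  rec <- markupRecord("v", 1, anchor,
                      marks = data.frame(feature_type = "soma", x = 1, y = 1),
                      vocabulary = c("soma", "distal_origin"))
  expect_identical(featureCounts(rec)[["soma"]], 1L)
})
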