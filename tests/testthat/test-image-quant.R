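# Line-profile membrane-expression quantification.

test_that("profile extraction samples constant images exactly", {
  img <- matrix(7, 32, 32)
  pr <- extractProfile(img, c(2, 10), c(28, 10))
  expect_true(all(pr@intensities == 7))
  expect_length(pr@intensities, 27)
  expect_error(extractProfile(img, c(5, 5), c(5, 5)), "zero-length")
  expect_error(extractProfile(img, c(-2, 5), c(10, 5)), "bounds")
})

test_that("profile peak sits at the ring radius of a synthetic cell", {
  # a little blur gives the radial profile a unique maximum at the ring
  # centre (the unblurred annulus has a flat top)
  img <- generateCellImage(0.8, blurSdPx = 1, noiseSd = 0)
  gt <- img$groundTruth
  cl <- img$lines[img$lines$role == "cell", ][1, ]
  pr <- extractProfile(img$image, c(cl$x0, cl$y0), c(cl$x1, cl$y1))
  peakPos <- pr@positions[which.max(pr@intensities)]
  # distance of the peak sample from the cell centre vs the true radius
  lineLen <- max(pr@positions)
  distFromCentre <- abs(peakPos - lineLen / 2)
  expect_lte(abs(distFromCentre - gt$radiusPx), 1)
})

test_that("reversing the endpoints reverses the profile", {
  img <- generateCellImage(0.6, blurSdPx = 1, noiseSd = 0)
  fwd <- extractProfile(img$image, c(5, 31.5), c(58, 31.5))
  rev <- extractProfile(img$image, c(58, 31.5), c(5, 31.5))
  expect_equal(rev@intensities, base::rev(fwd@intensities),
               tolerance = 1e-12)
})

test_that("relative expression implements the background-peak formula", {
  pr <- new("LineProfile", positions = 0:2,
            intensities = c(30, 100, 30), background = rep(20, 3),
            cellId = "c", lineId = "l")
  expect_equal(as.numeric(relativeMembraneExpression(pr, imageMax = 160)),
               0.5)

  # gain invariance: scaling image and background together
  prG <- new("LineProfile", positions = 0:2,
             intensities = 3 * c(30, 100, 30), background = rep(60, 3),
             cellId = "c", lineId = "l")
  expect_equal(as.numeric(relativeMembraneExpression(prG,
                                                     imageMax = 480)),
               0.5)

  # background above peak clips to 0 with a flag
  prBad <- new("LineProfile", positions = 0:2,
               intensities = c(10, 12, 11), background = rep(50, 3),
               cellId = "c", lineId = "l")
  expect_warning(v <- relativeMembraneExpression(prBad, imageMax = 160),
                 "clipped")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clipped"))

  expect_error(relativeMembraneExpression(
    new("LineProfile", positions = 0:1, intensities = c(1, 2),
        background = numeric(0), cellId = "c", lineId = "l"),
    imageMax = 160), "background")
})

test_that("noiseless unblurred chain returns the true expression exactly", {
  for (expr in c(0, 0.37, 0.5, 1)) {
    img <- generateCellImage(expr, blurSdPx = 0, noiseSd = 0)
    if (expr == 0) {
      expect_true(all(img$image == img$groundTruth$background))
      next
    }
    expect_equal(max(img$image),
                 img$groundTruth$background + expr * 160, tolerance = 1e-12)
    m <- suppressWarnings(quantifyMembrane(img$image, img$lines,
                                           imageMax = 160))
    expect_lt(abs(m@cohortMean - expr), 1e-6)
  }
})

test_that("cohort recovery at the basal expression level (30 cells)", {
  perLine <- syntheticCohortValues(30, expressionTrue = 0.37,
                                   blurSdPx = 1, noiseSd = 2)
  m <- aggregateCells(perLine)
  expect_equal(m@nCells, 30L)
  expect_lt(abs(m@cohortMean - 0.37), 0.05)
})

test_that("blur bias is monotone in the blur width", {
  means <- vapply(c(0, 1, 2, 3), function(b) {
    perLine <- syntheticCohortValues(5, expressionTrue = 0.5,
                                     blurSdPx = b, noiseSd = 0,
                                     seedOffset = 100)
    suppressWarnings(aggregateCells(perLine))@cohortMean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("aggregation is per-cell first, then across cells", {
  one <- data.frame(cellId = "c1", lineId = paste0("l", 1:3),
                    value = c(0.4, 0.5, 0.6))
  m1 <- suppressWarnings(aggregateCells(one))
  expect_equal(m1@perCell$value, 0.5)
  expect_true(is.na(m1@cohortSd))

  # identical cells -> SD 0
  same <- do.call(rbind, lapply(1:4, function(i)
    transform(one, cellId = paste0("c", i))))
  mSame <- suppressWarnings(aggregateCells(same))
  expect_equal(mSame@cohortSd, 0)

  # heterogeneous fixture: per-cell SD differs from pooled-line SD, and the
  # per-cell path is the implemented one
  het <- rbind(
    data.frame(cellId = "a", lineId = paste0("l", 1:3),
               value = c(0.1, 0.5, 0.9)),
    data.frame(cellId = "b", lineId = paste0("l", 1:3),
               value = c(0.45, 0.5, 0.55)))
  mHet <- suppressWarnings(aggregateCells(het))
  pooledSd <- sd(het$value)
  perCellSd <- sd(c(0.5, 0.5))
  expect_false(isTRUE(all.equal(pooledSd, perCellSd)))
  expect_equal(mHet@cohortSd, perCellSd)

  # wrong line count is a warning, not an error
  w <- capture_warnings(aggregateCells(rbind(one, one[1, ])))
  expect_match(w, "other than 3", all = FALSE)
})
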