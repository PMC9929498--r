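test_that("area equals the per-pixel counting oracle", {
  expect_identical(binaryArea(matrix(TRUE, 5, 5)), 25L)
  expect_identical(binaryArea(matrix(FALSE, 5, 5)), 0L)
  set.seed(7)
  for (rep in 1:5) {
    b <- matrix(runif(64 * 64) < runif(1, 0.2, 0.8), 64, 64)
    expect_identical(binaryArea(b), areaOracle(b))
  }
})

test_that("perimeter estimators behave on squares and discs", {
  expect_equal(binaryPerimeter(matrix(FALSE, 8, 8), "crofton4"), 0)
  expect_equal(binaryPerimeter(matrix(FALSE, 8, 8), "boundary_edges"), 0)
  for (n in c(10, 25, 40)) {
    sq <- makeSquare(n)
    expect_equal(binaryPerimeter(sq, "boundary_edges"), 4 * n)
    expect_lt(abs(binaryPerimeter(sq, "crofton4") - 4 * n) / (4 * n), 0.15)
  }
  disc <- makeDisc(25)
  expect_lt(abs(binaryPerimeter(disc, "crofton4") - 2 * pi * 25) /
            (2 * pi * 25), 0.05)
  expect_error(binaryPerimeter(makeDisc(5), "nope"))
})

test_that("Euler characteristic matches hand cases and the flood-fill oracle", {
  sq3 <- matrix(FALSE, 5, 5); sq3[2:4, 2:4] <- TRUE
  expect_identical(eulerCharacteristic(sq3), 1L)
  ring <- sq3; ring[3, 3] <- FALSE
  expect_identical(eulerCharacteristic(ring), 0L)
  two <- matrix(FALSE, 9, 9); two[2:3, 2:3] <- TRUE; two[6:8, 6:8] <- TRUE
  expect_identical(eulerCharacteristic(two), 2L)

  set.seed(11)
  for (rep in 1:100) {
    b <- matrix(runif(256) < runif(1, 0.2, 0.8), 16, 16)
    expect_identical(eulerCharacteristic(b, 8), eulerOracle(b, 8))
    expect_identical(eulerCharacteristic(b, 4), eulerOracle(b, 4))
  }
})

test_that("P^2/A follows its conventions and is scale invariant on squares", {
  expect_equal(p2OverA(0, 25), 0)
  expect_equal(p2OverA(10, 0), 0)     # empty-level convention
  expect_error(p2OverA(-1, 5), "non-negative")
  for (n in c(5, 12, 30)) {
    sq <- makeSquare(n)
    expect_equal(p2OverA(binaryPerimeter(sq, "boundary_edges"),
                         binaryArea(sq)), 16)
  }
})

test_that("threshold sweep uses strict retention on an interior grid", {
  mask <- matrix(FALSE, 8, 8); mask[2:5, 3:6] <- TRUE
  sw <- thresholdSweep(twoLevelImage(mask), nLevels = 80)
  expect_length(sw, 80)
  for (b in sw) expect_identical(pixels(b), mask)

  # constant image: all-empty binaries
  swc <- thresholdSweep(IntensityImage(matrix(0.3, 6, 6)), nLevels = 80)
  expect_true(all(vapply(swc, binaryArea, integer(1)) == 0L))

  # three-level image: area steps once near the middle value, and the
  # number of levels retaining the larger foreground equals the count of
  # grid points below 0.5
  px <- matrix(0, 10, 10); px[1:5, ] <- 0.5; px[1:2, ] <- 1
  img <- IntensityImage(px)
  sw3 <- thresholdSweep(img, nLevels = 80)
  areas <- vapply(sw3, binaryArea, integer(1))
  expect_setequal(unique(areas), c(50L, 20L))
  grid <- vapply(sw3, function(b) b@level, numeric(1))
  expect_identical(sum(areas == 50L), sum(grid < 0.5))
  expect_true(all(grid > 0 & grid < 1))
})

test_that("sweep respects the ROI and counts perimeter along its edge", {
  px <- matrix(0, 8, 8)
  roi <- matrix(FALSE, 8, 8); roi[3:6, 3:6] <- TRUE
  px[roi] <- 1; px[3, 3] <- 0             # one dark in-ROI pixel
  img <- IntensityImage(px, mask = roi)
  b <- thresholdSweep(img, nLevels = 10)[[5]]
  expect_identical(pixels(b), roi & px > 0)
  expect_identical(binaryArea(b), 15L)
  # the ROI boundary contributes perimeter (removing a corner pixel of
  # the 4x4 block leaves the digital boundary length at 16)
  expect_equal(binaryPerimeter(b, "boundary_edges"), 16)
})

test_that("minkowskiCurve integrates constant curves exactly", {
  mask <- matrix(FALSE, 12, 12); mask[3:6, 3:8] <- TRUE
  cv <- minkowskiCurve(twoLevelImage(mask), nLevels = 80)
  P0 <- binaryPerimeter(mask, "crofton4")
  A0 <- binaryArea(mask)
  expect_equal(perimeterCurve(cv), rep(P0, 80))
  expect_equal(areaCurve(cv), rep(A0, 80))
  expect_equal(eulerCurve(cv), rep(1, 80))
  s <- curveSummaries(cv)
  expect_equal(s[["sumP"]], 80 * P0)
  expect_equal(s[["sumA"]], 80 * A0)
  expect_equal(s[["sumEuler"]], 80)
  expect_equal(s[["sumP2A"]], 80 * P0^2 / A0)

  cv0 <- minkowskiCurve(IntensityImage(matrix(0.2, 8, 8)), nLevels = 80)
  expect_true(all(curveSummaries(cv0) == 0))
})

test_that("integrateFunctional sums plainly, with a trapezoid option", {
  expect_equal(integrateFunctional(rep(1, 80)), 80)
  expect_equal(integrateFunctional(numeric(80)), 0)
  lv <- seq(0, 1, length.out = 5)
  expect_equal(integrateFunctional(rep(2, 5), "trapezoid", lv), 2)
  expect_error(integrateFunctional(rep(2, 5), "trapezoid"), "levels")
  expect_error(integrateFunctional(c(1, NA)), "finite")
})

test_that("area curves are monotone non-increasing on random images", {
  set.seed(23)
  for (rep in 1:5) {
    img <- smoothImage(IntensityImage(matrix(runif(48 * 48), 48, 48)), 1.5)
    expect_true(all(diff(areaCurve(minkowskiCurve(img, 40))) <= 1e-9))
  }
})

test_that("Minkowski measures are additive over well-separated components", {
  set.seed(31)
  a <- matrix(FALSE, 40, 40); a[5:12, 5:14] <- TRUE
  b <- matrix(FALSE, 40, 40); b[20:30, 22:28] <- TRUE; b[24, 25] <- FALSE
  both <- a | b
  for (m in c("crofton4", "boundary_edges"))
    expect_equal(binaryPerimeter(both, m),
                 binaryPerimeter(a, m) + binaryPerimeter(b, m))
  expect_identical(binaryArea(both), binaryArea(a) + binaryArea(b))
  expect_identical(eulerCharacteristic(both),
                   eulerCharacteristic(a) + eulerCharacteristic(b))
})

test_that("integer upscaling scales A by k^2, edge perimeter by k, chi unchanged", {
  set.seed(41)
  b <- matrix(runif(100) < 0.4, 10, 10)
  for (k in c(2, 3)) {
    bk <- b[rep(seq_len(10), each = k), rep(seq_len(10), each = k)]
    expect_equal(binaryArea(bk), k^2 * binaryArea(b))
    expect_equal(binaryPerimeter(bk, "boundary_edges"),
                 k * binaryPerimeter(b, "boundary_edges"))
    expect_identical(eulerCharacteristic(bk), eulerCharacteristic(b))
  }
})

test_that("a thin stroke beats an equal-area disc on P^2/A (both estimators)", {
  disc <- makeDisc(12)                     # area ~452
  stroke <- matrix(FALSE, 60, 160)
  stroke[29:31, 3:153] <- TRUE             # 3 x 151 = 453 px
  for (m in c("crofton4", "boundary_edges")) {
    r_disc <- p2OverA(binaryPerimeter(disc, m), binaryArea(disc))
    r_strk <- p2OverA(binaryPerimeter(stroke, m), binaryArea(stroke))
    expect_gt(r_strk, r_disc)
  }
})
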