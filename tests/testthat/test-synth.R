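test_that("generators are pure functions of their spec and seed", {
  sp <- markingSpec("scribble", count = 3, targetTotalArea = 900, seed = 5)
  expect_identical(pixels(generateScribble(sp, c(80, 80))),
                   pixels(generateScribble(sp, c(80, 80))))
  sp2 <- sp; sp2@seed <- 6
  expect_false(identical(pixels(generateScribble(sp, c(80, 80))),
                         pixels(generateScribble(sp2, c(80, 80)))))
  bp <- markingSpec("blotch", count = 4, radius = 6, seed = 5)
  expect_identical(pixels(generateBlotch(bp, c(80, 80))),
                   pixels(generateBlotch(bp, c(80, 80))))
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generateScribble(sp, c(80, 80))); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("scribble area tracks length x width", {
  # one stroke, width 3, target 1200 px => length 400
  sp <- markingSpec("scribble", count = 1, strokeWidth = 3,
                    targetTotalArea = 1200, seed = 2)
  m <- generateScribble(sp, c(200, 200))
  expect_lt(abs(binaryArea(m) - 1200) / 1200, 0.15)
  expect_error(generateScribble(
    markingSpec("scribble", count = 1, strokeWidth = 3,
                targetTotalArea = 3, seed = 1), c(50, 50)),
    "impossible")
})

test_that("blotches are compact discs with the requested topology", {
  one <- generateBlotch(markingSpec("blotch", count = 1, radius = 10,
                                    seed = 4), c(60, 60))
  expect_lt(abs(binaryArea(one) - pi * 100) / (pi * 100), 0.03)
  for (k in c(3, 7)) {
    mk <- generateBlotch(markingSpec("blotch", count = k, radius = 5,
                                     seed = k), c(120, 120))
    expect_identical(eulerCharacteristic(mk), as.integer(k))
  }
  expect_error(generateBlotch(
    markingSpec("blotch", count = 30, radius = 12, seed = 1), c(60, 60)),
    "cannot place")
})

test_that("matchArea solves for blotch radius within tolerance", {
  sc <- generateScribble(markingSpec("scribble", count = 5,
                                     targetTotalArea = 1200, seed = 8),
                         c(120, 120))
  bl <- matchArea(sc, markingSpec("blotch", count = 10, seed = 8),
                  c(120, 120))
  Tsc <- binaryArea(sc)
  expect_lt(abs(binaryArea(bl) - Tsc) / Tsc, 0.05)

  # single blotch: radius close to the analytic sqrt(T/pi)
  one <- matchArea(sc, markingSpec("blotch", count = 1, seed = 8),
                   c(120, 120))
  expect_lt(abs(attr(one, "radius") - sqrt(Tsc / pi)), 1)

  # zero scribble area -> zero blotches
  empty <- BinaryImage(matrix(FALSE, 120, 120))
  none <- matchArea(empty, markingSpec("blotch", count = 10, seed = 1),
                    c(120, 120))
  expect_identical(binaryArea(none), 0L)
})

test_that("composeEgg builds the promised intensity field", {
  # flat background, no markings, no noise: degenerate constant egg
  flat <- composeEgg(c(40, 30), backgroundAmp = 0, noiseSd = 0, seed = 1)
  expect_true(imgMeta(flat)$degenerate)
  expect_true(all(curveSummaries(minkowskiCurve(flat)) == 0))

  # markings at intensity 1, no noise: mid-level sweep recovers the mask
  mk <- generateBlotch(markingSpec("blotch", count = 3, radius = 5,
                                   seed = 2), c(60, 45))
  egg <- composeEgg(c(60, 45), list(list(mask = mk, intensity = 1)),
                    backgroundAmp = 0, noiseSd = 0, seed = 1)
  sw <- thresholdSweep(egg, 80)
  mid <- pixels(sw[[40]])
  expect_identical(mid, pixels(mk) & roiMask(egg))

  # seeded runs are identical
  e1 <- composeEgg(c(40, 30), seed = 9)
  e2 <- composeEgg(c(40, 30), seed = 9)
  expect_identical(pixels(e1), pixels(e2))
  expect_error(composeEgg(c(40, 30), list(list(mask = matrix(TRUE, 5, 5),
                                               intensity = 1))),
               "dimensions")
})

test_that("painting composites markings; water and zero-count are identities", {
  egg <- smoothImage(composeEgg(c(96, 72), list(list(
    mask = generateBlotch(markingSpec("blotch", count = 10,
                                      targetTotalArea = 1400, seed = 3),
                          c(96, 72)),
    intensity = 0.85)), seed = 3), 1)
  w <- paintMarkings(egg, "water")
  expect_identical(pixels(w), pixels(egg))
  expect_identical(imgMeta(w)$treatment, "water")
  z <- paintMarkings(egg, "scribbles", count = 0)
  expect_identical(pixels(z), pixels(egg))

  p <- paintMarkings(egg, "scribbles", seed = 4, targetTotalArea = 1400)
  expect_gt(curveSummaries(minkowskiCurve(p))[["sumP2A"]],
            curveSummaries(minkowskiCurve(egg))[["sumP2A"]])
})

test_that("scribbled eggs dominate equal-area blotched eggs on Sigma(P^2/A)", {
  # small-scale version of the separation property (the acceptance suite
  # runs the full 50-pair comparison)
  wins <- 0L
  for (s in 1:10) {
    sc <- generateScribble(markingSpec("scribble", count = 5,
                                       targetTotalArea = 1400, seed = s),
                           c(96, 72))
    bl <- matchArea(sc, markingSpec("blotch", count = 10, seed = s),
                    c(96, 72))
    eS <- smoothImage(composeEgg(c(96, 72), list(list(mask = sc,
                                                      intensity = 0.85)),
                                 seed = s + 100), 1)
    eB <- smoothImage(composeEgg(c(96, 72), list(list(mask = bl,
                                                      intensity = 0.85)),
                                 seed = s + 100), 1)
    wins <- wins + (curveSummaries(minkowskiCurve(eS))[["sumP2A"]] >
                    curveSummaries(minkowskiCurve(eB))[["sumP2A"]])
  }
  expect_gte(wins, 9L)
})
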