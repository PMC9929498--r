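test_that("counts are reconstructed by round-half-up of freq x n", {
  counts <- reconstructCounts(
    c(scribbles = 0.65, blotches = 0.57, water = 0.62),
    c(scribbles = 17, blotches = 14, water = 13))
  expect_identical(unname(counts), c(11L, 8L, 8L))
  expect_identical(sum(counts), 27L)       # 27 rejections of 44 trials
  expect_identical(unname(reconstructCounts(0.5, 5)), 3L)  # half rounds up
  expect_error(reconstructCounts(1.2, 10), "freqs")
  expect_error(reconstructCounts(0.5, 0), "positive")
})

test_that("trial records expand counts faithfully", {
  rec <- buildTrialRecords(c(blotches = 8, scribbles = 11, water = 8),
                           c(blotches = 14, scribbles = 17, water = 13))
  expect_identical(nrow(rec), 44L)
  expect_identical(as.vector(table(rec$treatment)), c(14L, 17L, 13L))
  expect_identical(sum(rec$rejected), 27L)
  expect_error(buildTrialRecords(c(a = 5), c(a = 3)), "exceed")
})

test_that("the reconstructed-trial logit reproduces the reported Wald table", {
  ns <- c(blotches = 14, scribbles = 17, water = 13)
  counts <- reconstructCounts(c(blotches = 0.57, scribbles = 0.65,
                                water = 0.62), ns)
  res <- fitLogistic(buildTrialRecords(counts, ns), reference = "blotches")
  tab <- coefTable(res)
  expect_identical(res@nobs, 44L)
  expect_identical(res@residualDf, 41L)
  sc <- tab[tab$term == "treatment-scribbles", ]
  wa <- tab[tab$term == "treatment-water", ]
  # frozen closed-form values: log(11/6) - log(8/6) and friends
  expect_equal(sc$estimate, 0.3184537, tolerance = 1e-6)
  expect_equal(sc$se, 0.7411089, tolerance = 1e-6)
  expect_equal(wa$estimate, 0.1823216, tolerance = 1e-6)
  expect_equal(wa$se, 0.7852813, tolerance = 1e-6)
  # and their 2-dp presentation
  expect_equal(round(c(sc$estimate, sc$se, sc$z), 2), c(0.32, 0.74, 0.43))
  expect_equal(round(c(wa$estimate, wa$se, wa$z), 2), c(0.18, 0.79, 0.23))
})

test_that("glm Wald statistics match the saturated closed form", {
  set.seed(12)
  for (rep in 1:25) {
    ns <- setNames(sample(8:25, 3), c("a", "b", "c"))
    counts <- setNames(vapply(ns, function(n) sample(seq_len(n - 1), 1),
                              integer(1)), names(ns))
    rec <- buildTrialRecords(counts, ns)
    res <- fitLogistic(rec, reference = "a")
    oracle <- saturatedOracle(as.list(counts), as.list(ns), "a")
    tab <- coefTable(res)
    for (tr in rownames(oracle)) {
      row <- tab[tab$term == paste0("treatment-", tr), ]
      expect_equal(row$estimate, oracle[tr, "estimate"], tolerance = 1e-6)
      expect_equal(row$se, oracle[tr, "se"], tolerance = 1e-6)
    }
    # saturated design: fitted cell probabilities = observed proportions
    fitted <- tapply(res@fit$fitted.values, rec$treatment, mean)
    expect_equal(as.vector(fitted[names(ns)]), as.vector(counts / ns),
                 tolerance = 1e-8)
  }
})

test_that("separation is flagged rather than silently diverging", {
  rec <- buildTrialRecords(c(a = 10, b = 3), c(a = 10, b = 8))
  w <- capture_warnings(res <- fitLogistic(rec, reference = "a"))
  expect_true(any(grepl("separation", w)))
  expect_true(res@separation)
  expect_error(fitLogistic(rec, reference = "zz"), "not present")
})

test_that("paired t-test follows the textbook formula", {
  # identical vectors: zero differences by convention
  same <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_true(same$zeroVariance)
  expect_error(pairedTTest(c(1, 2, 3), c(2, 3, 4)), "zero-variance")

  set.seed(13)
  before <- rnorm(16); after <- before + rnorm(16, 0.3)
  res <- pairedTTest(before, after)
  expect_identical(res$df, 15)             # n - 1
  d <- after - before
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(16)),
               tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(res$statistic), 15),
               tolerance = 1e-12)
  expect_error(pairedTTest(1:3, 1:4), "lengths")
})
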