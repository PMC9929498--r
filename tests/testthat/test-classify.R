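## random Gaussian class data for the classifier checks
randomClassData <- function(K, p, nk, sdMu = 2) {
  mu <- matrix(rnorm(K * p, sd = sdMu), K)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(nk[k] * p), nk[k]), 2, mu[k, ], "+")))
  colnames(X) <- paste0("t", seq_len(p))
  list(X = X, y = factor(rep(letters[seq_len(K)], nk)))
}

test_that("pcaReduce picks the smallest sufficient component count", {
  # rank-1 data: one component explains everything
  set.seed(2)
  v <- rnorm(5)
  X1 <- outer(rnorm(30), v) + matrix(rnorm(150, sd = 1e-8), 30)
  r1 <- pcaReduce(X1, 0.99)
  expect_identical(r1$k, 1L)
  expect_gt(r1$explained[1], 0.99)

  X <- matrix(rnorm(250), 50, 5)
  expect_identical(pcaReduce(X, 1.0)$k, 5L)
  expect_error(pcaReduce(X, 0), "varFraction")
  expect_error(pcaReduce(X[1, , drop = FALSE], 0.9), "2 rows")

  # explained fractions equal eigenvalue ratios of the correlation matrix
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(pcaReduce(X, 0.9)$explained, ev / sum(ev))
})

test_that("linear-basis FDA reproduces LDA assignments exactly", {
  skip_if_not_installed("MASS")
  set.seed(42)
  for (r in 1:100) {
    K <- sample(2:3, 1)
    d <- randomClassData(K, sample(2:5, 1), sample(10:30, K, replace = TRUE))
    m <- fitFDA(d$X, d$y)
    mine <- as.character(predictClasses(m, d$X))
    theirs <- as.character(predict(MASS::lda(d$X, d$y), d$X)$class)
    expect_identical(mine, theirs)
  }
})

test_that("perfect separation gives perfect resubstitution", {
  set.seed(3)
  d <- randomClassData(2, 3, c(15, 15), sdMu = 20)
  m <- fitFDA(d$X, d$y)
  expect_true(all(m@trainingSummary$rates == 100))
})

test_that("randomly permuted labels stay near chance", {
  set.seed(9)
  X <- matrix(rnorm(500 * 3), 500, 3)
  colnames(X) <- paste0("t", 1:3)
  y <- factor(rep(c("a", "b"), each = 250))
  acc <- assignmentRates(X, sample(y))$overall
  expect_lt(acc, 58)   # chance 50% plus a margin
})

test_that("coefficient importances are a 100% decomposition", {
  set.seed(4)
  d <- randomClassData(2, 4, c(20, 20))
  imp <- coefficientImportance(fitFDA(d$X, d$y))
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  expect_true(all(imp >= 0))

  # only trait 1 differs between classes: it dominates the importance
  X <- cbind(t1 = c(rnorm(40, 0), rnorm(40, 6)),
             t2 = rnorm(80), t3 = rnorm(80))
  imp2 <- coefficientImportance(fitFDA(X, rep(c("a", "b"), each = 40)))
  expect_gt(imp2[["t1"]], 90)
})

test_that("assignments are invariant to affine trait rescaling", {
  set.seed(5)
  d <- randomClassData(2, 3, c(25, 25), sdMu = 1)
  base <- assignmentRates(d$X, d$y)
  X2 <- d$X
  X2[, 2] <- 1000 * X2[, 2] - 7
  again <- assignmentRates(X2, d$y)
  expect_identical(base$assigned, again$assigned)
  expect_equal(base$rates, again$rates)
})

test_that("leave-one-out rates sit near the Monte-Carlo Bayes rate", {
  # two unit-variance Gaussians, means 0 and 2: Bayes rule is x < 1
  set.seed(6)
  n <- 200
  X <- matrix(c(rnorm(n / 2, 0), rnorm(n / 2, 2)), ncol = 1,
              dimnames = list(NULL, "t1"))
  y <- factor(rep(c("a", "b"), each = n / 2))
  loo <- assignmentRates(X, y, scheme = "leave_one_out")
  expect_identical(loo$scheme, "leave_one_out")
  mc <- c(rnorm(20000, 0), rnorm(20000, 2))      # Monte-Carlo oracle
  bayes <- 100 * mean(c(mc[1:20000] < 1, mc[20001:40000] >= 1))
  ci <- 100 * 2.5 * sqrt(0.84 * 0.16 / n)        # generous binomial CI
  expect_lt(abs(loo$overall - bayes), ci)
})

test_that("degenerate fits fail loudly with guidance", {
  X <- cbind(t1 = rep(1, 20), t2 = rnorm(20))
  y <- rep(c("a", "b"), each = 10)
  expect_error(fitFDA(X, y), "constant trait")
  X2 <- cbind(t1 = rnorm(20), t2 = rnorm(20))
  expect_error(fitFDA(X2, rep("a", 20)), "2 classes")
  expect_error(fitFDA(X2[1:3, ], factor(c("a", "a", "b"))), "at least 2 rows")
  # collinear columns: singular scoring regression, ridge rescues it
  X3 <- cbind(t1 = rnorm(20), t2 = rnorm(20))
  X3 <- cbind(X3, t3 = X3[, 1] + X3[, 2])
  expect_error(fitFDA(X3, y), "ridge")
  expect_s4_class(fitFDA(X3, y, ridge = 1e-6), "FDAModel")
})

test_that("polynomial basis separates a radially defined class", {
  set.seed(8)
  n <- 120
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("t1", "t2")))
  y <- factor(ifelse(rowSums(X^2) < 1.2, "in", "out"))
  lin <- assignmentRates(X, y, basis = "linear")$overall
  quad <- assignmentRates(X, y, basis = "polynomial2")$overall
  expect_gt(quad, 90)
  expect_gt(quad, lin)
})

test_that("prediction rejects mismatched trait columns", {
  set.seed(10)
  d <- randomClassData(2, 3, c(12, 12))
  m <- fitFDA(d$X, d$y)
  bad <- d$X
  colnames(bad) <- c("x1", "x2", "x3")
  expect_error(predictClasses(m, bad), "trait columns")
})
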