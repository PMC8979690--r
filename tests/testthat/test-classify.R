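test_that("metric modes reproduce the worked confusion example", {
  asP <- metricsFromConfusion(c(tp = 8, tn = 5, fp = 5, fn = 2), mode = "as_printed")
  expect_equal(asP@precision, 80)
  expect_equal(asP@recall, 50)
  expect_equal(asP@f1, 2 * 80 * 50 / 130, tolerance = 1e-10)
  std <- metricsFromConfusion(c(tp = 8, tn = 5, fp = 5, fn = 2), mode = "standard")
  expect_equal(std@precision, 800 / 13, tolerance = 1e-10)
  expect_equal(std@recall, 80)

  for (mode in c("standard", "as_printed")) {
    perfect <- metricsFromConfusion(c(tp = 1, tn = 1, fp = 0, fn = 0), mode = mode)
    expect_equal(perfect@accuracy, 100)
    expect_equal(perfect@f1, 100)
  }
})

test_that("the two metric modes agree whenever fn equals fp", {
  set.seed(3)
  for (rep_ in 1:6) {
    tp <- sample(1:30, 1); tn <- sample(1:30, 1); off <- sample(0:10, 1)
    a <- metricsFromConfusion(c(tp = tp, tn = tn, fp = off, fn = off), "standard")
    b <- metricsFromConfusion(c(tp = tp, tn = tn, fp = off, fn = off), "as_printed")
    expect_equal(a@accuracy, b@accuracy)
    expect_equal(a@precision, b@precision, tolerance = 1e-10)
  }
})

test_that("zero denominators are reported as 0 with a flag", {
  m <- metricsFromConfusion(c(tp = 0, tn = 5, fp = 0, fn = 5), mode = "standard")
  expect_equal(m@precision, 0)
  expect_true("precision" %in% m@flags)
})

test_that("all three classifiers separate clean blobs perfectly", {
  set.seed(10)
  n <- 40
  X <- rbind(matrix(rnorm(n, 5, 0.3), n / 2, 2),
             matrix(rnorm(n, -5, 0.3), n / 2, 2))
  y <- rep(c("healthy", "rc"), each = n / 2)
  Xt <- rbind(matrix(rnorm(20, 5, 0.3), 10, 2),
              matrix(rnorm(20, -5, 0.3), 10, 2))
  yt <- rep(c("healthy", "rc"), each = 10)
  for (fam in c("lr", "svm", "rf")) {
    res <- trainEval(X, y, Xt, yt, spec = classifierSpec(fam),
                     posClass = "healthy", seed = 1)
    expect_equal(res$metrics@accuracy, 100, info = fam)
    expect_equal(res$confusion@tp + res$confusion@tn +
                 res$confusion@fp + res$confusion@fn, 20L)
  }
})

test_that("shuffled labels give chance-level accuracy on 500 test points", {
  set.seed(20)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  y <- sample(rep(c("healthy", "rc"), n / 2))
  Xt <- matrix(rnorm(500 * 4), 500, 4)
  yt <- sample(rep(c("healthy", "rc"), 250))
  res <- trainEval(X, y, Xt, yt, spec = classifierSpec("lr"),
                   posClass = "healthy", seed = 2)
  expect_gte(res$metrics@accuracy, 40)
  expect_lte(res$metrics@accuracy, 60)
})

test_that("accuracy is invariant under class swap with matrix transposition", {
  cm1 <- metricsFromConfusion(c(tp = 12, tn = 7, fp = 3, fn = 5))
  cm2 <- metricsFromConfusion(c(tp = 7, tn = 12, fp = 5, fn = 3))
  expect_equal(cm1@accuracy, cm2@accuracy)
})

test_that("non-finite features are rejected naming the column", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("ok", "bad")))
  X[3, 2] <- NaN
  expect_error(trainEval(X, rep(c("a", "b"), 5), X, rep(c("a", "b"), 5)),
               "bad")
})

test_that("sweep grids have the canonical setting counts and reproduce exactly", {
  expect_length(hogSweepGrid(), 8)
  expect_length(glcmSweepGrid(), 15)
  expect_length(gaborSweepGrid(), 8)
  expect_length(mrfSweepGrid(), 4)

  tiles <- lapply(1:10, function(i)
    testTile(if (i %% 2) "healthy" else "rc", i))
  names(tiles) <- sprintf("t%02d", 1:10)
  labels <- rep(c("healthy", "rc"), 5)
  grid <- list(g16 = function(t) gaborFeatures(t, sizes = 16),
               g24 = function(t) gaborFeatures(t, sizes = 24))
  # glmnet warns about the deliberately tiny per-class n; that is expected here
  s1 <- suppressWarnings(
    runSweep(tiles, labels, grid, classifiers = "lr", nRepeats = 1, seed = 4))
  s2 <- suppressWarnings(
    runSweep(tiles, labels, grid, classifiers = "lr", nRepeats = 1, seed = 4))
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2)
  expect_equal(sum(s1$best), 1)
})

test_that("a failing sweep cell is recorded while the sweep continues", {
  tiles <- lapply(1:6, function(i) testTile(if (i %% 2) "healthy" else "rc", i))
  names(tiles) <- sprintf("t%02d", 1:6)
  labels <- rep(c("healthy", "rc"), 3)
  grid <- list(boom = function(t) stop("nope"),
               ok = function(t) gaborFeatures(t, sizes = 16))
  res <- runSweep(tiles, labels, grid, classifiers = "svm", nRepeats = 1, seed = 1)
  expect_true(res$failed[res$setting == "boom"])
  expect_false(res$failed[res$setting == "ok"])
})
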