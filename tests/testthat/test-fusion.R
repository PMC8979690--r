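test_that("class-mean differences match the hand-worked example with tie-breaks", {
  X <- rbind(c(1, 0), c(3, 0), c(0, 0), c(0, 4))
  rownames(X) <- letters[1:4]
  rk <- diffRank(X, c(TRUE, TRUE, FALSE, FALSE), k = 2)
  expect_equal(abs(diffValues(rk)), c(2, 2))
  expect_equal(rk@order, c(1L, 2L))            # tie broken toward dim 1
  expect_equal(selectedIndices(rk), c(1L, 2L))
  expect_equal(unname(rk@classCounts), c(2L, 2L))
  expect_identical(rk@trainIds, letters[1:4])
})

test_that("rankings are shift-invariant and match a brute-force oracle", {
  set.seed(14)
  for (rep_ in 1:5) {
    n <- sample(6:20, 1); d <- sample(5:50, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- c(rep(TRUE, ceiling(n / 2)), rep(FALSE, floor(n / 2)))
    rk <- diffRank(X, y, k = min(3, d))
    brute <- apply(X, 2, function(col) mean(col[y]) - mean(col[!y]))
    expect_equal(diffValues(rk), unname(brute), tolerance = 1e-12)
    rkShift <- diffRank(X + 5.5, y, k = min(3, d))
    expect_equal(diffValues(rkShift), diffValues(rk), tolerance = 1e-10)
    expect_equal(rkShift@order, rk@order)
  }
})

test_that("k = D keeps every dimension and bad inputs error", {
  X <- matrix(rnorm(40), 8, 5)
  y <- rep(c(TRUE, FALSE), 4)
  rk <- diffRank(X, y, k = 5)
  expect_setequal(selectedIndices(rk), 1:5)
  expect_error(diffRank(X, rep(TRUE, 8), k = 2), "both classes")
  expect_error(diffRank(X, y, k = 6), "exceeds")
})

test_that("a frozen selection is applied verbatim to held-out rows", {
  set.seed(2)
  Xtr <- matrix(rnorm(200), 10, 20); rownames(Xtr) <- paste0("tr", 1:10)
  Xte <- matrix(rnorm(100), 5, 20); rownames(Xte) <- paste0("te", 1:5)
  y <- rep(c(TRUE, FALSE), 5)
  rk <- diffRank(Xtr, y, k = 4)
  sel <- selectFeatures(Xte, rk)
  expect_equal(dim(sel), c(5L, 4L))
  expect_equal(unname(sel), unname(Xte[, selectedIndices(rk)]))
  # the ranking remembers exactly which rows fitted it (leakage guard)
  expect_identical(rk@trainIds, paste0("tr", 1:10))
  expect_error(selectFeatures(Xte[, 1:7], rk), "does not match")
})

test_that("fusion concatenates deep-first with provenance and id checks", {
  deep <- matrix(rnorm(300), 3, 100, dimnames = list(c("a", "b", "c"), NULL))
  tex <- matrix(rnorm(177), 3, 59, dimnames = list(c("a", "b", "c"), NULL))
  fused <- fuseFeatures(deep, tex)
  expect_equal(ncol(fused), 159)
  expect_equal(attr(fused, "provenance"),
               c(rep("deep", 100), rep("texture", 59)))
  empty <- matrix(numeric(0), 3, 0, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(fuseFeatures(deep, empty)[, ]), unname(deep))
  rownames(tex) <- c("a", "b", "z")
  expect_error(fuseFeatures(deep, tex), "z")
})

test_that("z-scoring fits its parameters on the stated training rows only", {
  set.seed(5)
  deep <- matrix(rnorm(40, mean = 10), 4, 10,
                 dimnames = list(c("a", "b", "c", "d"), NULL))
  tex <- matrix(numeric(0), 4, 0, dimnames = list(rownames(deep), NULL))
  fused <- fuseFeatures(deep, tex, zscore = TRUE, trainIds = c("a", "b"))
  expect_equal(unname(colMeans(fused[c("a", "b"), ])), rep(0, 10), tolerance = 1e-10)
  expect_false(all(abs(colMeans(fused)) < 1e-10))
})

test_that("feature matrices and rankings round-trip through their text formats", {
  set.seed(6)
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("x", "y", "z"), paste0("f", 1:4)))
  attr(m, "extractor") <- "demo_v1"
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCsv(m, path)
  back <- readFeatureCsv(path)
  expect_equal(unname(back[, ]), unname(m[, ]), tolerance = 1e-12)
  expect_equal(colnames(back), colnames(m))
  expect_equal(rownames(back), rownames(m))
  expect_equal(attr(back, "extractor"), "demo_v1")

  X <- matrix(rnorm(60), 6, 10, dimnames = list(paste0("i", 1:6), NULL))
  rk <- diffRank(X, rep(c(TRUE, FALSE), 3), k = 3)
  jpath <- withr::local_tempfile(fileext = ".json")
  saveRanking(rk, jpath)
  rk2 <- readRanking(jpath)
  expect_equal(diffValues(rk2), diffValues(rk), tolerance = 1e-12)
  expect_equal(rk2@order, rk@order)
  expect_equal(rk2@kSelected, rk@kSelected)
  expect_identical(rk2@trainIds, rk@trainIds)
})
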