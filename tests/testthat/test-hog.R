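test_that("block descriptors have cell x bin dimensionality and the length formula holds", {
  img <- rampImage(16, 16)
  v <- hogFeatures(img, cellSize = 4, blockSize = 2, nBins = 9)
  # 4x4 cells -> 3x3 sliding blocks of 2x2 cells, 36 values per block
  expect_length(v, 9 * 36)
  expect_length(unique(sub("_[0-9]+$", "", names(v))), 9)

  big <- rampImage(96, 96)
  for (cs in c(6L, 8L)) {
    for (bs in 2:5) {
      nC <- 96 %/% cs
      nB <- nC - bs + 1
      expect_length(hogFeatures(big, cellSize = cs, blockSize = bs),
                    nB^2 * bs^2 * 9)
    }
  }
})

test_that("a constant image yields an all-zero descriptor, not NaN", {
  v <- hogFeatures(matrix(120, 24, 24), cellSize = 4, blockSize = 2)
  expect_true(all(is.finite(v)))
  expect_true(all(v == 0))
})

test_that("a vertical step edge votes into the horizontal-gradient orientation bins", {
  img <- cbind(matrix(10, 16, 8), matrix(200, 16, 8))
  v <- hogFeatures(img, cellSize = 4, blockSize = 2, nBins = 9)
  byBin <- tapply(v, (seq_along(v) - 1) %% 9 + 1, sum)
  # orientation 0 degrees falls between the first and last unsigned bins
  edgeMass <- byBin[1] + byBin[9]
  midMass <- byBin[5]   # 90-degree bin
  expect_gt(edgeMass, midMass)
  expect_equal(which.max(byBin) %in% c(1L, 9L), TRUE)
})

test_that("extraction is pure and undersized images are rejected with the minimum", {
  img <- rampImage(20, 20)
  expect_identical(hogFeatures(img, 4, 2), hogFeatures(img, 4, 2))
  expect_error(hogFeatures(matrix(1, 10, 10), cellSize = 6, blockSize = 4), "24 x 24")
})
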