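test_that("relu clamps negatives and is idempotent", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(2.5), 2.5)
  set.seed(1)
  z <- array(rnorm(60), c(5, 4, 3))
  expect_equal(relu(relu(z)), relu(z))
})

test_that("local response normalization matches a per-pixel loop oracle", {
  set.seed(11)
  a <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  got <- localResponseNorm(a)
  oracle <- a
  for (x in 1:4) for (y in 1:4) for (i in 1:8) {
    lo <- max(1, i - 2); hi <- min(8, i + 2)
    oracle[x, y, i] <- a[x, y, i] / (2 + 1e-4 * sum(a[x, y, lo:hi]^2))^0.75
  }
  expect_lt(max(abs(got - oracle)), 1e-6)

  expect_equal(localResponseNorm(array(0, c(3, 3, 5))), array(0, c(3, 3, 5)))
  # single active channel, n = 1, k = 1: closed form a / (1 + alpha a^2)^beta
  a1 <- array(0, c(2, 2, 4)); a1[1, 1, 2] <- 1.3
  got1 <- localResponseNorm(a1, k = 1, n = 1)
  expect_equal(got1[1, 1, 2], 1.3 / (1 + 1e-4 * 1.3^2)^0.75, tolerance = 1e-12)
  # scaling the input rescales through the closed form
  c_ <- 2.7
  gotC <- localResponseNorm(a1 * c_, k = 1, n = 1)
  expect_equal(gotC[1, 1, 2],
               c_ * 1.3 / (1 + 1e-4 * (c_ * 1.3)^2)^0.75, tolerance = 1e-12)
})

test_that("the fc7 tap emits 4096 values and the run is deterministic", {
  tile <- testTile("healthy", 1)
  D <- deepFeatures(list(a = tile, b = tile), weights = testWeights())
  expect_equal(ncol(D), 4096L)
  expect_true(all(is.finite(D)))
  expect_identical(D[1, ], D[2, ])             # duplicate images, equal rows
  D2 <- deepFeatures(list(a = tile), seed = 0L)
  expect_identical(unname(D2[1, ]), unname(D[1, ]))  # seeded init is reproducible
})

test_that("weight lists are validated against the architecture", {
  w <- testWeights()
  wBad <- w
  wBad$conv3$W <- wBad$conv3$W[, 1:10]
  expect_error(deepFeatures(list(testTile("rc", 2)), weights = wBad), "conv3")
})

test_that("the finetuning hook memorizes a tiny set and honors its contracts", {
  tiles <- list(a = testTile("healthy", 1), b = testTile("rc", 2))
  w0 <- testWeights()
  expect_identical(finetuneBackbone(tiles, c("healthy", "rc"),
                                    weights = w0, epochs = 0), w0)
  w1 <- finetuneBackbone(tiles, c("healthy", "rc"), weights = w0,
                         epochs = 6, patience = Inf, valFrac = 0)
  loss <- attr(w1, "loss")
  expect_length(loss, 6)
  expect_lt(loss[6], loss[1])                  # memorization loss decreases
  expect_error(finetuneBackbone(tiles, c("healthy", "rc"), weights = w0,
                                epochs = 2, patience = 1, valFrac = 0),
               "validation")
})

test_that("early stopping halts once patience is exhausted", {
  tiles <- list(a = testTile("healthy", 1), b = testTile("rc", 2),
                c = testTile("healthy", 3), d = testTile("rc", 4))
  w <- finetuneBackbone(tiles, c("healthy", "rc", "healthy", "rc"),
                        weights = testWeights(), epochs = 40, patience = 2,
                        valFrac = 0.25, lr = 0)
  # zero learning rate: validation accuracy never improves after epoch 1
  expect_lte(attr(w, "stoppedAt"), 3)
})
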