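test_that("optical density conversion follows Beer-Lambert and round-trips", {
  white <- array(255, c(1, 2, 3))
  white[1, 2, ] <- 94
  od <- rgbToOd(white)
  expect_equal(od$V[, 1], rep(0, 3))
  expect_false(od$mask[1])            # white pixel is background
  expect_equal(od$V[, 2], rep(log(255 / 94), 3), tolerance = 1e-12)
  expect_true(od$mask[2])

  tile <- testTile("healthy", 1)
  od2 <- rgbToOd(tile)
  back <- odToRgb(od2)
  idx <- rep(od2$mask, 3)
  expect_lt(max(abs(back - tile)[idx]), 1 + 1e-9)

  expect_error(rgbToOd(array(0, c(0, 3, 3))), "pixel")
  expect_error(rgbToOd(array(255, c(4, 4, 3))), "no tissue")
})

test_that("sparse factorization recovers an exact non-negative model", {
  set.seed(42)
  W0 <- matrix(runif(6, 0.05, 1), 3, 2)
  W0 <- sweep(W0, 2, sqrt(colSums(W0^2)), "/")
  H0 <- matrix(rexp(1000) * rbinom(1000, 1, 0.6), 2, 500)
  V0 <- W0 %*% H0
  od <- list(V = V0, mask = rep(TRUE, 500), dim = c(1L, 500L), i0 = 255)
  m <- suppressWarnings(fitStainModel(od, lambda = 0, maxIter = 2000))
  relErr <- sqrt(sum((V0 - stainBasis(m) %*% densityMaps(m))^2) / sum(V0^2))
  expect_lt(relErr, 1e-3)
})

test_that("rank-1 fit on a single pure stain recovers its direction", {
  dirn <- c(0.2, 0.9, 0.4); dirn <- dirn / sqrt(sum(dirn^2))
  set.seed(3)
  V <- dirn %o% rexp(300)
  od <- list(V = V, mask = rep(TRUE, 300), dim = c(1L, 300L), i0 = 255)
  m <- suppressWarnings(fitStainModel(od, r = 1, lambda = 0.01))
  expect_lt(angleDeg(stainBasis(m)[, 1], dirn), 0.5)
})

test_that("fitted models satisfy the factorization constraints and a monotone objective", {
  for (s in 1:2) {
    m <- fitStainModel(rgbToOd(testTile("rc", s)))
    W <- stainBasis(m); H <- densityMaps(m)
    expect_gte(min(W), -1e-12)
    expect_gte(min(H), -1e-12)
    expect_true(all(abs(sqrt(colSums(W^2)) - 1) < 1e-9))
    obj <- m@objective
    expect_true(all(diff(obj) <= 1e-8 * pmax(abs(obj[-length(obj)]), 1)))
    # hematoxylin-like stain (larger blue weight) is deterministically first
    expect_gte(W[3, 1], W[3, 2])
  }
  expect_error(
    fitStainModel(list(V = matrix(1, 3, 50), mask = rep(TRUE, 50),
                       dim = c(1L, 50L), i0 = 255)),
    "rank-deficient")
})

test_that("robust pseudomaximum uses interpolated percentiles and is order-free", {
  expect_equal(robustPseudomax(matrix(1:100, 1))[1], 99.01)
  expect_equal(robustPseudomax(matrix(7, 1, 40))[1], 7)
  set.seed(5)
  row <- runif(200)
  expect_equal(robustPseudomax(matrix(row, 1)),
               robustPseudomax(matrix(sample(row), 1)))
})

test_that("self-normalization reproduces the input within two intensity levels", {
  tile <- testTile("healthy", 2)
  od <- rgbToOd(tile)
  m <- fitStainModel(od)
  out <- normalizeToTarget(tile, m, srcModel = m)
  idx <- rep(od$mask, 3)
  expect_lt(max(abs(out - tile)[idx]), 2)
  # background pixels pass through bit-exactly
  if (any(!od$mask)) expect_equal(out[!idx], tile[!idx])
})

test_that("normalization is invariant to a global density rescale of the source", {
  tile <- testTile("rc", 3)
  m <- fitStainModel(rgbToOd(tile))
  m2 <- m; m2@H <- m@H * 4.2
  o1 <- normalizeToTarget(tile, m, srcModel = m)
  o2 <- normalizeToTarget(tile, m, srcModel = m2)
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("zero source pseudomax triggers the division guard", {
  tile <- testTile("healthy", 4)
  m <- fitStainModel(rgbToOd(tile))
  m0 <- m; m0@H[2, ] <- 0
  expect_warning(normalizeToTarget(tile, m, srcModel = m0), "scale factor")
})

test_that("normalizing two color variants to one target brings them together", {
  cfgA <- tissueSimConfig()
  basisB <- cbind(c(0.45, 0.80, 0.40), c(0.15, 0.93, 0.20))
  cfgB <- tissueSimConfig(stainBasis = basisB)
  a <- generateTile(cfgA, "healthy", seed = 11)
  b <- generateTile(cfgB, "healthy", seed = 11)   # same structure, other colors
  before <- mean(abs(a - b))
  tgt <- fitStainModel(rgbToOd(testTile("healthy", 1)))
  na <- normalizeToTarget(a, tgt)
  nb <- normalizeToTarget(b, tgt)
  after <- mean(abs(na - nb))
  expect_lt(after, before)
})

test_that("stain models serialize to JSON and drive normalization after reload", {
  tile <- testTile("healthy", 1)
  m <- fitStainModel(rgbToOd(tile))
  path <- withr::local_tempfile(fileext = ".json")
  saveStainModel(m, path)
  t2 <- readStainModel(path)
  expect_equal(t2$W, unname(stainBasis(m)), tolerance = 1e-12)
  expect_equal(t2$rm, unname(robustPseudomax(m)), tolerance = 1e-12)
  o1 <- normalizeToTarget(testTile("rc", 2), m)
  o2 <- normalizeToTarget(testTile("rc", 2), t2)
  expect_equal(o1, o2, tolerance = 1e-9)
})
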