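test_that("co-occurrence counting matches the worked one-pair example", {
  m <- glcmMatrix(matrix(c(1, 2), 1, 2), d = 1, theta = 0, nLevels = 8,
                  quantize = FALSE)
  expect_equal(dim(m$counts), c(8L, 8L))
  expect_equal(m$counts[1, 2], 1L)
  expect_equal(sum(m$counts), 1L)
  expect_equal(sum(m$probs), 1)
})

test_that("a constant image occupies a single diagonal cell", {
  g <- matrix(180, 5, 5)
  m <- glcmMatrix(g, nLevels = 8, maxValue = 255)
  lev <- floor(180 / 255 * 8) + 1
  expect_equal(m$counts[lev, lev], sum(m$counts))
})

test_that("reversing the offset transposes the count matrix", {
  set.seed(1)
  g <- matrix(sample(1:4, 48, TRUE), 6, 8)
  fwd <- glcmMatrix(g, theta = 0, nLevels = 4, quantize = FALSE)$counts
  # theta + 180 degrees = pairs read in reverse order
  rev_ <- glcmMatrix(g[, ncol(g):1], theta = 0, nLevels = 4, quantize = FALSE)$counts
  expect_equal(rev_, t(fwd))
})

test_that("counts equal exhaustive pair enumeration on small 4-level images", {
  set.seed(99)
  for (rep_ in 1:12) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    q <- matrix(sample(1:4, h * w, TRUE), h, w)
    for (th in c(0, 45, 90, 135)) {
      d <- sample(1:2, 1)
      got <- try(glcmMatrix(q, d = d, theta = th, nLevels = 4,
                            quantize = FALSE)$counts, silent = TRUE)
      want <- bruteGlcm(q, d, th, 4)
      if (inherits(got, "try-error")) {
        expect_equal(sum(want), 0)     # offset fell outside the image
      } else {
        expect_equal(got, want)
      }
    }
  }
})

test_that("properties match a double-loop oracle to 1e-12", {
  set.seed(21)
  for (rep_ in 1:8) {
    P <- matrix(rexp(9), 3, 3); P <- P / sum(P)
    got <- glcmProperties(P)
    want <- bruteGlcmProps(P)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
  }
})

test_that("degenerate and closed-form matrices give the expected properties", {
  single <- matrix(0, 8, 8); single[3, 3] <- 1
  p <- suppressWarnings(glcmProperties(single))
  expect_equal(p$contrast, 0)
  expect_equal(p$energy, 1)
  expect_equal(p$homogeneity, 1)
  expect_true(p$degenerate)
  expect_warning(glcmProperties(single), "zero-variance")

  pd <- glcmProperties(diag(8) / 8)
  expect_equal(pd$contrast, 0)
  expect_equal(pd$homogeneity, 1)
  expect_equal(pd$energy, 1 / 8)
  expect_equal(pd$correlation, 1)
})

test_that("feature combinations keep the canonical property order", {
  g <- rampImage(24, 24)
  all4 <- glcmFeatures(g)
  expect_length(all4, 4)
  expect_equal(names(all4),
               paste0("glcm_", c("contrast", "correlation", "energy", "homogeneity")))
  # order contract: energy + contrast still emits contrast first
  two <- glcmFeatures(g, combo = c("energy", "contrast"))
  expect_equal(names(two), c("glcm_contrast", "glcm_energy"))
  con <- suppressWarnings(glcmFeatures(matrix(9, 16, 16), combo = "contrast"))
  expect_equal(as.numeric(con), 0)
  expect_error(glcmFeatures(g, combo = character(0)), "combo")
  expect_error(glcmMatrix(g, nLevels = 1), "nLevels")
})
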