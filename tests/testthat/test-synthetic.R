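test_that("zero stain density renders a pure-white tile", {
  cfg <- tissueSimConfig(nucleiDensity = c(healthy = 0L, rc = 0L),
                         textureScale = 0, stromaBase = 0, noiseSd = 0)
  tile <- generateTile(cfg, "healthy", seed = 1)
  expect_equal(max(abs(tile - 255)), 0)
})

test_that("stain separation closes the loop on generated tiles within 5 degrees", {
  cfg <- tissueSimConfig()
  for (s in 1:2) {
    tile <- generateTile(cfg, if (s == 1) "healthy" else "rc", seed = s)
    m <- fitStainModel(rgbToOd(tile))
    expect_lt(angleDeg(stainBasis(m)[, 1], cfg$stainBasis[, 1]), 5)
    expect_lt(angleDeg(stainBasis(m)[, 2], cfg$stainBasis[, 2]), 5)
  }
})

test_that("tiles are deterministic in the seed and classes differ", {
  cfg <- tissueSimConfig()
  expect_identical(generateTile(cfg, "rc", seed = 9),
                   generateTile(cfg, "rc", seed = 9))
  expect_false(identical(generateTile(cfg, "rc", seed = 9),
                         generateTile(cfg, "healthy", seed = 9)))
})

test_that("the two classes are distinguishable through MRF texture statistics", {
  cfg <- tissueSimConfig()
  b1 <- sapply(1:50, function(i)
    mrfFeatures(generateTile(cfg, "healthy", seed = i))[["mrf_b2"]])
  b2 <- sapply(1:50, function(i)
    mrfFeatures(generateTile(cfg, "rc", seed = 1000 + i))[["mrf_b2"]])
  expect_lt(stats::wilcox.test(b1, b2)$p.value, 0.01)
})

test_that("augmentation is lossless, label-free and multiplies counts as declared", {
  tile <- testTile("healthy", 5)
  a <- augmentTile(tile, c("rot90", "rot180", "rot270", "hflip"))
  expect_length(a, 4)
  expect_identical(augmentTile(a$rot180, "rot180")$rot180, tile)
  expect_identical(augmentTile(a$rot90, "rot270")$rot270, tile)
  expect_identical(augmentTile(a$hflip, "hflip")$hflip, tile)
  # 210 sources with 2 extra variants each -> 630 images, as in a x3 scheme
  man <- data.frame(id = sprintf("i%03d", 1:630), label = "rc",
                    source = rep(sprintf("s%03d", 1:210), each = 3))
  expect_equal(nrow(man), 210 * 3)
})

test_that("augmented variants inherit their source's label in the manifest", {
  ds <- generateDataset(nPerClass = 3, augmentOps = c("rot90", "hflip"), seed = 2)
  expect_equal(nrow(ds$manifest), 2 * 3 * 3)
  byS <- tapply(ds$manifest$label, ds$manifest$source,
                function(x) length(unique(x)))
  expect_true(all(byS == 1))
  bySplit <- tapply(ds$manifest$split, ds$manifest$source,
                    function(x) length(unique(x)))
  expect_true(all(bySplit == 1))     # no source straddles the split
})

test_that("stratified splitting reproduces the canonical 7:3 counts", {
  man <- rbind(
    data.frame(id = sprintf("r%03d", 1:630), label = "rc",
               source = rep(sprintf("rs%03d", 1:210), each = 3)),
    data.frame(id = sprintf("h%03d", 1:560), label = "healthy",
               source = rep(sprintf("hs%03d", 1:140), each = 4)))
  sp <- splitDataset(man, trainFrac = 0.7, seed = 1)
  expect_equal(sum(sp$split == "train" & sp$label == "rc"), 441)
  expect_equal(sum(sp$split == "val" & sp$label == "rc"), 189)
  expect_equal(sum(sp$split == "train" & sp$label == "healthy"), 392)
  expect_equal(sum(sp$split == "val" & sp$label == "healthy"), 168)
  sp2 <- splitDataset(man, trainFrac = 0.7, seed = 1)
  expect_identical(sp, sp2)
  tiny <- data.frame(id = "a", label = "x", source = "a")
  expect_error(splitDataset(tiny), "fewer than 2")
})

test_that("datasets round-trip through PNG tiles and a CSV manifest", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(nPerClass = 2, seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readDataset(dir)
  expect_equal(back$manifest$id, ds$manifest$id)
  # 8-bit quantization: tiles agree to half an intensity level
  expect_lt(max(abs(back$tiles[[1]] - ds$tiles[[1]])), 0.5 + 1e-9)
})
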