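# Shared fixtures: everything is generated in code, nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# backbone weights are expensive to draw; share one seeded set across tests
testWeights <- function() {
  if (is.null(.fixtures$weights)) .fixtures$weights <- alexNetWeights(seed = 0L)
  .fixtures$weights
}

testTile <- function(label = "healthy", seed = 1L, cfg = tissueSimConfig()) {
  key <- sprintf("tile_%s_%d", label, seed)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- generateTile(cfg, label, seed = seed)
  .fixtures[[key]]
}

# a small flat-gray ramp image with deterministic texture, for descriptor tests
rampImage <- function(h = 32L, w = 32L, seed = 7L) {
  set.seed(seed)
  matrix(stats::runif(h * w, 0, 255), h, w)
}

angleDeg <- function(a, b) {
  acos(pmin(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 1)) * 180 / pi
}

# brute-force GLCM: count every ordered pixel pair at the offset by explicit
# looping — the enumeration oracle for the vectorized implementation
bruteGlcm <- function(q, d, theta, nLevels) {
  off <- switch(as.character(theta),
    "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0L, nLevels, nLevels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q))
        counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1L
    }
  }
  counts
}

# double-loop evaluation of the four GLCM properties
bruteGlcmProps <- function(P) {
  n <- nrow(P); lev <- seq_len(n) - 1
  contrast <- 0; energy <- 0; homog <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    contrast <- contrast + P[i, j] * (lev[i] - lev[j])^2
    energy <- energy + P[i, j]^2
    homog <- homog + P[i, j] / (1 + (lev[i] - lev[j])^2)
  }
  mui <- 0; muj <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mui <- mui + lev[i] * P[i, j]; muj <- muj + lev[j] * P[i, j]
  }
  si <- 0; sj <- 0; corr <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- si + (lev[i] - mui)^2 * P[i, j]
    sj <- sj + (lev[j] - muj)^2 * P[i, j]
  }
  for (i in seq_len(n)) for (j in seq_len(n))
    corr <- corr + (lev[i] - mui) * (lev[j] - muj) * P[i, j]
  list(contrast = contrast, correlation = corr / sqrt(si * sj),
       energy = energy, homogeneity = homog)
}
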