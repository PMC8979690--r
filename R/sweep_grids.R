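#' Standard parameter grids for descriptor sweeps
#'
#' Named lists of tile -> feature-vector functions covering the
#' conventional tuning grids of each descriptor, ready for [runSweep()]:
#' \itemize{
#'   \item HOG: cell sizes \{6, 8\} crossed with block sizes \{2, 3, 4, 5\}
#'     — 8 settings;
#'   \item GLCM: all 15 non-empty combinations of the four properties;
#'   \item LBP: cell sizes 4 to 32 in steps of 4;
#'   \item Gabor: single-size banks, filter sizes 4 to 32 in steps of 4;
#'   \item MRF: iteration counts 20 to 50 in steps of 10.
#' }
#'
#' @param cellSizes,blockSizes HOG grid axes.
#' @return named list of extractor functions.
#' @export
hogSweepGrid <- function(cellSizes = c(6L, 8L), blockSizes = 2:5) {
  grid <- list()
  for (cs in cellSizes) for (bs in blockSizes) {
    grid[[sprintf("cell%d_block%d", cs, bs)]] <-
      local({ cs0 <- cs; bs0 <- bs
        function(tile) hogFeatures(tile, cellSize = cs0, blockSize = bs0) })
  }
  grid
}

#' @rdname hogSweepGrid
#' @param d,nLevels GLCM parameters shared across the 15 combinations.
#' @export
glcmSweepGrid <- function(d = 1L, nLevels = 8L) {
  combos <- glcmCombos()
  grid <- list()
  for (cb in combos) {
    grid[[paste(cb, collapse = "+")]] <-
      local({ cb0 <- cb
        function(tile) glcmFeatures(tile, combo = cb0, d = d, nLevels = nLevels) })
  }
  grid
}

#' @rdname hogSweepGrid
#' @param lbpCellSizes LBP cell-size axis.
#' @export
lbpSweepGrid <- function(lbpCellSizes = seq(4L, 32L, by = 4L)) {
  grid <- list()
  for (cs in lbpCellSizes) {
    grid[[sprintf("cell%d", cs)]] <-
      local({ cs0 <- cs; function(tile) lbpFeatures(tile, cellSize = cs0) })
  }
  grid
}

#' @rdname hogSweepGrid
#' @param filterSizes Gabor filter-size axis.
#' @export
gaborSweepGrid <- function(filterSizes = seq(4L, 32L, by = 4L)) {
  grid <- list()
  for (fs in filterSizes) {
    grid[[sprintf("size%d", fs)]] <-
      local({ fs0 <- fs; function(tile) gaborFeatures(tile, sizes = fs0) })
  }
  grid
}

#' @rdname hogSweepGrid
#' @param iterations MRF iteration axis.
#' @export
mrfSweepGrid <- function(iterations = seq(20L, 50L, by = 10L)) {
  grid <- list()
  for (it in iterations) {
    grid[[sprintf("iter%d", it)]] <-
      local({ it0 <- it; function(tile) mrfFeatures(tile, nIterations = it0) })
  }
  grid
}
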