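#' Histogram of oriented gradients
#'
#' Dalal-Triggs style HOG over a grayscale image: square-root gamma
#' compression, central-difference gradients
#' \eqn{G_x = H(x+1,y) - H(x-1,y)}, \eqn{G_y = H(x,y+1) - H(x,y-1)},
#' magnitude \eqn{G = \sqrt{G_x^2 + G_y^2}} and unsigned orientation
#' \eqn{\alpha = \arctan(G_y / G_x)} folded into [0, 180). Magnitude-weighted
#' votes are linearly interpolated between the two nearest orientation bins,
#' accumulated per cell, grouped into blocks of \code{blockSize} x
#' \code{blockSize} cells sliding by one cell, and each block vector is
#' L2-Hys normalized (L2, clip at 0.2, renormalize; zero blocks stay zero).
#'
#' Output length is
#' \code{nBlocksY * nBlocksX * blockSize^2 * nBins} with
#' \code{nBlocks = nCells - blockSize + 1} per axis.
#'
#' @param img grayscale matrix (any intensity scale) or RGB tile (converted
#'   via [toGrayscale()]).
#' @param cellSize pixels per cell side (default 6).
#' @param blockSize cells per block side (default 4).
#' @param nBins unsigned orientation bins (default 9).
#' @return named numeric feature vector with attribute \code{extractor}.
#' @examples
#' v <- hogFeatures(matrix(runif(256), 16, 16), cellSize = 4, blockSize = 2)
#' length(v)  # 9 blocks x 4 cells x 9 bins = 324
#' @export
hogFeatures <- function(img, cellSize = 6L, blockSize = 4L, nBins = 9L) {
  g <- toGrayscale(img)
  if (cellSize < 2L) stop("cellSize must be at least 2")
  if (blockSize < 1L) stop("blockSize must be at least 1")
  if (nBins < 2L) stop("nBins must be at least 2")
  h <- nrow(g); w <- ncol(g)
  minSide <- cellSize * blockSize
  if (h < minSide || w < minSide)
    stop("image must be at least ", minSide, " x ", minSide,
         " pixels for this cell/block configuration")
  # gamma normalization: square-root compression on [0,1] scale
  top <- max(g)
  g <- sqrt(g / max(top, 1e-12))
  # central differences, edges replicated (gradient 0 contribution there is fine)
  gx <- matrix(0, h, w)  # along columns (x = column index)
  gy <- matrix(0, h, w)  # along rows
  gx[, 2:(w - 1)] <- g[, 3:w] - g[, 1:(w - 2)]
  gy[2:(h - 1), ] <- g[3:h, ] - g[1:(h - 2), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi        # (-180, 180]
  ang <- ang %% 180                      # unsigned, [0, 180)
  nCy <- h %/% cellSize; nCx <- w %/% cellSize
  hUse <- nCy * cellSize; wUse <- nCx * cellSize
  binW <- 180 / nBins
  # linear interpolation between the two nearest bin centers (center k: (k+0.5)*binW)
  pos <- ang / binW - 0.5
  b0 <- floor(pos)
  f <- pos - b0
  b0 <- b0 %% nBins
  b1 <- (b0 + 1) %% nBins
  cellHist <- array(0, c(nCy, nCx, nBins))
  idxY <- (seq_len(hUse) - 1L) %/% cellSize + 1L
  idxX <- (seq_len(wUse) - 1L) %/% cellSize + 1L
  cy <- matrix(idxY, hUse, wUse)[, seq_len(wUse)]
  cx <- matrix(idxX, hUse, wUse, byrow = TRUE)
  sub <- cbind(c(cy), c(cx))
  m <- mag[seq_len(hUse), seq_len(wUse)]
  for (side in 1:2) {
    b <- if (side == 1) b0 else b1
    wgt <- if (side == 1) (1 - f) else f
    key <- c(b[seq_len(hUse), seq_len(wUse)]) * (nCy * nCx) +
      (sub[, 2] - 1L) * nCy + sub[, 1]
    acc <- rowsum(c(m * wgt[seq_len(hUse), seq_len(wUse)]), key)
    cellHist[as.integer(rownames(acc))] <- cellHist[as.integer(rownames(acc))] + acc[, 1]
  }
  nBy <- nCy - blockSize + 1L
  nBx <- nCx - blockSize + 1L
  out <- numeric(nBy * nBx * blockSize^2 * nBins)
  nm <- character(length(out))
  p <- 0L
  for (by in seq_len(nBy)) {
    for (bx in seq_len(nBx)) {
      blk <- c(cellHist[by:(by + blockSize - 1L), bx:(bx + blockSize - 1L), , drop = FALSE])
      nrm <- sqrt(sum(blk^2))
      if (nrm > 1e-12) {
        blk <- pmin(blk / nrm, 0.2)           # L2-Hys
        nrm2 <- sqrt(sum(blk^2))
        if (nrm2 > 1e-12) blk <- blk / nrm2
      } else blk[] <- 0
      span <- p + seq_along(blk)
      out[span] <- blk
      nm[span] <- sprintf("hog_b%02d_%02d_%03d", by, bx, seq_along(blk))
      p <- p + length(blk)
    }
  }
  names(out) <- nm
  structure(out, extractor = sprintf("hog_c%d_b%d_o%d", cellSize, blockSize, nBins))
}
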