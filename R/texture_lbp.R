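# Uniform-pattern code table for P neighbors: uniform patterns (at most two
# circular 0/1 transitions) get bins 1..P(P-1)+2 ordered by increasing decimal
# code; every non-uniform pattern shares the final bin P(P-1)+3.
lbpUniformMap <- function(P = 8L) {
  codes <- 0:(2^P - 1)
  bits <- sapply(codes, function(c) as.integer(intToBits(c))[seq_len(P)])
  trans <- colSums(abs(bits - bits[c(2:P, 1L), , drop = FALSE]))
  nBins <- P * (P - 1L) + 3L
  map <- integer(length(codes))
  uni <- which(trans <= 2L)
  map[uni] <- seq_along(uni)               # ascending decimal order
  map[trans > 2L] <- nBins                 # shared non-uniform bin
  attr(map, "nBins") <- nBins
  map
}

#' Uniform local binary pattern features
#'
#' Each pixel is coded by comparing its neighbors to it: a neighbor at least
#' as bright contributes a 1, else 0, and the P bits form a binary code. For
#' the default 8 neighbors at radius 1 the neighborhood is the 3 x 3 window
#' and bits are read left to right, top to bottom (top-left is the most
#' significant bit). For other P or R, neighbors are sampled on a circle of
#' radius R with bilinear interpolation, clockwise from the top-left
#' diagonal. Codes are mapped to the uniform-pattern table (patterns with at
#' most two circular transitions get their own bin, all others share one;
#' 59 bins for P = 8), histogrammed per non-overlapping cell, and the cell
#' histograms are concatenated. Histograms are L1-normalized per cell by
#' default; unnormalized histograms sum to the number of coded pixels in the
#' cell.
#'
#' LBP codes compare intensities to the center only, so adding a constant to
#' every pixel leaves all codes unchanged.
#'
#' @param img grayscale matrix, or RGB tile (converted).
#' @param nNeighbors P, number of sampling points (default 8).
#' @param radius R, sampling radius in pixels (default 1).
#' @param cellSize cell side in pixels (default 16); a cell larger than the
#'   coded image falls back to a single cell with a warning.
#' @param normalize L1-normalize each cell histogram (default TRUE).
#' @return named numeric vector (cells x bins) with attribute
#'   \code{extractor}.
#' @export
lbpFeatures <- function(img, nNeighbors = 8L, radius = 1L, cellSize = 16L,
                        normalize = TRUE) {
  g <- toGrayscale(img)
  P <- as.integer(nNeighbors); R <- as.integer(radius)
  if (P < 4L) stop("nNeighbors must be at least 4")
  if (R < 1L) stop("radius must be at least 1")
  h <- nrow(g); w <- ncol(g)
  if (h <= 2L * R || w <= 2L * R) stop("image too small for radius ", R)
  if (P == 8L && R == 1L) {
    # classic square window, reading order TL,T,TR,L,R,BL,B,BR; TL is the MSB
    offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  } else {
    ang <- -pi * 3 / 4 + 2 * pi * (seq_len(P) - 1L) / P  # clockwise from top-left
    offs <- lapply(ang, function(a) c(R * sin(a), R * cos(a)))
  }
  ri <- (R + 1L):(h - R); ci <- (R + 1L):(w - R)
  center <- g[ri, ci, drop = FALSE]
  code <- matrix(0, nrow(center), ncol(center))
  for (p in seq_len(P)) {
    dy <- offs[[p]][1]; dx <- offs[[p]][2]
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0; fx <- dx - x0
    pick <- function(oy, ox) g[ri + oy, ci + ox, drop = FALSE]
    nb <- if (abs(fy) < 1e-9 && abs(fx) < 1e-9) {
      pick(as.integer(round(dy)), as.integer(round(dx)))
    } else {
      (1 - fy) * (1 - fx) * pick(y0, x0) + (1 - fy) * fx * pick(y0, x0 + 1L) +
        fy * (1 - fx) * pick(y0 + 1L, x0) + fy * fx * pick(y0 + 1L, x0 + 1L)
    }
    code <- code + (nb >= center) * 2^(P - p)   # first-read bit is the MSB
  }
  map <- lbpUniformMap(P)
  nBins <- attr(map, "nBins")
  binned <- matrix(map[code + 1L], nrow(code), ncol(code))
  ch <- nrow(binned); cw <- ncol(binned)
  if (cellSize > ch || cellSize > cw) {
    warning("cell larger than the coded image; using a single cell")
    cellSize <- max(ch, cw)
  }
  nCy <- max(ch %/% cellSize, 1L); nCx <- max(cw %/% cellSize, 1L)
  out <- numeric(0); nm <- character(0)
  for (cy in seq_len(nCy)) {
    for (cx in seq_len(nCx)) {
      ys <- ((cy - 1L) * cellSize + 1L):(if (cy == nCy) ch else cy * cellSize)
      xs <- ((cx - 1L) * cellSize + 1L):(if (cx == nCx) cw else cx * cellSize)
      hist <- tabulate(binned[ys, xs], nbins = nBins)
      if (normalize && sum(hist) > 0) hist <- hist / sum(hist)
      out <- c(out, hist)
      nm <- c(nm, sprintf("lbp_c%02d_%02d_b%02d", cy, cx, seq_len(nBins)))
    }
  }
  names(out) <- nm
  structure(out, extractor = sprintf("lbp_p%d_r%d_c%d", P, R, cellSize))
}
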