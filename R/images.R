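#' Read and write RGB tiles
#'
#' Tiles are held in memory as numeric arrays of shape height x width x 3
#' with channel intensities in [0, 255]. \code{readTile} accepts PNG or TIFF
#' (any bit depth EBImage can decode, rescaled to [0, 255]); grayscale files
#' are expanded to three identical channels. \code{writeTile} writes 8-bit
#' output; the format follows the file extension.
#'
#' @param path file path.
#' @return \code{readTile}: numeric H x W x 3 array in [0, 255].
#' @export
readTile <- function(path) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), c(dim(px), 3L))
  } else if (dim(px)[3] > 3L) {
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  }
  # EBImage stores x (width) first; transpose to row = y convention
  out <- aperm(px, c(2L, 1L, 3L)) * 255
  pmin(pmax(out, 0), 255)
}

#' @rdname readTile
#' @param img numeric H x W x 3 array in [0, 255].
#' @export
writeTile <- function(img, path) {
  img <- checkTile(img)
  px <- aperm(img / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path, bits.per.sample = 8L)
  invisible(path)
}

# validate an RGB tile array; returns it (numeric, clipped shape checks only)
checkTile <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("tile must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stop("tile must have at least one pixel")
  if (any(!is.finite(img))) stop("tile contains non-finite values")
  if (min(img) < 0 || max(img) > 255) stop("tile intensities must lie in [0, 255]")
  img
}

#' Convert an RGB tile to grayscale
#'
#' ITU-R BT.601 luma weights (0.299, 0.587, 0.114), the fixed convention for
#' all texture descriptors in this package.
#'
#' @param img numeric H x W x 3 array in [0, 255], or an H x W matrix
#'   (returned unchanged).
#' @return numeric H x W matrix on the same intensity scale as the input.
#' @export
toGrayscale <- function(img) {
  if (is.matrix(img)) return(img)
  checkTile(img)
  img[, , 1] * 0.299 + img[, , 2] * 0.587 + img[, , 3] * 0.114
}

# Reflect-pad a matrix ("symmetric" style, edge pixel repeated: abcd -> ba|abcd|dc).
padReflect <- function(m, top, bottom, left, right) {
  h <- nrow(m); w <- ncol(m)
  if (max(top, bottom) >= h || max(left, right) >= w)
    stop("padding exceeds image size")
  rows <- c(rev(seq_len(top)), seq_len(h), h + 1L - seq_len(bottom))
  cols <- c(rev(seq_len(left)), seq_len(w), w + 1L - seq_len(right))
  m[rows, cols, drop = FALSE]
}

# 2-D correlation of image with kernel, reflect boundary, output size = input.
# FFT-based; kernel may be even-sized (anchored at floor((k-1)/2)+1).
convolve2dReflect <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  cy <- (kh - 1L) %/% 2L; cx <- (kw - 1L) %/% 2L
  p <- padReflect(img, cy, kh - 1L - cy, cx, kw - 1L - cx)
  H <- nrow(p) + kh - 1L; W <- ncol(p) + kw - 1L
  A <- matrix(0, H, W); A[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  kf <- kern[kh:1, kw:1, drop = FALSE]  # correlation = conv with flipped kernel
  B <- matrix(0, H, W); B[seq_len(kh), seq_len(kw)] <- kf
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (H * W)
  full[(kh - 1L) + seq_len(nrow(img)), (kw - 1L) + seq_len(ncol(img)), drop = FALSE]
}

#' Geometric augmentation of a tile
#'
#' Lossless 90-degree rotations and horizontal flip, the augmentation family
#' used to expand small histology datasets. Operations act on the pixel grid
#' only; labels are untouched by construction.
#'
#' @param img numeric H x W x 3 array (or H x W matrix).
#' @param ops character subset of \code{c("rot90","rot180","rot270","hflip")}.
#' @param keepOriginal prepend the untransformed image to the output list.
#' @return named list of transformed images, one per op (plus
#'   \code{"original"} when \code{keepOriginal} is TRUE).
#' @export
augmentTile <- function(img, ops = c("rot90", "rot180", "rot270", "hflip"),
                        keepOriginal = FALSE) {
  ops <- match.arg(ops, c("rot90", "rot180", "rot270", "hflip"), several.ok = TRUE)
  if (length(ops) == 0L) stop("ops must be non-empty")
  rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  one <- function(op) {
    f <- switch(op,
      rot90  = rot90cw,
      rot180 = function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
      rot270 = function(m) rot90cw(rot90cw(rot90cw(m))),
      hflip  = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    )
    if (is.matrix(img)) return(f(img))
    out <- lapply(1:3, function(ch) f(img[, , ch]))
    array(unlist(out), c(dim(out[[1]]), 3L))
  }
  res <- lapply(ops, one)
  names(res) <- ops
  if (keepOriginal) res <- c(list(original = img), res)
  res
}
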