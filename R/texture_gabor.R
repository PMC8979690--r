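#' Gabor kernel (real part)
#'
#' A Gaussian-modulated cosine probe,
#' \deqn{G(x,y) = \exp\!\big(-(x'^2 + \gamma^2 y'^2)/(2\sigma^2)\big)\,
#'   \cos(2\pi x'/\lambda)}
#' with \eqn{x' = x\cos\theta + y\sin\theta},
#' \eqn{y' = -x\sin\theta + y\cos\theta}, sampled on a \code{size} x
#' \code{size} grid centered on the kernel.
#'
#' @param size kernel side length in pixels.
#' @param theta orientation in degrees.
#' @param lambda wavelength of the cosine carrier (default \code{size / 4}).
#' @param sigma Gaussian envelope SD (default \code{0.56 * lambda}).
#' @param gamma spatial aspect ratio of the envelope (default 0.5).
#' @return size x size numeric matrix.
#' @export
gaborKernel <- function(size, theta = 0, lambda = size / 4,
                        sigma = 0.56 * lambda, gamma = 0.5) {
  if (lambda <= 0) stop("lambda must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  c0 <- (size - 1) / 2
  xs <- seq_len(size) - 1 - c0
  X <- matrix(xs, size, size, byrow = TRUE)   # column index = x
  Y <- matrix(xs, size, size)                 # row index = y
  th <- theta * pi / 180
  xp <- X * cos(th) + Y * sin(th)
  yp <- -X * sin(th) + Y * cos(th)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda)
}

#' Gabor filter-bank texture features
#'
#' Convolves the grayscale image with the real part of a Gabor kernel for
#' every (filter size, orientation) pair in the bank, using
#' reflected-boundary convolution, and emits the mean and variance of each
#' filtered image. Vector length is \code{2 * length(sizes) *
#' length(orientations)}.
#'
#' @param img grayscale matrix, or RGB tile (converted).
#' @param sizes kernel side lengths (default \code{seq(4, 32, by = 4)}, the
#'   standard sweep grid).
#' @param orientations orientations in degrees (default 0, 45, 90, 135).
#' @param lambdaFrac carrier wavelength as a fraction of the kernel size
#'   (default 1/4).
#' @param sigmaFrac envelope SD as a fraction of the wavelength
#'   (default 0.56).
#' @param gamma envelope aspect ratio (default 0.5).
#' @return named numeric vector (\code{gabor_s<size>_t<theta>_{mean,var}})
#'   with attribute \code{extractor}.
#' @export
gaborFeatures <- function(img, sizes = seq(4L, 32L, by = 4L),
                          orientations = c(0, 45, 90, 135),
                          lambdaFrac = 0.25, sigmaFrac = 0.56, gamma = 0.5) {
  g <- toGrayscale(img)
  if (any(sizes >= min(dim(g)))) stop("kernel size must be smaller than the image")
  out <- numeric(0)
  for (s in sizes) {
    lam <- s * lambdaFrac
    for (th in orientations) {
      k <- gaborKernel(s, theta = th, lambda = lam,
                       sigma = sigmaFrac * lam, gamma = gamma)
      resp <- convolve2dReflect(g, k)
      v <- c(mean(resp), stats::var(c(resp)))
      names(v) <- sprintf("gabor_s%d_t%d_%s", s, th, c("mean", "var"))
      out <- c(out, v)
    }
  }
  structure(out, extractor = sprintf("gabor_s%s", paste(sizes, collapse = "-")))
}
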