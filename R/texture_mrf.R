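#' Gauss-Markov random field texture features
#'
#' Models the (centered) grayscale image as a conditional autoregression:
#' the expected value of each pixel given the rest of the image depends only
#' on its symmetric neighbor pairs,
#' \deqn{E[x_s \mid rest] = \sum_r \beta_r \,(x_{s+o_r} + x_{s-o_r}),}
#' one interaction coefficient per clique-offset direction \eqn{o_r}
#' (default: horizontal and vertical nearest neighbors). The coefficients
#' are the least-squares solution of the neighbor regression over interior
#' pixels, computed by cyclic coordinate descent run for \code{nIterations}
#' sweeps from zero — deterministic for a given image and configuration.
#' The feature vector is the fitted coefficients followed by the residual
#' noise variance: length \code{length(offsets) + 1}.
#'
#' @param img grayscale matrix, or RGB tile (converted).
#' @param offsets list of integer c(drow, dcol) clique offsets (default
#'   4-connected pairs: \code{list(c(0, 1), c(1, 0))}).
#' @param nIterations coordinate-descent sweeps (default 20; the sweep grid
#'   20, 30, 40, 50 is the conventional tuning range).
#' @return named numeric vector \code{c(mrf_b<k>..., mrf_var)} with
#'   attribute \code{extractor}.
#' @export
mrfFeatures <- function(img, offsets = list(c(0L, 1L), c(1L, 0L)),
                        nIterations = 20L) {
  g <- toGrayscale(img)
  if (nIterations < 1L) stop("nIterations must be at least 1")
  if (length(offsets) < 1L) stop("offsets must be non-empty")
  if (any(vapply(offsets, function(o) all(o == 0L), logical(1))))
    stop("offsets must be non-degenerate (not c(0, 0))")
  p <- length(offsets)
  my <- max(vapply(offsets, function(o) abs(o[1]), integer(1)))
  mx <- max(vapply(offsets, function(o) abs(o[2]), integer(1)))
  h <- nrow(g); w <- ncol(g)
  if (h <= 2L * my || w <= 2L * mx) stop("image too small for the clique offsets")
  x <- g - mean(g)
  if (stats::sd(c(g)) < 1e-12) {
    warning("constant image: zero-variance regression, coefficients set to 0")
    out <- c(rep(0, p), 0)
    names(out) <- c(sprintf("mrf_b%d", seq_len(p)), "mrf_var")
    return(structure(out, extractor = sprintf("mrf_p%d_i%d", p, nIterations)))
  }
  ri <- (my + 1L):(h - my); ci <- (mx + 1L):(w - mx)
  y <- c(x[ri, ci])
  X <- vapply(offsets, function(o) {
    c(x[ri + o[1], ci + o[2]] + x[ri - o[1], ci - o[2]])
  }, numeric(length(y)))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- rep(0, p)
  for (it in seq_len(nIterations)) {      # cyclic coordinate descent on LS
    for (j in seq_len(p)) {
      denom <- XtX[j, j]
      if (denom < 1e-12) next
      beta[j] <- beta[j] + (Xty[j] - sum(XtX[j, ] * beta)) / denom
    }
  }
  resid <- y - X %*% beta
  out <- c(beta, mean(resid^2))
  names(out) <- c(sprintf("mrf_b%d", seq_len(p)), "mrf_var")
  structure(out, extractor = sprintf("mrf_p%d_i%d", p, nIterations))
}

#' Simulate a stationary Gauss-MRF texture field
#'
#' Exact spectral sampling of the first-order conditional autoregression on
#' a torus: the field has conditional mean
#' \eqn{\beta_1 (x_{left} + x_{right}) + \beta_2 (x_{up} + x_{down})} and
#' conditional variance \eqn{\sigma^2}. Requires the stability condition
#' \eqn{2(|\beta_1| + |\beta_2|) < 1}. Sampling multiplies the spectrum of
#' white noise by \eqn{1/\sqrt{1 - \lambda(u, v)}} where
#' \eqn{\lambda(u,v) = 2\beta_1\cos(2\pi v/W) + 2\beta_2\cos(2\pi u/H)}.
#'
#' @param nrow,ncol field dimensions.
#' @param beta length-2 interaction coefficients (horizontal, vertical).
#' @param sigma conditional noise SD (default 1).
#' @param seed integer seed.
#' @return nrow x ncol numeric matrix, zero-mean texture field.
#' @export
simulateGMRF <- function(nrow, ncol, beta = c(0.24, 0.24), sigma = 1,
                         seed = 0L) {
  if (2 * sum(abs(beta)) >= 1) stop("unstable field: need 2*(|b1|+|b2|) < 1")
  set.seed(seed)
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  u <- (seq_len(nrow) - 1) / nrow
  v <- (seq_len(ncol) - 1) / ncol
  lam <- 2 * beta[1] * matrix(cos(2 * pi * v), nrow, ncol, byrow = TRUE) +
         2 * beta[2] * matrix(cos(2 * pi * u), nrow, ncol)
  spec <- sigma / sqrt(1 - lam)
  x <- Re(stats::fft(stats::fft(z) * spec, inverse = TRUE)) / (nrow * ncol)
  x - mean(x)
}
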