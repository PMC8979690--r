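#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized gray levels separated by the offset
#' (distance \code{d}, angle \code{theta}): element (i, j) is the number of
#' pixel pairs whose first pixel has level i and whose neighbor at the
#' offset has level j. Angles follow the usual GLCM convention: 0 degrees is
#' the pixel d columns to the right, 90 degrees d rows up, 45/135 the
#' diagonals. Counting is ordered (non-symmetric) by default; with
#' \code{symmetric = TRUE} each pair is also counted in reverse.
#'
#' Quantization bins the intensity range [0, maxValue] uniformly into
#' \code{nLevels} levels. With \code{quantize = FALSE} the image must
#' already contain integer levels in 1..nLevels.
#'
#' @param img grayscale matrix, or RGB tile (converted).
#' @param d offset distance in pixels (default 1).
#' @param theta offset angle in degrees: 0, 45, 90 or 135 (default 0).
#' @param nLevels number of gray levels (default 8).
#' @param symmetric also count reversed pairs (default FALSE).
#' @param quantize bin intensities into levels (default TRUE).
#' @param maxValue top of the intensity range for quantization (default 255).
#' @return list of class \code{"GlcmMatrix"}: \code{counts} (nLevels x
#'   nLevels integer), \code{probs} (counts / total), \code{d}, \code{theta},
#'   \code{nLevels}, \code{symmetric}.
#' @examples
#' m <- glcmMatrix(matrix(c(1, 2), 1, 2), quantize = FALSE)
#' m$counts[1, 2]  # the pair (1, 2) occurs once
#' @export
glcmMatrix <- function(img, d = 1L, theta = 0, nLevels = 8L,
                       symmetric = FALSE, quantize = TRUE, maxValue = 255) {
  g <- toGrayscale(img)
  if (nLevels < 2L) stop("nLevels must be at least 2")
  if (!theta %in% c(0, 45, 90, 135)) stop("theta must be one of 0, 45, 90, 135")
  if (quantize) {
    q <- pmin(floor(g / maxValue * nLevels) + 1L, nLevels)
  } else {
    q <- g
    if (any(q != round(q)) || min(q) < 1 || max(q) > nLevels)
      stop("with quantize = FALSE the image must hold integer levels in 1..nLevels")
  }
  h <- nrow(q); w <- ncol(q)
  # offset (drow, dcol); image row 1 is the top, so 90 degrees (up) is -d rows
  off <- switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d))
  rows <- seq_len(h); cols <- seq_len(w)
  r1 <- rows[rows + off[1] >= 1L & rows + off[1] <= h]
  c1 <- cols[cols + off[2] >= 1L & cols + off[2] <= w]
  if (length(r1) == 0L || length(c1) == 0L)
    stop("offset (d = ", d, ", theta = ", theta, ") falls outside the image")
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(0L, nLevels, nLevels)
  tab <- tabulate((c(a) - 1L) * nLevels + c(b), nbins = nLevels * nLevels)
  counts <- matrix(tab, nLevels, nLevels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  probs <- if (total > 0) counts / total else counts
  structure(list(counts = counts, probs = probs, d = d, theta = theta,
                 nLevels = nLevels, symmetric = symmetric),
            class = "GlcmMatrix")
}

#' Haralick-style properties of a co-occurrence matrix
#'
#' Four scalar summaries of the normalized GLCM P over levels indexed
#' i, j = 0..N-1:
#' \itemize{
#'   \item contrast \eqn{\sum_{i,j} P(i,j)(i-j)^2}
#'   \item correlation \eqn{\sum_{i,j} (i-\mu_i)(j-\mu_j)P(i,j) / (\sigma_i\sigma_j)}
#'     with marginal means/SDs \eqn{\mu_i,\mu_j,\sigma_i,\sigma_j}
#'   \item energy \eqn{\sum_{i,j} P(i,j)^2}
#'   \item homogeneity \eqn{\sum_{i,j} P(i,j)/(1+(i-j)^2)}
#' }
#' A zero-variance marginal (single occupied level) makes correlation
#' undefined; it is reported as 1 with a \code{degenerate} flag.
#'
#' @param m a \code{"GlcmMatrix"} from [glcmMatrix()], or a normalized
#'   probability matrix.
#' @return named list: contrast, correlation, energy, homogeneity,
#'   degenerate (logical).
#' @export
glcmProperties <- function(m) {
  P <- if (inherits(m, "GlcmMatrix")) m$probs else m
  if (abs(sum(P) - 1) > 1e-8) stop("probabilities must sum to 1")
  n <- nrow(P)
  lev <- seq_len(n) - 1
  D <- outer(lev, lev, "-")
  contrast <- sum(P * D^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + D^2))
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum(lev * pi_); muj <- sum(lev * pj)
  si <- sqrt(sum((lev - mui)^2 * pi_)); sj <- sqrt(sum((lev - muj)^2 * pj))
  degenerate <- (si < 1e-12 || sj < 1e-12)
  correlation <- if (degenerate) {
    warning("zero-variance marginal: correlation reported as 1")
    1
  } else {
    sum(outer(lev - mui, lev - muj) * P) / (si * sj)
  }
  list(contrast = contrast, correlation = correlation, energy = energy,
       homogeneity = homogeneity, degenerate = degenerate)
}

# the 15 property combinations, in canonical sweep order
glcmCombos <- function() {
  props <- c("contrast", "correlation", "energy", "homogeneity")
  combos <- list()
  for (k in 1:4) combos <- c(combos, utils::combn(props, k, simplify = FALSE))
  # order: singletons, pairs, triples, all — matching the canonical listing
  combos
}

#' GLCM feature vector over angles
#'
#' Computes the GLCM at each requested angle, evaluates the selected
#' property combination on each, and averages every property across angles
#' (the usual rotation-pooling). Properties appear in the fixed order
#' contrast, correlation, energy, homogeneity restricted to \code{combo}.
#'
#' @inheritParams glcmMatrix
#' @param combo character subset of
#'   \code{c("contrast","correlation","energy","homogeneity")}, any of the
#'   15 non-empty combinations.
#' @param angles angles to average over (default the four standard ones).
#' @return named numeric feature vector with attribute \code{extractor}.
#' @export
glcmFeatures <- function(img, combo = c("contrast", "correlation", "energy",
                                        "homogeneity"),
                         angles = c(0, 45, 90, 135), d = 1L, nLevels = 8L,
                         symmetric = FALSE, quantize = TRUE, maxValue = 255) {
  props <- c("contrast", "correlation", "energy", "homogeneity")
  if (length(combo) == 0L) stop("combo must be non-empty")
  combo <- match.arg(combo, props, several.ok = TRUE)
  combo <- props[props %in% combo]  # fixed emission order
  g <- toGrayscale(img)
  perAngle <- sapply(angles, function(th) {
    p <- suppressWarnings(glcmProperties(
      glcmMatrix(g, d = d, theta = th, nLevels = nLevels,
                 symmetric = symmetric, quantize = quantize,
                 maxValue = maxValue)))
    unlist(p[combo])
  })
  v <- if (is.matrix(perAngle)) rowMeans(perAngle) else mean(perAngle)
  names(v) <- paste0("glcm_", combo)
  structure(v, extractor = sprintf("glcm_d%d_n%d_%s", d, nLevels,
                                   paste(substr(combo, 1, 3), collapse = "+")))
}
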