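#' Convert an RGB tile to Beer-Lambert optical densities
#'
#' Each channel intensity I is mapped to an optical density
#' \eqn{V = \ln(I_0 / I)} after clipping intensities to \eqn{[1, I_0]} so the
#' log is finite. Stain concentrations mix linearly in OD space, which is
#' what makes the factorization in [fitStainModel()] meaningful. Pixels whose
#' maximum OD over the three channels falls below \code{bgThreshold} are
#' flagged as background (near-white glass): they are excluded from stain
#' fitting but retained so normalization can pass them through unchanged.
#'
#' @param img numeric H x W x 3 array in [0, 255].
#' @param i0 incident light intensity (default 255, the 8-bit convention).
#' @param bgThreshold OD level below which a pixel counts as background
#'   (default 0.15).
#' @return list with \code{V} (3 x N OD matrix, column-major over pixels),
#'   \code{mask} (logical length N, TRUE = tissue), \code{dim} (height,
#'   width), \code{i0}.
#' @examples
#' img <- array(94, c(2, 2, 3))
#' od <- rgbToOd(img)
#' od$V[1, 1]  # log(255/94)
#' @export
rgbToOd <- function(img, i0 = 255, bgThreshold = 0.15) {
  checkTile(img)
  if (i0 <= 0) stop("i0 must be positive")
  h <- dim(img)[1]; w <- dim(img)[2]
  I <- matrix(c(img[, , 1], img[, , 2], img[, , 3]), nrow = 3L, byrow = TRUE)
  I <- pmin(pmax(I, 1), i0)
  V <- log(i0 / I)
  mask <- apply(V, 2L, max) >= bgThreshold
  if (!any(mask)) stop("no tissue pixels: every pixel is below the background OD threshold")
  list(V = V, mask = mask, dim = c(h, w), i0 = i0)
}

#' Invert optical densities back to an RGB tile
#'
#' \eqn{I = I_0 \exp(-V)}, the inverse of [rgbToOd()] (up to the intensity
#' clipping applied there).
#'
#' @param od a list as returned by [rgbToOd()], or a 3 x N OD matrix (then
#'   \code{dim} must be supplied).
#' @param dim integer c(height, width); taken from \code{od} when present.
#' @param i0 incident intensity; taken from \code{od} when present.
#' @return numeric H x W x 3 array in [0, i0].
#' @export
odToRgb <- function(od, dim = NULL, i0 = NULL) {
  if (is.list(od)) {
    if (is.null(dim)) dim <- od$dim
    if (is.null(i0)) i0 <- od$i0
    od <- od$V
  }
  if (is.null(i0)) i0 <- 255
  if (is.null(dim)) stop("dim (height, width) required for a bare OD matrix")
  I <- pmin(pmax(i0 * exp(-od), 0), i0)
  array(c(I[1, ], I[2, ], I[3, ]), c(dim[1], dim[2], 3L))
}

#' Fit a sparse non-negative stain model to optical densities
#'
#' Factorizes the tissue-pixel OD matrix as \eqn{V \approx W H} by
#' minimizing \deqn{\tfrac12 \|V - WH\|_F^2 + \lambda \sum_j \|H_{j,:}\|_1}
#' subject to \eqn{W, H \ge 0} and unit Euclidean norm on each column of W.
#' The solver is multiplicative (Lee-Seung updates with the L1 term folded
#' into the H denominator), which makes the penalized objective
#' non-increasing across iterations; the unit-norm constraint is imposed at
#' the end by rescaling each W column and compensating the matching H row,
#' which leaves the reconstruction WH unchanged. Stains are ordered so the
#' column with the larger blue-channel OD weight (the hematoxylin-like,
#' nucleus-binding stain) comes first, making bases comparable across tiles.
#'
#' Density maps are returned for every pixel of the tile: background columns
#' are filled in by a fixed-basis non-negative fit so the model covers the
#' whole image, although only tissue pixels shaped the basis.
#'
#' @param od list from [rgbToOd()].
#' @param r number of stains (default 2 for hematoxylin and eosin).
#' @param lambda sparsity weight (default 0.1).
#' @param seed integer seed for the random initialization.
#' @param maxIter maximum solver iterations (default 200).
#' @param tol relative objective change declaring convergence (default 1e-6).
#' @return a [StainModel-class] object.
#' @export
fitStainModel <- function(od, r = 2L, lambda = 0.1, seed = 0L,
                          maxIter = 200L, tol = 1e-6) {
  if (r < 1L) stop("r must be at least 1")
  if (lambda < 0) stop("lambda must be non-negative")
  V <- od$V[, od$mask, drop = FALSE]
  n <- ncol(V)
  ev <- eigen(V %*% t(V), symmetric = TRUE, only.values = TRUE)$values
  if (sum(ev > 1e-10 * max(ev, 1e-300)) < r)
    stop("OD matrix is rank-deficient for ", r, " stains (constant image?)")
  eps <- 1e-16
  set.seed(seed)
  # For the two-stain case, initialize the basis at the extreme OD angles in
  # the top-2 singular plane (the classical geometric stain estimate); the
  # sparse factorization then refines it. Other r: seeded random init.
  W <- if (r == 2L) extremeAngleInit(V) else {
    W0 <- matrix(stats::runif(3L * r, 0.1, 1), 3L, r)
    sweep(W0, 2L, sqrt(colSums(W0^2)), "/")
  }
  H <- pmax(solve(crossprod(W) + diag(1e-8, r), crossprod(W, V)), 0)
  # Block-coordinate (HALS) solver: each H row is minimized exactly by L1
  # soft-thresholding, each W column by projecting its unconstrained optimum
  # onto the non-negative unit sphere — so the penalized objective is
  # non-increasing and the unit-norm constraint holds at every iteration.
  objective <- function(W, H) 0.5 * sum((V - W %*% H)^2) + lambda * sum(H)
  obj <- numeric(maxIter)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    G <- crossprod(W)                       # r x r, diag = 1
    A <- crossprod(W, V)                    # r x N
    for (j in seq_len(r)) {
      resid <- A[j, ] - G[j, -j, drop = FALSE] %*% H[-j, , drop = FALSE]
      H[j, ] <- pmax(resid - lambda, 0)
    }
    B <- V %*% t(H)                         # 3 x r
    C <- H %*% t(H)                         # r x r
    for (j in seq_len(r)) {
      v <- B[, j] - W[, -j, drop = FALSE] %*% C[-j, j, drop = FALSE]
      v <- pmax(v, 0)
      nv <- sqrt(sum(v^2))
      if (nv > eps) W[, j] <- v / nv
    }
    obj[it] <- objective(W, H)
    if (it > 1L && abs(obj[it - 1L] - obj[it]) <= tol * abs(obj[it - 1L])) {
      obj <- obj[seq_len(it)]
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("stain factorization did not converge in ", maxIter,
            " iterations; returning the last iterate")
  # Polish: refit basis and concentrations with the penalty off, starting
  # from the sparse solution (the lasso-then-least-squares refit idiom).
  # The L1 stage identifies the stain geometry; the polish removes its
  # shrinkage bias from W and from the reconstruction.
  for (it in seq_len(maxIter)) {
    G <- crossprod(W)
    A <- crossprod(W, V)
    for (j in seq_len(r)) {
      resid <- A[j, ] - G[j, -j, drop = FALSE] %*% H[-j, , drop = FALSE]
      H[j, ] <- pmax(resid, 0)
    }
    B <- V %*% t(H)
    C <- H %*% t(H)
    Wold <- W
    for (j in seq_len(r)) {
      v <- pmax(B[, j] - W[, -j, drop = FALSE] %*% C[-j, j, drop = FALSE], 0)
      nv <- sqrt(sum(v^2))
      if (nv > eps) W[, j] <- v / nv
    }
    if (max(abs(W - Wold)) < 1e-9) break
  }
  # deterministic stain order: larger blue-channel weight (hematoxylin) first
  ord <- order(W[3L, ], decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  # density maps for every pixel (background columns: fixed-basis NNLS)
  Hfull <- matrix(0, r, length(od$mask))
  Hfull[, od$mask] <- H
  if (any(!od$mask)) {
    Vb <- od$V[, !od$mask, drop = FALSE]
    Hb <- pmax(solve(crossprod(W) + diag(1e-8, r), crossprod(W, Vb)), 0.01)
    WtW <- crossprod(W)
    WtV <- crossprod(W, Vb)
    for (i in 1:100) Hb <- Hb * WtV / (WtW %*% Hb + eps)
    Hfull[, !od$mask] <- pmax(Hb, 0)
  }
  new("StainModel", W = W, H = Hfull, dim = as.integer(od$dim),
      mask = od$mask, lambda = lambda, objective = obj)
}

# Geometric two-stain initialization: robust extreme angles (1st / 99th
# percentile) of the OD cloud projected into its top-2 singular plane.
extremeAngleInit <- function(V) {
  sv <- svd(V, nu = 2L, nv = 0L)
  E <- sv$u
  proj <- crossprod(E, V)
  if (stats::median(proj[1, ]) < 0) { E[, 1] <- -E[, 1]; proj[1, ] <- -proj[1, ] }
  phi <- atan2(proj[2, ], proj[1, ])
  q <- stats::quantile(phi, c(0.01, 0.99), names = FALSE)
  W0 <- cbind(E %*% c(cos(q[1]), sin(q[1])), E %*% c(cos(q[2]), sin(q[2])))
  W0 <- pmax(W0, 1e-3)
  sweep(W0, 2L, sqrt(colSums(W0^2)), "/")
}

#' Robust pseudomaximum of stain density rows
#'
#' The 99th percentile of each density row, a robust stand-in for the row
#' maximum used to match stain intensity scales between source and target.
#' Percentile convention: linear interpolation between order statistics
#' (R quantile type 7), fixed and documented so results are reproducible.
#'
#' @param h a [StainModel-class] or an r x N density matrix.
#' @param prob percentile level (default 0.99).
#' @return numeric length-r vector of per-stain pseudomaxima.
#' @examples
#' robustPseudomax(matrix(1:100, nrow = 1))  # 99.01
#' @export
robustPseudomax <- function(h, prob = 0.99) {
  if (is(h, "StainModel")) h <- densityMaps(h)
  if (!is.matrix(h) || ncol(h) < 1L) stop("h must be a non-empty matrix")
  apply(h, 1L, stats::quantile, probs = prob, names = FALSE, type = 7L)
}

#' Normalize a tile's stain colors to a target's stain basis
#'
#' Structure-preserving color normalization: the source tile keeps its own
#' stain density maps (the tissue structure) but is re-rendered with the
#' target's stain color basis. Density rows are first rescaled by the ratio
#' of target to source robust pseudomaxima,
#' \eqn{H^{norm}_{j,:} = H_{j,:} \, RM(H_t)_j / RM(H_s)_j}, then recomposed
#' as \eqn{V^{norm} = W_t H^{norm}} and inverted through Beer-Lambert,
#' \eqn{I^{norm} = I_0 \exp(-V^{norm})}. Background pixels (per the source's
#' OD mask) pass through unchanged.
#'
#' @param img source tile, numeric H x W x 3 in [0, 255].
#' @param target the target stain model: a [StainModel-class], or a list
#'   with elements \code{W} (3 x r basis) and \code{rm} (length-r robust
#'   pseudomaxima) as returned by [readStainModel()].
#' @param targetRm target pseudomaxima; defaults to
#'   \code{robustPseudomax(target)} for a StainModel target, or
#'   \code{target$rm} for a list target.
#' @param srcModel optional pre-fitted [StainModel-class] of \code{img};
#'   fitted here when NULL.
#' @param i0,bgThreshold,lambda,seed,maxIter passed to [rgbToOd()] and
#'   [fitStainModel()] when the source model is fitted internally.
#' @return normalized tile, numeric H x W x 3 in [0, i0].
#' @export
normalizeToTarget <- function(img, target, targetRm = NULL, srcModel = NULL,
                              i0 = 255, bgThreshold = 0.15, lambda = 0.1,
                              seed = 0L, maxIter = 200L) {
  if (is(target, "StainModel")) {
    Wt <- stainBasis(target)
    if (is.null(targetRm)) targetRm <- robustPseudomax(target)
  } else {
    Wt <- target$W
    if (is.null(targetRm)) targetRm <- target$rm
  }
  if (is.null(srcModel)) {
    od <- rgbToOd(img, i0 = i0, bgThreshold = bgThreshold)
    srcModel <- fitStainModel(od, r = ncol(Wt), lambda = lambda,
                              seed = seed, maxIter = maxIter)
  }
  if (stainCount(srcModel) != ncol(Wt))
    stop("source and target stain models must share the same stain count")
  Hs <- densityMaps(srcModel)
  srcRm <- robustPseudomax(srcModel)
  scale <- targetRm / srcRm
  if (any(!is.finite(scale) | srcRm <= 0)) {
    warning("zero source pseudomax for at least one stain; scale factor set to 1")
    scale[!is.finite(scale) | srcRm <= 0] <- 1
  }
  Hnorm <- Hs * scale
  Vnorm <- Wt %*% Hnorm
  out <- odToRgb(Vnorm, dim = srcModel@dim, i0 = i0)
  if (any(!srcModel@mask)) {  # background passes through untouched
    keep <- !srcModel@mask
    for (ch in 1:3) {
      plane <- out[, , ch]
      orig <- img[, , ch]
      plane[keep] <- orig[keep]
      out[, , ch] <- plane
    }
  }
  out
}

#' Serialize a stain model to a JSON sidecar
#'
#' Writes the stain basis, robust pseudomaxima, sparsity weight and stain
#' count — everything [normalizeToTarget()] needs from a target — as a small
#' JSON file. Density maps are deliberately not serialized.
#'
#' @param model a [StainModel-class].
#' @param path output JSON path.
#' @param rm pseudomaxima to store (default computed from the model).
#' @return \code{readStainModel}: list with \code{W}, \code{rm},
#'   \code{lambda}, \code{r}, usable as the \code{target} of
#'   [normalizeToTarget()].
#' @export
saveStainModel <- function(model, path, rm = robustPseudomax(model)) {
  obj <- list(W = stainBasis(model), rm = rm,
              lambda = model@lambda, r = stainCount(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveStainModel
#' @export
readStainModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(W = matrix(unlist(obj$W), nrow = 3L), rm = as.numeric(obj$rm),
       lambda = as.numeric(obj$lambda), r = as.integer(obj$r))
}
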