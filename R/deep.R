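#' Rectified linear unit
#'
#' Elementwise \eqn{\max(0, z)}. Idempotent: \code{relu(relu(z)) == relu(z)}.
#'
#' @param z numeric scalar, vector, matrix or array.
#' @return same shape as \code{z}.
#' @export
relu <- function(z) pmax(z, 0)

#' Local response normalization across channels
#'
#' AlexNet-style cross-channel competition: activity at channel i is divided
#' by a power of the summed squared activity of its channel neighborhood,
#' \deqn{b^i_{x,y} = a^i_{x,y} \Big/ \Big(k + \alpha
#'   \sum_{j=\max(0, i-n/2)}^{\min(N-1, i+n/2)} (a^j_{x,y})^2\Big)^\beta}
#' with the window clipped at the channel range. Defaults are the classical
#' constants k = 2, alpha = 1e-4, beta = 0.75, n = 5.
#'
#' @param a numeric H x W x C activation array (or a matrix, treated as
#'   H x W x 1).
#' @param k,alpha,beta,n LRN parameters; \code{n} is the total window size
#'   (the window spans \code{floor(n/2)} channels each side).
#' @return array of the same shape.
#' @export
localResponseNorm <- function(a, k = 2, alpha = 1e-4, beta = 0.75, n = 5L) {
  if (n < 1L) stop("n must be at least 1")
  if (beta <= 0) stop("beta must be positive")
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  N <- dim(a)[3]
  half <- n %/% 2L
  sq <- a^2
  cs <- array(0, dim(a) + c(0, 0, 1))           # running sum over channels
  for (i in seq_len(N)) cs[, , i + 1L] <- cs[, , i] + sq[, , i]
  out <- a
  for (i in seq_len(N)) {
    lo <- max(1L, i - half); hi <- min(N, i + half)
    s <- cs[, , hi + 1L] - cs[, , lo]
    out[, , i] <- a[, , i] / (k + alpha * s)^beta
  }
  out
}

# layer table of the AlexNet-shaped backbone (single-tower variant:
# 5 conv + 3 fully-connected, fc7 tapped as the 4096-dim descriptor)
alexNetArch <- function(nClasses = 2L) {
  list(
    conv1 = list(type = "conv", k = 11L, inC = 3L,   outC = 96L,  stride = 4L, pad = 2L,
                 lrn = TRUE, pool = TRUE),
    conv2 = list(type = "conv", k = 5L,  inC = 96L,  outC = 256L, stride = 1L, pad = 2L,
                 lrn = TRUE, pool = TRUE),
    conv3 = list(type = "conv", k = 3L,  inC = 256L, outC = 384L, stride = 1L, pad = 1L,
                 lrn = FALSE, pool = FALSE),
    conv4 = list(type = "conv", k = 3L,  inC = 384L, outC = 384L, stride = 1L, pad = 1L,
                 lrn = FALSE, pool = FALSE),
    conv5 = list(type = "conv", k = 3L,  inC = 384L, outC = 256L, stride = 1L, pad = 1L,
                 lrn = FALSE, pool = TRUE),
    fc6 = list(type = "fc", inD = 9216L, outD = 4096L),
    fc7 = list(type = "fc", inD = 4096L, outD = 4096L),
    fc8 = list(type = "fc", inD = 4096L, outD = as.integer(nClasses))
  )
}

#' Seeded random weights for the AlexNet-shaped backbone
#'
#' He-normal initialization (SD \eqn{\sqrt{2/\mathrm{fan_{in}}}}, zero
#' biases), which keeps activation magnitudes of order one through the ReLU
#' stack. Weights of convolutional layers are stored ready for the im2col
#' matrix product: one (k*k*inC) x outC matrix per layer.
#'
#' @param seed integer seed; the same seed always yields bit-identical
#'   weights.
#' @param nClasses output width of the final layer (default 2).
#' @return named list of layers, each \code{list(W, b)}.
#' @export
alexNetWeights <- function(seed = 0L, nClasses = 2L) {
  set.seed(seed)
  arch <- alexNetArch(nClasses)
  out <- lapply(arch, function(l) {
    fanIn <- if (l$type == "conv") l$k^2 * l$inC else l$inD
    outW <- if (l$type == "conv") l$outC else l$outD
    list(W = matrix(stats::rnorm(fanIn * outW, sd = sqrt(2 / fanIn)), fanIn, outW),
         b = numeric(outW))
  })
  names(out) <- names(arch)
  out
}

# validate a weight list against the architecture; stops at the first mismatch
checkWeights <- function(weights, nClasses = 2L) {
  arch <- alexNetArch(nClasses)
  for (nm in names(arch)) {
    l <- arch[[nm]]
    fanIn <- if (l$type == "conv") l$k^2 * l$inC else l$inD
    outW <- if (l$type == "conv") l$outC else l$outD
    wl <- weights[[nm]]
    if (is.null(wl) || !all(dim(wl$W) == c(fanIn, outW)) || length(wl$b) != outW)
      stop("weight/architecture mismatch at layer '", nm, "': expected ",
           fanIn, " x ", outW)
  }
  invisible(TRUE)
}

# zero-padded strided convolution of an H x W x C array via im2col;
# weights: (k*k*C) x outC with columns ordered (ky, kx, channel)
convForward <- function(x, W, b, k, stride, pad) {
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  ph <- h + 2L * pad; pw <- w + 2L * pad
  P <- array(0, c(ph, pw, C))
  P[pad + seq_len(h), pad + seq_len(w), ] <- x
  outH <- (ph - k) %/% stride + 1L
  outW <- (pw - k) %/% stride + 1L
  baseY <- (seq_len(outH) - 1L) * stride
  baseX <- (seq_len(outW) - 1L) * stride
  base <- rep(baseY, times = outW) + rep(baseX, each = outH) * ph
  colOff <- as.vector(outer(
    as.vector(outer(seq_len(k), (seq_len(k) - 1L) * ph, "+")),
    (seq_len(C) - 1L) * ph * pw, "+"))
  M <- matrix(P[outer(base, colOff, "+")], outH * outW, k * k * C)
  out <- M %*% W
  out <- sweep(out, 2L, b, "+")
  array(out, c(outH, outW, ncol(W)))
}

# 3 x 3 stride-2 overlapping max pooling
maxPool <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  outH <- (h - 3L) %/% 2L + 1L
  outW <- (w - 3L) %/% 2L + 1L
  res <- NULL
  for (ky in 0:2) {
    for (kx in 0:2) {
      sl <- x[seq(1L + ky, by = 2L, length.out = outH),
              seq(1L + kx, by = 2L, length.out = outW), , drop = FALSE]
      res <- if (is.null(res)) sl else pmax(res, sl)
    }
  }
  res
}

# forward pass to the flattened pool5 activations (length 9216)
pool5Forward <- function(x, weights) {
  arch <- alexNetArch()
  for (nm in paste0("conv", 1:5)) {
    l <- arch[[nm]]
    x <- convForward(x, weights[[nm]]$W, weights[[nm]]$b, l$k, l$stride, l$pad)
    x <- relu(x)
    if (l$lrn) x <- localResponseNorm(x)
    if (l$pool) x <- maxPool(x)
  }
  c(x)
}

# fully-connected head; returns the requested tap
fcForward <- function(p5, weights, layer = "fc7") {
  a6 <- relu(drop(p5 %*% weights$fc6$W) + weights$fc6$b)
  if (layer == "fc6") return(a6)
  a7 <- relu(drop(a6 %*% weights$fc7$W) + weights$fc7$b)
  if (layer == "fc7") return(a7)
  drop(a7 %*% weights$fc8$W) + weights$fc8$b
}

#' Preprocess a tile for the backbone
#'
#' Resizes the shorter side to \code{inputSize} (bilinear), center-crops to
#' \code{inputSize} x \code{inputSize}, scales to [0, 1] and standardizes
#' each channel by the given means and SDs.
#'
#' @param img numeric H x W x 3 tile in [0, 255].
#' @param inputSize spatial side expected by the network (default 224).
#' @param channelMeans,channelSds per-channel standardization constants
#'   (defaults: the ImageNet conventions).
#' @return inputSize x inputSize x 3 array.
#' @export
preprocessTile <- function(img, inputSize = 224L,
                           channelMeans = c(0.485, 0.456, 0.406),
                           channelSds = c(0.229, 0.224, 0.225)) {
  checkTile(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  sc <- inputSize / min(h, w)
  nh <- max(inputSize, round(h * sc)); nw <- max(inputSize, round(w * sc))
  eb <- EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)), colormode = "Color")
  eb <- EBImage::resize(eb, w = nw, h = nh)
  px <- aperm(EBImage::imageData(eb), c(2L, 1L, 3L))
  y0 <- (dim(px)[1] - inputSize) %/% 2L
  x0 <- (dim(px)[2] - inputSize) %/% 2L
  px <- px[y0 + seq_len(inputSize), x0 + seq_len(inputSize), , drop = FALSE]
  for (ch in 1:3) px[, , ch] <- (px[, , ch] - channelMeans[ch]) / channelSds[ch]
  px
}

#' Extract deep features from tiles
#'
#' Runs each tile through the AlexNet-shaped backbone (5 convolutional
#' layers with ReLU, local response normalization and overlapping max
#' pooling, then the fully-connected stack) and returns the activations of
#' the tapped layer — 4096 values per image for the default "fc7" tap.
#' Weights come from \code{weights}; when NULL, a seeded He-random
#' initialization is used, so the extractor works as an untrained random
#' projection and the run is fully deterministic given \code{seed}.
#'
#' @param images list of tiles (H x W x 3 arrays in [0, 255]) or a single
#'   tile; names become row ids.
#' @param weights a weight list from [alexNetWeights()] /
#'   [finetuneBackbone()], a path to an RDS file holding one, or NULL for
#'   seeded random initialization.
#' @param layer tapped layer: "fc6", "fc7" (default) or "fc8".
#' @param seed seed for the random initialization when \code{weights} is
#'   NULL.
#' @param inputSize,channelMeans,channelSds see [preprocessTile()].
#' @return numeric matrix, one row per image (rownames = image ids, when
#'   named), with attribute \code{extractor}.
#' @export
deepFeatures <- function(images, weights = NULL, layer = "fc7", seed = 0L,
                         inputSize = 224L,
                         channelMeans = c(0.485, 0.456, 0.406),
                         channelSds = c(0.229, 0.224, 0.225)) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  if (length(images) == 0L) stop("no images supplied")
  if (is.character(weights)) weights <- readRDS(weights)
  if (is.null(weights)) weights <- alexNetWeights(seed = seed)
  checkWeights(weights, nClasses = ncol(weights$fc8$W))
  if (!layer %in% c("fc6", "fc7", "fc8"))
    stop("feature layer must be one of fc6, fc7, fc8")
  rows <- lapply(images, function(im) {
    x <- preprocessTile(im, inputSize = inputSize,
                        channelMeans = channelMeans, channelSds = channelSds)
    fcForward(pool5Forward(x, weights), weights, layer = layer)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(images)
  colnames(out) <- sprintf("%s_%04d", layer, seq_len(ncol(out)))
  structure(out, extractor = sprintf("alexnet_%s_seed%d", layer, seed))
}

#' Fine-tune the fully-connected head on labelled tiles
#'
#' Optional training hook: the convolutional layers stay frozen as a fixed
#' feature transform and the fully-connected stack (fc6-fc8) is trained by
#' full-batch gradient descent on the softmax cross-entropy, with early
#' stopping when validation accuracy has not improved for \code{patience}
#' consecutive epochs. The pipeline never requires this hook; with
#' \code{epochs = 0} the input weights are returned unchanged.
#'
#' @param images list of labelled tiles.
#' @param labels factor or character labels, one per tile (two classes).
#' @param weights starting weights (default: seeded random initialization).
#' @param epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping;
#'   \code{Inf} disables early stopping (no validation split needed).
#' @param valFrac fraction of tiles held out for validation (default 0.25).
#' @param lr learning rate (default 1e-4, stable for full-batch descent on
#'   this head).
#' @param seed seed for the split and any weight initialization.
#' @param inputSize,channelMeans,channelSds see [preprocessTile()].
#' @return updated weight list; attributes \code{loss} (training loss per
#'   epoch) and \code{stoppedAt} (last epoch run).
#' @export
finetuneBackbone <- function(images, labels, weights = NULL, epochs = 10L,
                             patience = 5L, valFrac = 0.25, lr = 1e-4,
                             seed = 0L, inputSize = 224L,
                             channelMeans = c(0.485, 0.456, 0.406),
                             channelSds = c(0.229, 0.224, 0.225)) {
  if (is.null(weights)) weights <- alexNetWeights(seed = seed)
  checkWeights(weights, nClasses = ncol(weights$fc8$W))
  if (epochs == 0L) return(weights)
  y <- as.integer(factor(labels))
  if (length(unique(y)) != 2L) stop("labels must contain exactly two classes")
  set.seed(seed)
  n <- length(images)
  nVal <- floor(valFrac * n)
  useVal <- is.finite(patience)
  if (useVal && nVal < 1L)
    stop("no validation split available: increase valFrac or set patience = Inf")
  idx <- sample.int(n)
  valIdx <- if (nVal >= 1L) idx[seq_len(nVal)] else integer(0)
  trIdx <- setdiff(idx, valIdx)
  P5 <- do.call(rbind, lapply(images, function(im)
    pool5Forward(preprocessTile(im, inputSize, channelMeans, channelSds), weights)))
  Y <- diag(2)[y, , drop = FALSE]
  softmax <- function(z) {
    z <- z - apply(z, 1L, max)
    e <- exp(z); e / rowSums(e)
  }
  forwardHead <- function(X, w) {
    a6 <- relu(sweep(X %*% w$fc6$W, 2L, w$fc6$b, "+"))
    a7 <- relu(sweep(a6 %*% w$fc7$W, 2L, w$fc7$b, "+"))
    z8 <- sweep(a7 %*% w$fc8$W, 2L, w$fc8$b, "+")
    list(a6 = a6, a7 = a7, z8 = z8)
  }
  best <- weights; bestVal <- -Inf; since <- 0L
  lossHist <- numeric(0)
  for (ep in seq_len(epochs)) {
    Xtr <- P5[trIdx, , drop = FALSE]; Ytr <- Y[trIdx, , drop = FALSE]
    f <- forwardHead(Xtr, weights)
    pr <- softmax(f$z8)
    lossHist[ep] <- -mean(rowSums(Ytr * log(pmax(pr, 1e-12))))
    m <- nrow(Xtr)
    d8 <- (pr - Ytr) / m
    g8 <- crossprod(f$a7, d8)
    d7 <- (d8 %*% t(weights$fc8$W)) * (f$a7 > 0)
    g7 <- crossprod(f$a6, d7)
    d6 <- (d7 %*% t(weights$fc7$W)) * (f$a6 > 0)
    g6 <- crossprod(Xtr, d6)
    weights$fc8$W <- weights$fc8$W - lr * g8
    weights$fc8$b <- weights$fc8$b - lr * colSums(d8)
    weights$fc7$W <- weights$fc7$W - lr * g7
    weights$fc7$b <- weights$fc7$b - lr * colSums(d7)
    weights$fc6$W <- weights$fc6$W - lr * g6
    weights$fc6$b <- weights$fc6$b - lr * colSums(d6)
    if (useVal) {
      fv <- forwardHead(P5[valIdx, , drop = FALSE], weights)
      acc <- mean(max.col(fv$z8) == y[valIdx])
      if (acc > bestVal) { bestVal <- acc; best <- weights; since <- 0L }
      else { since <- since + 1L; if (since >= patience) break }
    }
  }
  out <- if (useVal) best else weights
  attr(out, "loss") <- lossHist
  attr(out, "stoppedAt") <- ep
  out
}
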