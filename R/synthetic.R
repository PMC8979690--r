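#' Configuration for the synthetic two-stain tissue simulator
#'
#' The simulator renders histology-like tiles through the Beer-Lambert
#' relation \eqn{I = I_0 \exp(-W H)}: a hematoxylin-like density map of
#' randomly placed soft nuclei (purple) over an eosin-like stroma map
#' (pink) whose spatial texture is a Gauss-MRF field. The two classes
#' differ in nucleus count per tile and in the stroma field's interaction
#' coefficients — a denser, more anisotropic texture for the tumor class —
#' so class signal is carried both in color/density (visible to the deep
#' extractor) and in texture statistics (visible to the texture
#' descriptors).
#'
#' @param imageSize tile side in pixels (default 96).
#' @param stainBasis 3 x 2 OD color basis, columns = (hematoxylin, eosin);
#'   default: unit-normalized Ruifrok-Johnston H&E vectors.
#' @param nucleiDensity named nucleus counts per tile,
#'   \code{c(healthy = 25, rc = 55)}.
#' @param nucleusRadius radius range in pixels (default c(2, 5)).
#' @param textureBeta named list of stroma GMRF coefficients per class;
#'   default \code{healthy = c(0.22, 0.22)} (isotropic),
#'   \code{rc = c(0.05, 0.38)} (anisotropic).
#' @param textureScale stroma texture amplitude in density units
#'   (default 0.25).
#' @param stromaBase baseline eosin density (default 0.35).
#' @param noiseSd density-space Gaussian noise SD (default 0.02).
#' @param i0 incident intensity (default 255).
#' @return list of class \code{"TissueSimConfig"}.
#' @export
tissueSimConfig <- function(imageSize = 96L,
                            stainBasis = NULL,
                            nucleiDensity = c(healthy = 25L, rc = 55L),
                            nucleusRadius = c(2, 5),
                            textureBeta = list(healthy = c(0.22, 0.22),
                                               rc = c(0.05, 0.38)),
                            textureScale = 0.25,
                            stromaBase = 0.35,
                            noiseSd = 0.02,
                            i0 = 255) {
  if (is.null(stainBasis)) {
    stainBasis <- cbind(hematoxylin = c(0.650, 0.704, 0.286),
                        eosin = c(0.072, 0.990, 0.105))
  }
  stainBasis <- sweep(stainBasis, 2L, sqrt(colSums(stainBasis^2)), "/")
  if (min(stainBasis) < 0) stop("stain basis must be non-negative")
  stopifnot(imageSize >= 16L, all(nucleiDensity >= 0), textureScale >= 0,
            stromaBase >= 0, noiseSd >= 0)
  structure(list(imageSize = as.integer(imageSize), stainBasis = stainBasis,
                 nucleiDensity = nucleiDensity, nucleusRadius = nucleusRadius,
                 textureBeta = textureBeta, textureScale = textureScale,
                 stromaBase = stromaBase, noiseSd = noiseSd, i0 = i0),
            class = "TissueSimConfig")
}

#' Generate one synthetic stained tile
#'
#' Builds class-dependent hematoxylin and eosin density maps and renders
#' them as \eqn{I_0\exp(-WH)}. Nuclei are soft disks (Gaussian shoulder) at
#' random positions; the stroma carries the class's Gauss-MRF texture and
#' is attenuated under nuclei. Deterministic given \code{seed}.
#'
#' @param cfg a \code{"TissueSimConfig"}.
#' @param label class label, a name of \code{cfg$nucleiDensity}
#'   ("healthy" or "rc" by default).
#' @param seed integer seed.
#' @return numeric imageSize x imageSize x 3 tile in [0, i0].
#' @export
generateTile <- function(cfg, label, seed = 0L) {
  if (!label %in% names(cfg$nucleiDensity)) stop("unknown label: ", label)
  n <- cfg$imageSize
  set.seed(seed)
  nNuc <- cfg$nucleiDensity[[label]]
  hem <- matrix(0, n, n)
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  if (nNuc > 0) {
    cy <- stats::runif(nNuc, 1, n); cx <- stats::runif(nNuc, 1, n)
    rad <- stats::runif(nNuc, cfg$nucleusRadius[1], cfg$nucleusRadius[2])
    amp <- stats::runif(nNuc, 0.7, 1.2)
    for (i in seq_len(nNuc)) {
      d2 <- (yy - cy[i])^2 + (xx - cx[i])^2
      hem <- hem + amp[i] * exp(-d2 / (2 * (rad[i] / 1.5)^2))
    }
    hem <- pmin(hem, 1.6)    # overlapping nuclei saturate
  }
  beta <- cfg$textureBeta[[label]]
  field <- simulateGMRF(n, n, beta = beta, sigma = 1,
                        seed = deriveSeed(seed, 1L))
  field <- field / max(stats::sd(field), 1e-12)
  eos <- cfg$stromaBase + cfg$textureScale * field
  eos <- eos * (1 - 0.5 * pmin(hem, 1))   # eosin displaced under nuclei
  if (cfg$noiseSd > 0) {
    set.seed(deriveSeed(seed, 2L))
    hem <- hem + stats::rnorm(n * n, sd = cfg$noiseSd)
    eos <- eos + stats::rnorm(n * n, sd = cfg$noiseSd)
  }
  H <- rbind(pmax(c(hem), 0), pmax(c(eos), 0))
  V <- cfg$stainBasis %*% H
  I <- pmin(pmax(cfg$i0 * exp(-V), 0), cfg$i0)
  array(c(I[1, ], I[2, ], I[3, ]), c(n, n, 3L))
}

#' Generate a labelled synthetic dataset with augmentation and split
#'
#' Draws \code{nPerClass} source tiles per class, optionally expands each
#' with the requested lossless geometric variants, assigns a stratified
#' train/validation split (augmented variants of one source always share
#' the source's split), and optionally writes PNG tiles plus a
#' \code{manifest.csv} to \code{dir}.
#'
#' @param nPerClass source tiles per class.
#' @param cfg a \code{"TissueSimConfig"} (default [tissueSimConfig()]).
#' @param augmentOps character subset of
#'   \code{c("rot90","rot180","rot270","hflip")}, or NULL for no
#'   augmentation.
#' @param trainFrac training fraction (default 0.7).
#' @param seed master seed.
#' @param dir output directory for PNG tiles and manifest, or NULL to keep
#'   everything in memory.
#' @return list with \code{tiles} (named list) and \code{manifest}
#'   (data.frame id, path, label, split, provenance, source).
#' @export
generateDataset <- function(nPerClass = 100L, cfg = tissueSimConfig(),
                            augmentOps = NULL, trainFrac = 0.7, seed = 0L,
                            dir = NULL) {
  labels <- names(cfg$nucleiDensity)
  tiles <- list()
  rows <- list()
  k <- 0L
  for (li in seq_along(labels)) {
    lab <- labels[li]
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      srcId <- sprintf("%s_%03d", lab, i)
      tile <- generateTile(cfg, lab, seed = deriveSeed(seed, k))
      variants <- list(original = tile)
      if (!is.null(augmentOps))
        variants <- c(variants, augmentTile(tile, ops = augmentOps))
      for (vn in names(variants)) {
        id <- if (vn == "original") srcId else paste0(srcId, "_", vn)
        tiles[[id]] <- variants[[vn]]
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, path = NA_character_, label = lab, split = NA_character_,
          provenance = vn, source = srcId, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- splitDataset(manifest, trainFrac = trainFrac,
                           seed = deriveSeed(seed, k + 1L))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(manifest$id, ".png"))
    for (j in seq_len(nrow(manifest))) writeTile(tiles[[manifest$id[j]]], manifest$path[j])
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(tiles = tiles, manifest = manifest)
}

#' Stratified train/validation split of a dataset manifest
#'
#' Assigns each image to train or val so that within every class the
#' training fraction is \code{trainFrac} (exact to rounding). With
#' \code{groupBySource} (default, recommended) the split is drawn over
#' source images and every augmented variant inherits its source's side, so
#' augmentations never leak across the split.
#'
#' @param manifest data.frame with columns \code{id}, \code{label}, and
#'   (for grouped splitting) \code{source}.
#' @param trainFrac training fraction in (0, 1) (default 0.7).
#' @param seed integer seed; the same seed reproduces the same split.
#' @param groupBySource keep augmentations of one source together
#'   (default TRUE).
#' @return the manifest with its \code{split} column filled
#'   ("train" / "val").
#' @export
splitDataset <- function(manifest, trainFrac = 0.7, seed = 0L,
                         groupBySource = TRUE) {
  if (trainFrac <= 0 || trainFrac >= 1) stop("trainFrac must be in (0, 1)")
  if (is.null(manifest$source)) manifest$source <- manifest$id
  set.seed(seed)
  manifest$split <- NA_character_
  for (lab in unique(manifest$label)) {
    sel <- manifest$label == lab
    units <- if (groupBySource) unique(manifest$source[sel]) else manifest$id[sel]
    if (length(units) < 2L)
      stop("class '", lab, "' has fewer than 2 ",
           if (groupBySource) "source images" else "images")
    nTrain <- round(trainFrac * length(units))
    trainUnits <- sample(units, nTrain)
    key <- if (groupBySource) manifest$source else manifest$id
    manifest$split[sel] <- ifelse(key[sel] %in% trainUnits, "train", "val")
  }
  manifest
}

#' Read a dataset manifest and its tiles from disk
#'
#' Companion of [generateDataset()]'s \code{dir} mode: loads
#' \code{manifest.csv} and every referenced tile.
#'
#' @param dir directory holding \code{manifest.csv} and tiles.
#' @return list with \code{tiles} and \code{manifest}.
#' @export
readDataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  tiles <- lapply(manifest$path, readTile)
  names(tiles) <- manifest$id
  list(tiles = tiles, manifest = manifest)
}
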