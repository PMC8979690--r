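#' Run the fusion classification pipeline end to end
#'
#' Orchestrates the full workflow on a labelled tile collection: optional
#' stain normalization to a target tile, texture and deep feature
#' extraction, class-mean-difference selection of the deep block
#' (training rows only), concatenation fusion, repeated stratified
#' splitting, classifier training and metric computation. Every source of
#' randomness derives from the single master seed through a fixed counter
#' scheme, so a rerun with the same configuration reproduces the report
#' exactly.
#'
#' The configuration is a nested list (or a YAML file path with the same
#' structure):
#' \describe{
#'   \item{data}{one of \code{dir} (a directory written by
#'     [generateDataset()]), or \code{synthetic = list(nPerClass, ...)} to
#'     generate fixtures in-process.}
#'   \item{normalize}{logical (default FALSE); \code{targetId} names the
#'     normalization target tile, default: first training tile of the
#'     positive class.}
#'   \item{texture}{\code{list(method, params)}; method one of "hog",
#'     "glcm", "lbp", "gabor", "mrf" or "none" (deep-only ablation).}
#'   \item{deep}{\code{list(layer = "fc7", weights = NULL,
#'     inputSize = 224)}.}
#'   \item{fusion}{"fused" (default), "deep" or "texture" — which
#'     representation reaches the classifier.}
#'   \item{k}{deep dimensions retained (default 100).}
#'   \item{classifier}{"lr", "svm" or "rf" (default "svm").}
#'   \item{nRepeats}{re-split/evaluation repeats (default 10).}
#'   \item{metricMode}{"standard" or "as_printed".}
#'   \item{posClass}{positive label (default "healthy").}
#'   \item{seed}{master seed (default 0).}
#'   \item{outDir}{artifact directory, or NULL for in-memory only.}
#' }
#'
#' @param config nested list or YAML path as described above.
#' @param dataset optional pre-built list(tiles, manifest) overriding
#'   \code{config$data}.
#' @return list with \code{report} (per-repeat and mean metrics,
#'   representation label, resolved seeds), \code{perRepeat} data.frame,
#'   \code{meanMetrics}, \code{ranking}, and \code{outDir}.
#' @export
runPipeline <- function(config = list(), dataset = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    data = list(synthetic = list(nPerClass = 20L)),
    normalize = FALSE, targetId = NULL,
    texture = list(method = "gabor", params = list()),
    deep = list(layer = "fc7", weights = NULL, inputSize = 224L),
    fusion = "fused", k = 100L, classifier = "svm", nRepeats = 10L,
    metricMode = "standard", posClass = "healthy", seed = 0L,
    outDir = NULL), config)
  seed <- as.integer(cfg$seed)

  # --- stage 1: data -------------------------------------------------------
  if (is.null(dataset)) {
    dataset <- if (!is.null(cfg$data$dir)) {
      readDataset(cfg$data$dir)
    } else {
      sy <- cfg$data$synthetic
      generateDataset(nPerClass = sy$nPerClass %||% 20L,
                      cfg = do.call(tissueSimConfig, sy$sim %||% list()),
                      augmentOps = sy$augmentOps,
                      trainFrac = sy$trainFrac %||% 0.7,
                      seed = deriveSeed(seed, 1L))
    }
  }
  tiles <- dataset$tiles
  manifest <- dataset$manifest
  labels <- manifest$label[match(names(tiles), manifest$id)]
  if (length(unique(labels)) != 2L)
    stop("pipeline stage 'data': manifest must contain exactly two classes")

  # --- stage 2: stain normalization ---------------------------------------
  if (isTRUE(cfg$normalize)) {
    targetId <- cfg$targetId
    if (is.null(targetId)) {
      cand <- manifest$id[manifest$split == "train" & manifest$label == cfg$posClass]
      if (length(cand) == 0L) cand <- manifest$id[manifest$label == cfg$posClass]
      targetId <- cand[1]
    }
    tgtOd <- rgbToOd(tiles[[targetId]])
    tgtModel <- fitStainModel(tgtOd, seed = deriveSeed(seed, 2L))
    tgtRm <- robustPseudomax(tgtModel)
    tiles <- lapply(stats::setNames(names(tiles), names(tiles)), function(id) {
      res <- try(normalizeToTarget(tiles[[id]], tgtModel, targetRm = tgtRm,
                                   seed = deriveSeed(seed, 2L)), silent = TRUE)
      if (inherits(res, "try-error"))
        stop("pipeline stage 'normalize' failed on tile '", id, "': ",
             attr(res, "condition")$message)
      res
    })
  }

  # --- stage 3: texture features ------------------------------------------
  texMethod <- cfg$texture$method %||% "none"
  texture <- if (texMethod == "none") {
    matrix(numeric(0), nrow = length(tiles), ncol = 0L,
           dimnames = list(names(tiles), NULL))
  } else {
    fn <- switch(texMethod, hog = hogFeatures, glcm = glcmFeatures,
                 lbp = lbpFeatures, gabor = gaborFeatures, mrf = mrfFeatures,
                 stop("unknown texture method: ", texMethod))
    rows <- lapply(stats::setNames(names(tiles), names(tiles)), function(id) {
      res <- try(do.call(fn, c(list(tiles[[id]]), cfg$texture$params)),
                 silent = TRUE)
      if (inherits(res, "try-error"))
        stop("pipeline stage 'texture' failed on tile '", id, "': ",
             attr(res, "condition")$message)
      res
    })
    do.call(rbind, rows)
  }

  # --- stage 4: deep features ---------------------------------------------
  needDeep <- cfg$fusion %in% c("fused", "deep")
  deep <- if (needDeep) {
    deepFeatures(tiles, weights = cfg$deep$weights,
                 layer = cfg$deep$layer %||% "fc7",
                 seed = deriveSeed(seed, 3L),
                 inputSize = cfg$deep$inputSize %||% 224L)
  } else NULL

  # --- stage 5: repeated split / select / fuse / classify ------------------
  perRepeat <- list()
  ranking1 <- NULL
  fused1 <- NULL
  for (r in seq_len(cfg$nRepeats)) {
    man <- splitDataset(manifest, trainFrac = 0.7,
                        seed = deriveSeed(seed, 10L + r))
    trainIds <- man$id[man$split == "train"]
    valIds <- man$id[man$split == "val"]
    rep_ <- buildRepresentation(deep, texture, labels, names(tiles),
                                trainIds, cfg, seedRep = deriveSeed(seed, 10L + r))
    if (r == 1L) { ranking1 <- rep_$ranking; fused1 <- rep_$X }
    tr <- match(trainIds, names(tiles)); va <- match(valIds, names(tiles))
    res <- trainEval(rep_$X[tr, , drop = FALSE], labels[tr],
                     rep_$X[va, , drop = FALSE], labels[va],
                     spec = classifierSpec(cfg$classifier),
                     posClass = cfg$posClass, mode = cfg$metricMode,
                     seed = deriveSeed(seed, 100L + r))
    m <- res$metrics
    perRepeat[[r]] <- data.frame(repeatIdx = r, accuracy = m@accuracy,
                                 precision = m@precision, recall = m@recall,
                                 f1 = m@f1)
  }
  perRepeat <- do.call(rbind, perRepeat)
  meanMetrics <- colMeans(perRepeat[, c("accuracy", "precision", "recall", "f1")])

  report <- list(
    schema = "histofuse-report/1",
    representation = cfg$fusion,
    textureMethod = texMethod,
    classifier = cfg$classifier,
    metricMode = cfg$metricMode,
    nRepeats = cfg$nRepeats,
    seed = seed,
    perRepeat = perRepeat,
    mean = as.list(meanMetrics))

  # --- stage 6: artifacts ---------------------------------------------------
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(deep)) writeFeatureCsv(deep, file.path(cfg$outDir, "deep.csv"))
    if (ncol(texture) > 0L)
      writeFeatureCsv(texture, file.path(cfg$outDir, "texture.csv"))
    if (!is.null(ranking1)) saveRanking(ranking1, file.path(cfg$outDir, "ranking.json"))
    if (!is.null(fused1)) writeFeatureCsv(fused1, file.path(cfg$outDir, "fused.csv"))
    jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "rows")
    yaml::write_yaml(cfg[setdiff(names(cfg), "deep")],
                     file.path(cfg$outDir, "config.yaml"))
  }
  list(report = report, perRepeat = perRepeat, meanMetrics = meanMetrics,
       ranking = ranking1, outDir = cfg$outDir)
}

# assemble the classifier input for one repeat: select deep dims on the
# training rows only, then fuse per the requested representation
buildRepresentation <- function(deep, texture, labels, ids, trainIds, cfg,
                                seedRep) {
  if (cfg$fusion == "texture") {
    if (ncol(texture) == 0L) stop("texture representation requested but texture method is 'none'")
    return(list(X = texture, ranking = NULL))
  }
  tr <- match(trainIds, ids)
  ranking <- diffRank(deep[tr, , drop = FALSE], labels[tr],
                      k = min(cfg$k, ncol(deep)), posClass = cfg$posClass)
  deepSel <- selectFeatures(deep, ranking)
  X <- if (cfg$fusion == "deep") deepSel else fuseFeatures(deepSel, texture)
  list(X = X, ranking = ranking)
}
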