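#' Rank feature dimensions by class-mean difference
#'
#' For each dimension k of a training feature matrix, computes the
#' difference of class means
#' \deqn{\mathrm{diff}_k = \frac{1}{N_{pos}}\sum_{i \in pos} v_{i,k} -
#'   \frac{1}{N_{neg}}\sum_{i \in neg} v_{i,k},}
#' ranks dimensions from the largest difference down (by absolute value by
#' default, so dimensions that strongly favor either class are kept; set
#' \code{signed = TRUE} for the literal signed ranking) and retains the top
#' k. Ties break toward the lower dimension index. The ranking must be
#' computed on training rows only; it records those row ids, and
#' [selectFeatures()] applies the frozen index set verbatim to any matrix.
#'
#' @param features numeric matrix, rows = images (rownames used as ids),
#'   columns = dimensions.
#' @param labels logical or two-level factor per row; TRUE / first level =
#'   positive class.
#' @param k number of dimensions to retain (default 100).
#' @param signed rank by signed difference instead of absolute (default
#'   FALSE).
#' @param posClass the positive label when \code{labels} is not logical
#'   (default: first factor level).
#' @return a [DiffRanking-class].
#' @export
diffRank <- function(features, labels, k = 100L, signed = FALSE,
                     posClass = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  d <- ncol(features)
  if (k > d) stop("k (", k, ") exceeds the number of dimensions (", d, ")")
  if (k < 1L) stop("k must be at least 1")
  pos <- if (is.logical(labels)) labels else {
    if (is.null(posClass)) posClass <- levels(factor(labels))[1]
    labels == posClass
  }
  if (length(pos) != nrow(features)) stop("labels must match rows")
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present in the training rows")
  diff <- colMeans(features[pos, , drop = FALSE]) -
          colMeans(features[!pos, , drop = FALSE])
  key <- if (signed) diff else abs(diff)
  ord <- order(key, seq_len(d), decreasing = c(TRUE, FALSE), method = "radix")
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  new("DiffRanking", diff = unname(diff), order = as.integer(ord),
      kSelected = as.integer(k),
      classCounts = c(pos = nPos, neg = nNeg),
      trainIds = ids, signed = signed)
}

#' Apply a frozen feature selection
#'
#' Subsets a feature matrix to the dimensions retained by a
#' [DiffRanking-class], in rank order. The ranking carries its training row
#' ids, so selection on evaluation data reuses exactly the indices chosen
#' on the training rows — re-fitting on pooled rows is impossible through
#' this interface.
#'
#' @param features numeric matrix with the same column space the ranking was
#'   fitted on.
#' @param ranking a [DiffRanking-class].
#' @return matrix with \code{kSelected} columns.
#' @export
selectFeatures <- function(features, ranking) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (ncol(features) != length(ranking@diff))
    stop("feature width (", ncol(features), ") does not match the ranking (",
         length(ranking@diff), ")")
  features[, selectedIndices(ranking), drop = FALSE]
}

#' Fuse deep and texture feature blocks
#'
#' Horizontal concatenation with the deep block first, preserving row
#' alignment by image id and labelling each column with its provenance.
#' An optional z-scoring standardizes every column using means and SDs
#' fitted on a stated set of training rows only.
#'
#' @param deep numeric matrix of selected deep features (rows = images).
#' @param texture numeric matrix of texture features, same rows in the same
#'   order (may have zero columns).
#' @param zscore standardize columns (default FALSE).
#' @param trainIds row ids (or indices) used to fit standardization
#'   parameters when \code{zscore = TRUE}; default all rows.
#' @return fused matrix; columns named \code{deep_*} then \code{tex_*},
#'   attribute \code{provenance} gives the block of each column.
#' @export
fuseFeatures <- function(deep, texture, zscore = FALSE, trainIds = NULL) {
  if (!is.matrix(deep)) deep <- as.matrix(deep)
  if (!is.matrix(texture)) texture <- as.matrix(texture)
  if (nrow(texture) > 0L && nrow(deep) != nrow(texture))
    stop("deep and texture blocks must have the same number of rows")
  di <- rownames(deep); ti <- rownames(texture)
  if (!is.null(di) && !is.null(ti) && ncol(texture) > 0L && !identical(di, ti)) {
    bad <- union(setdiff(di, ti), setdiff(ti, di))
    if (length(bad) == 0L) bad <- unique(c(di[di != ti], ti[di != ti]))
    stop("row ids do not align between blocks: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (ncol(texture) == 0L) {
    fused <- deep
    prov <- rep("deep", ncol(deep))
  } else {
    fused <- cbind(deep, texture)
    prov <- c(rep("deep", ncol(deep)), rep("texture", ncol(texture)))
  }
  colnames(fused) <- paste0(ifelse(prov == "deep", "deep_", "tex_"),
                            c(colnames(deep) %||% sprintf("d%04d", seq_len(ncol(deep))),
                              if (ncol(texture) > 0L)
                                colnames(texture) %||% sprintf("t%04d", seq_len(ncol(texture)))))
  if (zscore) {
    rows <- if (is.null(trainIds)) seq_len(nrow(fused))
            else if (is.character(trainIds)) match(trainIds, rownames(fused))
            else trainIds
    mu <- colMeans(fused[rows, , drop = FALSE])
    sdv <- apply(fused[rows, , drop = FALSE], 2L, stats::sd)
    sdv[sdv < 1e-12] <- 1
    fused <- sweep(sweep(fused, 2L, mu, "-"), 2L, sdv, "/")
  }
  structure(fused, provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write or read a feature matrix as CSV
#'
#' Plain-text interchange for feature blocks: header = dimension names,
#' first column \code{id} = row ids, one row per image. Round-trips the
#' \code{extractor} attribute through a \code{# extractor:} comment line.
#'
#' @param features numeric matrix with rownames.
#' @param path CSV path.
#' @return \code{readFeatureCsv}: the matrix with ids and extractor
#'   restored.
#' @export
writeFeatureCsv <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ex <- attr(features, "extractor")
  if (!is.null(ex)) writeLines(paste0("# extractor: ", ex), con)
  df <- data.frame(id = rownames(features) %||% as.character(seq_len(nrow(features))),
                   features, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @export
readFeatureCsv <- function(path) {
  first <- readLines(path, n = 1L)
  ex <- if (startsWith(first, "# extractor: ")) sub("^# extractor: ", "", first) else NULL
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  if (!is.null(ex)) attr(m, "extractor") <- ex
  m
}

#' Serialize a diff ranking to JSON
#'
#' @param ranking a [DiffRanking-class].
#' @param path JSON path.
#' @return \code{readRanking}: the restored [DiffRanking-class].
#' @export
saveRanking <- function(ranking, path) {
  jsonlite::write_json(list(
    diff = ranking@diff, order = ranking@order, kSelected = ranking@kSelected,
    classCounts = as.list(ranking@classCounts), trainIds = ranking@trainIds,
    signed = ranking@signed), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveRanking
#' @export
readRanking <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DiffRanking", diff = as.numeric(o$diff), order = as.integer(o$order),
      kSelected = as.integer(o$kSelected),
      classCounts = c(pos = as.integer(o$classCounts$pos),
                      neg = as.integer(o$classCounts$neg)),
      trainIds = as.character(o$trainIds), signed = isTRUE(o$signed))
}
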