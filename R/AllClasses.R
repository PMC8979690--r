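#' @import methods
NULL

#' Stain separation model
#'
#' Result of sparse non-negative factorization of a tile's optical densities
#' \eqn{V \approx W H}: a 3 x r stain color-appearance basis \code{W} (one
#' unit-norm column per stain, hematoxylin-like stain first) and r x N stain
#' density maps \code{H} over the tile's pixels.
#'
#' @slot W 3 x r non-negative stain basis; columns have unit Euclidean norm.
#' @slot H r x N non-negative density maps (N = height * width).
#' @slot dim integer height/width of the source tile.
#' @slot mask logical length-N flag; TRUE for tissue pixels that entered the
#'   factorization, FALSE for background pixels carried through unchanged.
#' @slot lambda sparsity weight on the L1 term of the factorization objective.
#' @slot objective numeric trace of the objective value per solver iteration.
#'
#' @seealso [fitStainModel()], [normalizeToTarget()]
#' @export
setClass("StainModel",
  representation(
    W = "matrix",
    H = "matrix",
    dim = "integer",
    mask = "logical",
    lambda = "numeric",
    objective = "numeric"
  )
)

setValidity("StainModel", function(object) {
  msg <- character()
  if (nrow(object@W) != 3L) msg <- c(msg, "W must have 3 rows (RGB optical density)")
  if (ncol(object@W) != nrow(object@H)) msg <- c(msg, "ncol(W) must equal nrow(H)")
  if (min(object@W) < -1e-12) msg <- c(msg, "W must be non-negative")
  if (min(object@H) < -1e-12) msg <- c(msg, "H must be non-negative")
  nrm <- sqrt(colSums(object@W^2))
  if (any(abs(nrm - 1) > 1e-9)) msg <- c(msg, "columns of W must have unit Euclidean norm")
  if (length(object@lambda) != 1L || object@lambda < 0) msg <- c(msg, "lambda must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Class-mean difference feature ranking
#'
#' Per-dimension difference of class means over the training rows of a
#' feature matrix, with the permutation that sorts dimensions from the
#' largest difference down, and the number of leading dimensions retained.
#' The ranking stores the ids of the rows it was fitted on so a selection can
#' never silently be re-fit on evaluation data.
#'
#' @slot diff numeric length-D vector of class-mean differences (absolute by
#'   default; signed when fitted with \code{signed = TRUE}).
#' @slot order integer permutation of 1:D sorting \code{diff} non-increasing,
#'   ties broken by lower dimension index.
#' @slot kSelected integer count of leading ranked dimensions retained.
#' @slot classCounts named integer, numbers of positive and negative
#'   training rows.
#' @slot trainIds character ids of the rows the ranking was computed on.
#' @slot signed logical; FALSE means dimensions were ranked by |difference|.
#'
#' @seealso [diffRank()], [selectFeatures()]
#' @export
setClass("DiffRanking",
  representation(
    diff = "numeric",
    order = "integer",
    kSelected = "integer",
    classCounts = "integer",
    trainIds = "character",
    signed = "logical"
  )
)

setValidity("DiffRanking", function(object) {
  msg <- character()
  d <- length(object@diff)
  if (!setequal(object@order, seq_len(d))) msg <- c(msg, "order must be a permutation of 1:D")
  key <- if (object@signed) object@diff else abs(object@diff)
  if (is.unsorted(rev(key[object@order]))) msg <- c(msg, "diff[order] must be non-increasing")
  if (object@kSelected > d) msg <- c(msg, "kSelected must not exceed the number of dimensions")
  if (length(object@classCounts) != 2L) msg <- c(msg, "classCounts must have two entries")
  if (length(msg)) msg else TRUE
})

#' Two-class confusion matrix
#'
#' Counts of test outcomes under the convention that the positive class is
#' the healthy tissue class: \code{tp} = healthy classified healthy,
#' \code{tn} = tumor classified tumor, \code{fp} = healthy misclassified,
#' \code{fn} = tumor misclassified.
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @seealso [metricsFromConfusion()], [trainEval()]
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) "counts must be non-negative" else TRUE
})

#' Classification metrics report
#'
#' Accuracy, precision, recall and F1 as percentages in [0, 100], computed
#' from a [ConfusionMatrix] in one of two modes (see
#' [metricsFromConfusion()]). \code{flags} records metrics whose denominator
#' was zero (reported as 0).
#'
#' @slot accuracy,precision,recall,f1 percentages.
#' @slot mode "standard" or "as_printed".
#' @slot flags character vector of degenerate-denominator metric names.
#' @export
setClass("MetricsReport",
  representation(
    accuracy = "numeric", precision = "numeric",
    recall = "numeric", f1 = "numeric",
    mode = "character", flags = "character"
  )
)

setValidity("MetricsReport", function(object) {
  v <- c(object@accuracy, object@precision, object@recall, object@f1)
  msg <- character()
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100)) msg <- c(msg, "metrics must lie in [0, 100]")
  if (!object@mode %in% c("standard", "as_printed")) msg <- c(msg, "mode must be 'standard' or 'as_printed'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StainModel", function(object) {
  cat("StainModel:", ncol(object@W), "stains over",
      paste(object@dim, collapse = " x "), "pixels\n")
  cat("  tissue pixels:", sum(object@mask), "of", length(object@mask),
      sprintf("(lambda = %g)\n", object@lambda))
  cat("  W (columns = stains):\n")
  print(round(object@W, 4))
})

setMethod("show", "DiffRanking", function(object) {
  cat("DiffRanking over", length(object@diff), "dimensions;",
      object@kSelected, "selected",
      if (object@signed) "(signed ranking)\n" else "(|diff| ranking)\n")
  cat("  training rows:", sum(object@classCounts),
      sprintf("(pos = %d, neg = %d)\n", object@classCounts[1], object@classCounts[2]))
  top <- utils::head(object@order, 5L)
  cat("  top dims:", paste(top, collapse = ", "),
      " diff:", paste(signif(object@diff[top], 4), collapse = ", "), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
    dimnames = list(truth = c("pos", "neg"), predicted = c("pos", "neg")))
  cat("ConfusionMatrix (positive = healthy):\n")
  print(m)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s]: accuracy %.2f%%, precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
              object@mode, object@accuracy, object@precision, object@recall, object@f1))
  if (length(object@flags)) cat("  zero-denominator flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @describeIn StainModel stain color-appearance basis (3 x r matrix).
#' @param object a \code{StainModel}.
#' @export
setGeneric("stainBasis", function(object) standardGeneric("stainBasis"))

#' @export
setMethod("stainBasis", "StainModel", function(object) object@W)

#' @describeIn StainModel stain density maps (r x N matrix).
#' @export
setGeneric("densityMaps", function(object) standardGeneric("densityMaps"))

#' @export
setMethod("densityMaps", "StainModel", function(object) object@H)

#' @describeIn StainModel number of stains r.
#' @export
setGeneric("stainCount", function(object) standardGeneric("stainCount"))

#' @export
setMethod("stainCount", "StainModel", function(object) ncol(object@W))

#' @describeIn DiffRanking indices of the retained dimensions, in rank order.
#' @param object a \code{DiffRanking}.
#' @export
setGeneric("selectedIndices", function(object) standardGeneric("selectedIndices"))

#' @export
setMethod("selectedIndices", "DiffRanking",
  function(object) object@order[seq_len(object@kSelected)])

#' @describeIn DiffRanking per-dimension class-mean differences.
#' @export
setGeneric("diffValues", function(object) standardGeneric("diffValues"))

#' @export
setMethod("diffValues", "DiffRanking", function(object) object@diff)

#' Coerce a metrics report to a one-row data.frame
#'
#' @param x a \code{MetricsReport}.
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return data.frame with columns accuracy, precision, recall, f1, mode.
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(accuracy = x@accuracy, precision = x@precision,
             recall = x@recall, f1 = x@f1, mode = x@mode,
             stringsAsFactors = FALSE)
}
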