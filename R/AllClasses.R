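#' LabeledImageSet: a stack of same-size grayscale images with class labels
#'
#' The universal container moved between pipeline stages. Images are stored
#' as a height x width x n array of intensities in \[0, 1\]; labels are a
#' factor whose levels define the class order used everywhere downstream
#' (confusion-matrix rows, indicator coding, network outputs).
#'
#' @slot images numeric array, height x width x n, intensities in \[0, 1\].
#' @slot labels factor of length n; levels are the declared class names.
#'
#' @export
setClass("LabeledImageSet",
  representation(images = "array", labels = "factor"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@images)
    if (length(d) != 3L)
      msg <- c(msg, "images must be a height x width x n array")
    else {
      if (d[1] < 1L || d[2] < 1L)
        msg <- c(msg, "image height and width must be positive")
      if (length(object@labels) != d[3])
        msg <- c(msg, "length(labels) must equal the number of images")
    }
    if (nlevels(object@labels) < 1L)
      msg <- c(msg, "at least one class name must be declared")
    if (anyNA(object@labels))
      msg <- c(msg, "labels must not contain NA")
    if (length(object@images) &&
        (anyNA(object@images) ||
         min(object@images) < -1e-8 || max(object@images) > 1 + 1e-8))
      msg <- c(msg, "intensities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabeledImageSet
#'
#' @param images height x width x n numeric array (or a list of equal-size
#'   matrices) of intensities in \[0, 1\].
#' @param labels vector of class labels, one per image.
#' @param classNames optional character vector fixing the class order; by
#'   default classes are ordered by first appearance in `labels`.
#' @return A [LabeledImageSet-class] object.
#' @examples
#' imgs <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
#' LabeledImageSet(imgs, c("a", "a", "b", "b"))
#' @export
LabeledImageSet <- function(images, labels, classNames = NULL) {
  if (is.list(images)) {
    if (length(images)) {
      d <- dim(images[[1]])
      images <- array(unlist(images, use.names = FALSE),
                      dim = c(d[1], d[2], length(images)))
    } else {
      stop("cannot infer image dimensions from an empty list; pass an array")
    }
  }
  labels <- as.character(labels)
  if (is.null(classNames)) classNames <- unique(labels)
  unknown <- setdiff(labels, classNames)
  if (length(unknown))
    stopf("labels not in the declared class set: %s",
          paste(unique(unknown), collapse = ", "))
  new("LabeledImageSet", images = images,
      labels = factor(labels, levels = classNames))
}

#' EigenModel: a fitted eigenimage (PCA) basis
#'
#' Mean pixel vector plus the leading eigenvectors and eigenvalues of the
#' training pixel covariance (divisor n - 1). Component rows are orthonormal
#' and sign-fixed so each row's largest-magnitude entry is positive.
#'
#' @slot mean numeric length-D per-pixel training mean (D = height * width).
#' @slot components K x D matrix; row k is the k-th eigenvector.
#' @slot eigenvalues length-K non-negative reals, descending.
#' @slot totalVariance total variance of the centered training data (sum of
#'   all covariance eigenvalues, not just the K retained).
#' @slot dim integer height/width of the source images (NA if fitted on a
#'   plain matrix).
#' @export
setClass("EigenModel",
  representation(mean = "numeric", components = "matrix",
                 eigenvalues = "numeric", totalVariance = "numeric",
                 dim = "integer"),
  validity = function(object) {
    msg <- character(0)
    K <- nrow(object@components)
    if (length(object@mean) != ncol(object@components))
      msg <- c(msg, "mean length must equal ncol(components)")
    if (length(object@eigenvalues) != K)
      msg <- c(msg, "one eigenvalue per component row is required")
    if (K && is.unsorted(rev(object@eigenvalues)))
      msg <- c(msg, "eigenvalues must be sorted in descending order")
    if (K && min(object@eigenvalues) < -1e-10)
      msg <- c(msg, "eigenvalues must be non-negative")
    if (K) {
      gram <- tcrossprod(object@components)
      if (max(abs(gram - diag(K))) > 1e-8)
        msg <- c(msg, "component rows must be orthonormal")
    }
    if (length(msg)) msg else TRUE
  })

#' SelectionResult: outcome of stepwise discriminant feature selection
#'
#' @slot selected integer ids of the selected feature columns, in entry order.
#' @slot trace data.frame with one row per step: step, action
#'   ("enter"/"remove"/"stop"), feature, statistic (partial F), p_value.
#' @slot terminatedReason one of "no-candidate", "cap-reached",
#'   "iteration-guard".
#' @export
setClass("SelectionResult",
  representation(selected = "integer", trace = "data.frame",
                 terminatedReason = "character"),
  validity = function(object) {
    msg <- character(0)
    if (anyDuplicated(object@selected))
      msg <- c(msg, "selected feature ids must be unique")
    if (!object@terminatedReason %in%
        c("no-candidate", "cap-reached", "iteration-guard"))
      msg <- c(msg, "unknown termination reason")
    need <- c("step", "action", "feature", "statistic", "p_value")
    if (!all(need %in% names(object@trace)))
      msg <- c(msg, "trace must have columns step/action/feature/statistic/p_value")
    if (length(msg)) msg else TRUE
  })

#' MLPModel: a trained one-hidden-layer dense network
#'
#' ReLU hidden layer, softmax output; dropout is applied only during
#' training, so prediction is deterministic.
#'
#' @slot w1 input_dim x hidden_dim weight matrix.
#' @slot b1 hidden biases.
#' @slot w2 hidden_dim x output_dim weight matrix.
#' @slot b2 output biases.
#' @slot classNames class labels in output order.
#' @slot control the [mlpControl()] list the model was trained with.
#' @export
setClass("MLPModel",
  representation(w1 = "matrix", b1 = "numeric", w2 = "matrix",
                 b2 = "numeric", classNames = "character", control = "list"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@w1) != nrow(object@w2))
      msg <- c(msg, "hidden dimensions of w1 and w2 disagree")
    if (length(object@b1) != ncol(object@w1))
      msg <- c(msg, "b1 length must equal hidden width")
    if (length(object@b2) != ncol(object@w2))
      msg <- c(msg, "b2 length must equal output width")
    if (length(object@classNames) != ncol(object@w2))
      msg <- c(msg, "one class name per output unit is required")
    if (!all(is.finite(object@w1)) || !all(is.finite(object@w2)) ||
        !all(is.finite(object@b1)) || !all(is.finite(object@b2)))
      msg <- c(msg, "parameters must be finite")
    if (length(msg)) msg else TRUE
  })

#' ConfusionReport: confusion counts, recognition rates and per-class metrics
#'
#' Rows of the confusion matrix are the true classes, columns the predicted
#' classes. `rowPercent` is the row-normalized matrix in percent; its
#' diagonal holds the per-class recognition rates. The macro average is the
#' unweighted mean of the diagonal recognition rates; the weighted average
#' weights them by class support (equal to overall accuracy).
#'
#' @slot counts G x G integer matrix (may be 0 x 0 when the report was built
#'   from percentages alone).
#' @slot rowPercent G x G matrix of row percentages.
#' @slot perClass data.frame of one-vs-rest TP/TN/FP/FN, sensitivity and
#'   specificity per class (empty when counts are unknown).
#' @slot macroAverage unweighted mean of diagonal recognition rates.
#' @slot weightedAverage support-weighted mean of diagonal recognition rates.
#' @export
setClass("ConfusionReport",
  representation(counts = "matrix", rowPercent = "matrix",
                 perClass = "data.frame", macroAverage = "numeric",
                 weightedAverage = "numeric"),
  validity = function(object) {
    msg <- character(0)
    rp <- object@rowPercent
    if (nrow(rp) != ncol(rp))
      msg <- c(msg, "rowPercent must be square")
    ok <- is.finite(rp)
    if (any(rp[ok] < -1e-9) || any(rp[ok] > 100 + 1e-9))
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (length(object@counts) && any(object@counts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })
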