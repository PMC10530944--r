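# Generics and accessors for the package's S4 classes.

#' @rdname LabeledImageSet-class
#' @param x,object a `LabeledImageSet`.
#' @export
setGeneric("getImages", function(x) standardGeneric("getImages"))

#' @rdname LabeledImageSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname LabeledImageSet-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname LabeledImageSet-class
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname LabeledImageSet-class
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @rdname LabeledImageSet-class
#' @export
setGeneric("flattenImages", function(x) standardGeneric("flattenImages"))

#' @describeIn LabeledImageSet-class image array accessor.
#' @export
setMethod("getImages", "LabeledImageSet", function(x) x@images)

#' @describeIn LabeledImageSet-class label factor accessor.
#' @export
setMethod("classLabels", "LabeledImageSet", function(x) x@labels)

#' @describeIn LabeledImageSet-class declared class names, in order.
#' @export
setMethod("classNames", "LabeledImageSet", function(x) levels(x@labels))

#' @describeIn LabeledImageSet-class number of images.
#' @export
setMethod("nImages", "LabeledImageSet", function(x) dim(x@images)[3])

#' @describeIn LabeledImageSet-class height/width of every image.
#' @export
setMethod("imageDim", "LabeledImageSet", function(x) dim(x@images)[1:2])

#' @describeIn LabeledImageSet-class flatten to an n x (height*width) matrix
#'   (column-major within each image); the row order matches the labels.
#' @export
setMethod("flattenImages", "LabeledImageSet", function(x) {
  d <- dim(x@images)
  m <- t(matrix(x@images, nrow = d[1] * d[2], ncol = d[3]))
  rownames(m) <- NULL
  m
})

#' @describeIn LabeledImageSet-class subset images (keeps all class levels).
#' @param i index vector of images to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  new("LabeledImageSet", images = x@images[, , i, drop = FALSE],
      labels = x@labels[i])
})

setMethod("show", "LabeledImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("LabeledImageSet: %d image(s) of %d x %d pixels\n",
              d[3], d[1], d[2]))
  tab <- table(object@labels)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

#' @rdname EigenModel-class
#' @param object,x an `EigenModel`.
#' @export
setGeneric("eigenMean", function(x) standardGeneric("eigenMean"))

#' @rdname EigenModel-class
#' @export
setGeneric("eigenComponents", function(x) standardGeneric("eigenComponents"))

#' @rdname EigenModel-class
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname EigenModel-class
#' @export
setGeneric("totalVariance", function(x) standardGeneric("totalVariance"))

#' @describeIn EigenModel-class per-pixel training mean.
#' @export
setMethod("eigenMean", "EigenModel", function(x) x@mean)

#' @describeIn EigenModel-class K x D eigenvector matrix.
#' @export
setMethod("eigenComponents", "EigenModel", function(x) x@components)

#' @describeIn EigenModel-class descending covariance eigenvalues.
#' @export
setMethod("eigenValues", "EigenModel", function(x) x@eigenvalues)

#' @describeIn EigenModel-class total training variance (all components).
#' @export
setMethod("totalVariance", "EigenModel", function(x) x@totalVariance)

setMethod("show", "EigenModel", function(object) {
  cat(sprintf("EigenModel: %d component(s) over %d pixels\n",
              nrow(object@components), ncol(object@components)))
  ev <- explainedVariance(object)
  if (nrow(ev))
    cat(sprintf("cumulative explained variance: %.1f%%\n",
                100 * ev$cumulative[nrow(ev)]))
})

#' @rdname SelectionResult-class
#' @param x,object a `SelectionResult`.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' @describeIn SelectionResult-class selected feature ids, in entry order.
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @describeIn SelectionResult-class per-step enter/remove trace.
#' @export
setMethod("selectionTrace", "SelectionResult", function(x) x@trace)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d feature(s) selected, terminated: %s\n",
              length(object@selected), object@terminatedReason))
  if (length(object@selected))
    cat("selected:", paste(object@selected, collapse = " "), "\n")
})

#' @rdname ConfusionReport-class
#' @param x,object a `ConfusionReport`.
#' @export
setGeneric("macroAverage", function(x) standardGeneric("macroAverage"))

#' @rdname ConfusionReport-class
#' @export
setGeneric("weightedAverage", function(x) standardGeneric("weightedAverage"))

#' @rdname ConfusionReport-class
#' @export
setGeneric("rowPercent", function(x) standardGeneric("rowPercent"))

#' @rdname ConfusionReport-class
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname ConfusionReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @describeIn ConfusionReport-class unweighted mean diagonal recognition rate.
#' @export
setMethod("macroAverage", "ConfusionReport", function(x) x@macroAverage)

#' @describeIn ConfusionReport-class support-weighted mean diagonal rate.
#' @export
setMethod("weightedAverage", "ConfusionReport", function(x) x@weightedAverage)

#' @describeIn ConfusionReport-class row-normalized percentage matrix.
#' @export
setMethod("rowPercent", "ConfusionReport", function(x) x@rowPercent)

#' @describeIn ConfusionReport-class raw confusion counts.
#' @export
setMethod("confusionCounts", "ConfusionReport", function(x) x@counts)

#' @describeIn ConfusionReport-class per-class TP/TN/FP/FN and
#'   sensitivity/specificity.
#' @export
setMethod("perClassMetrics", "ConfusionReport", function(x) x@perClass)

setMethod("show", "ConfusionReport", function(object) {
  cat("Recognition rates (%)\n")
  rp <- round(object@rowPercent, 2)  # display only; raw values retained
  print(rp)
  cat(sprintf("Average (macro): %.2f\n", object@macroAverage))
  if (is.finite(object@weightedAverage))
    cat(sprintf("Average (weighted): %.2f\n", object@weightedAverage))
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %d -> %d -> %d (%s parameters)\n",
              nrow(object@w1), ncol(object@w1), ncol(object@w2),
              format(countParameters(nrow(object@w1), ncol(object@w1),
                                     ncol(object@w2)), big.mark = ",")))
  cat("classes:", paste(object@classNames, collapse = ", "), "\n")
})
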