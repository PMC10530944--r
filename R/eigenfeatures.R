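# Eigenimage (PCA) feature extraction.
#
# Images are flattened to rows of an n x D matrix and the leading
# eigenvectors of the pixel covariance (divisor n - 1) are computed through a
# rank-reduced singular value decomposition of the centered data, so the
# D x D covariance matrix is never materialized even when D >> n.

#' Fit an eigenimage model on a training set
#'
#' @param x a [LabeledImageSet-class] or an n x D numeric matrix of flattened
#'   images (one row per image).
#' @param k number of components to retain, 1 <= k <= min(n - 1, D). The
#'   conventional full-size default in this pipeline is 150.
#' @return An [EigenModel-class]. Eigenvector signs are fixed so each
#'   component's largest-magnitude entry is positive, making serialized
#'   models comparable across platforms.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' fitEigenModel(X, k = 3)
#' @export
fitEigenModel <- function(x, k = 150) {
  if (is(x, "LabeledImageSet")) {
    dm <- imageDim(x)
    X <- flattenImages(x)
  } else if (is.matrix(x) && is.numeric(x)) {
    dm <- c(NA_integer_, NA_integer_)
    X <- x
  } else stopf("x must be a LabeledImageSet or a numeric matrix")
  n <- nrow(X); D <- ncol(X)
  if (n < 2L) stopf("at least 2 images are required to fit a covariance")
  k <- assertCount(k, "k", min = 1L)
  if (k > min(n - 1L, D))
    stopf("k = %d exceeds min(n - 1, D) = %d", k, min(n - 1L, D))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = k)
  eig <- sv$d^2 / (n - 1)
  comp <- t(sv$v)
  # sign convention: largest-|entry| of each component is positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  new("EigenModel", mean = mu, components = comp,
      eigenvalues = eig[seq_len(k)], totalVariance = sum(eig),
      dim = as.integer(dm))
}

#' Project images onto a fitted eigenimage basis
#'
#' Scores are `(flattened image - mean) %*% t(components)`; on the training
#' set each score column has mean zero and variance equal to the
#' corresponding eigenvalue.
#'
#' @param model an [EigenModel-class].
#' @param x a [LabeledImageSet-class] or n x D matrix with D matching the
#'   model.
#' @return n x K score matrix with columns `PC1 ... PCK` (the feature matrix
#'   consumed by [runStepwise()] and [trainMLP()]).
#' @export
projectEigen <- function(model, x) {
  stopifnot(is(model, "EigenModel"))
  X <- if (is(x, "LabeledImageSet")) flattenImages(x) else x
  if (!is.matrix(X) || ncol(X) != length(model@mean))
    stopf("images have %s pixels but the model expects %d",
          if (is.matrix(X)) ncol(X) else "?", length(model@mean))
  scores <- sweep(X, 2L, model@mean) %*% t(model@components)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- NULL
  scores
}

#' Per-component explained-variance fractions
#'
#' @param model an [EigenModel-class].
#' @return data.frame with columns `component`, `eigenvalue`, `fraction` (of
#'   total training variance) and `cumulative`.
#' @export
explainedVariance <- function(model) {
  stopifnot(is(model, "EigenModel"))
  tv <- model@totalVariance
  frac <- if (tv > 0) model@eigenvalues / tv else
    rep(0, length(model@eigenvalues))
  data.frame(component = seq_along(frac), eigenvalue = model@eigenvalues,
             fraction = frac, cumulative = cumsum(frac))
}

#' Serialize an eigenimage model as flat text arrays plus JSON metadata
#'
#' @param model an [EigenModel-class].
#' @param directory output directory (created if needed).
#' @return Invisibly, `directory`.
#' @export
saveEigenModel <- function(model, directory) {
  stopifnot(is(model, "EigenModel"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", directory)
  wr <- function(x, f)
    writeLines(format(x, digits = 17, scientific = TRUE, trim = TRUE),
               file.path(directory, f))
  wr(model@mean, "mean.txt")
  wr(as.vector(model@components), "components.txt")
  wr(model@eigenvalues, "eigenvalues.txt")
  meta <- list(D = ncol(model@components), K = nrow(model@components),
               totalVariance = model@totalVariance,
               imageDim = model@dim, divisor = "n-1",
               signConvention = "largest-magnitude entry positive")
  jsonlite::write_json(meta, file.path(directory, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' @rdname saveEigenModel
#' @export
loadEigenModel <- function(directory) {
  meta <- jsonlite::read_json(file.path(directory, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(f) as.numeric(readLines(file.path(directory, f)))
  new("EigenModel", mean = rd("mean.txt"),
      components = matrix(rd("components.txt"), meta$K, meta$D),
      eigenvalues = rd("eigenvalues.txt"),
      totalVariance = meta$totalVariance,
      dim = as.integer(meta$imageDim))
}
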