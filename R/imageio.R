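# Manifest-driven image loading, normalization, and mean filtering.

#' Read a CSV manifest of image paths and labels
#'
#' @param path CSV file with columns `path` and `label`. Relative image paths
#'   are resolved against the manifest's own directory.
#' @return data.frame with columns `path` (absolute or resolved) and `label`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopf("manifest '%s' does not exist", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("path", "label") %in% names(man)))
    stopf("manifest '%s' must have columns 'path' and 'label'", path)
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  if (anyDuplicated(man$path))
    stopf("manifest '%s' lists duplicate image paths", path)
  man[c("path", "label")]
}

#' Load a manifest-described image set as normalized grayscale intensities
#'
#' Each image is decoded (PNG/JPEG/TIFF), converted to single-channel
#' luminance if it has color channels, resized to the target shape with
#' bilinear resampling, and scaled to \[0, 1\].
#'
#' @param manifest a data.frame with columns `path`/`label`, or the path of a
#'   CSV manifest (see [readManifest()]).
#' @param targetHeight,targetWidth output image size in pixels.
#' @param classNames optional explicit class order; defaults to first
#'   appearance order of the labels.
#' @return A [LabeledImageSet-class].
#' @export
loadDataset <- function(manifest, targetHeight = 128, targetWidth = 128,
                        classNames = NULL) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- readManifest(manifest)
  if (!is.data.frame(manifest) || !all(c("path", "label") %in% names(manifest)))
    stopf("manifest must be a data.frame with columns 'path' and 'label'")
  targetHeight <- assertCount(targetHeight, "targetHeight", min = 1L)
  targetWidth <- assertCount(targetWidth, "targetWidth", min = 1L)
  if (is.null(classNames)) classNames <- unique(as.character(manifest$label))
  bad <- !(manifest$label %in% classNames)
  if (any(bad))
    stopf("record %d ('%s') has unknown label '%s'",
          which(bad)[1], manifest$path[which(bad)[1]],
          manifest$label[which(bad)[1]])
  n <- nrow(manifest)
  imgs <- array(0, c(targetHeight, targetWidth, n))
  for (i in seq_len(n)) {
    p <- manifest$path[i]
    if (!file.exists(p)) stopf("record %d: image file '%s' is missing", i, p)
    img <- try(suppressWarnings(EBImage::readImage(p)), silent = TRUE)
    if (inherits(img, "try-error"))
      stopf("record %d: '%s' could not be decoded as an image", i, p)
    if (length(dim(img)) > 2L) img <- EBImage::channel(img, "luminance")
    # EBImage stores width x height; transpose into our height x width grid
    d <- dim(img)
    if (d[1] != targetWidth || d[2] != targetHeight)
      img <- EBImage::resize(img, w = targetWidth, h = targetHeight)
    imgs[, , i] <- clamp01(t(EBImage::imageData(img)))
  }
  LabeledImageSet(imgs, manifest$label, classNames = classNames)
}

#' The mean-filter (averaging) smoothing kernel
#'
#' A size x size mask with every weight equal to 1 / size^2 (the classic
#' 3 x 3 mask of 1/9 entries by default), so the filter output at each pixel
#' is the mean of its neighborhood.
#'
#' @param size odd kernel side length in pixels.
#' @return size x size numeric matrix whose entries sum to 1.
#' @export
averagingKernel <- function(size = 3) {
  size <- assertCount(size, "size", min = 1L)
  if (size %% 2L == 0L) stopf("kernel size must be odd, got %d", size)
  matrix(1 / size^2, size, size)
}

#' Apply the averaging filter to one intensity grid
#'
#' The mask moves pixel by pixel over the whole image; each output pixel is
#' the mean of its size x size neighborhood. Borders use replicate
#' (edge-value) padding, so the output has the same size as the input and no
#' artificial dark halo is introduced.
#'
#' @param image numeric matrix of intensities.
#' @param size odd kernel side length, at most `min(dim(image))`.
#' @return matrix of the same dimensions.
#' @examples
#' applyAveragingFilter(matrix(runif(64), 8, 8))
#' @export
applyAveragingFilter <- function(image, size = 3) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("image must be a numeric matrix")
  size <- assertCount(size, "size", min = 1L)
  if (size %% 2L == 0L) stopf("kernel size must be odd, got %d", size)
  if (size > min(dim(image)))
    stopf("kernel size %d exceeds the smallest image dimension", size)
  r <- (size - 1L) %/% 2L
  if (r == 0L) return(image)
  h <- nrow(image); w <- ncol(image)
  pad <- image[c(rep(1L, r), seq_len(h), rep(h, r)),
               c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (di in 0:(size - 1L))
    for (dj in 0:(size - 1L))
      out <- out + pad[di + seq_len(h), dj + seq_len(w), drop = FALSE]
  out / size^2
}

#' Apply the averaging filter to every image in a set
#'
#' @param x a [LabeledImageSet-class].
#' @param size odd kernel side length.
#' @return A [LabeledImageSet-class] of the same shape.
#' @export
filterDataset <- function(x, size = 3) {
  stopifnot(is(x, "LabeledImageSet"))
  imgs <- x@images
  for (i in seq_len(dim(imgs)[3]))
    imgs[, , i] <- applyAveragingFilter(x@images[, , i], size)
  new("LabeledImageSet", images = imgs, labels = x@labels)
}
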