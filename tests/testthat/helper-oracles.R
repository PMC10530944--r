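# Independent oracles and small fixtures used across the suite.

# double-loop neighborhood-mean filter with replicate padding
naiveMeanFilter <- function(image, size = 3) {
  h <- nrow(image); w <- ncol(image); r <- (size - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ci <- min(max(i + di, 1), h)
          cj <- min(max(j + dj, 1), w)
          acc <- acc + image[ci, cj]
        }
      }
      out[i, j] <- acc / size^2
    }
  }
  out
}

# dense covariance eigendecomposition PCA (only viable when D is tiny)
densePCAOracle <- function(X, k) {
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  scores <- sweep(X, 2, colMeans(X)) %*% e$vectors[, seq_len(k), drop = FALSE]
  list(values = e$values[seq_len(k)], vectors = e$vectors[, seq_len(k), drop = FALSE],
       scores = scores)
}

# enter-mode p-value of a single candidate given selected columns, via
# stats::lm + anova.mlm Wilks (exact F for a 1-df hypothesis)
wilksEnterOracle <- function(selected, candidate, labels) {
  Y <- swldanet::classIndicator(labels, drop = TRUE)
  x <- candidate
  if (is.null(selected) || NCOL(selected) == 0) {
    an <- stats::anova(stats::lm(Y ~ x), test = "Wilks")
  } else {
    S <- as.matrix(selected)
    an <- stats::anova(stats::lm(Y ~ S + x), test = "Wilks")
  }
  an["x", "Pr(>F)"]
}

# small labeled random design with a requested number of classes
randomDesign <- function(n, p, G, seed) {
  withr::with_seed(seed, {
    y <- factor(rep(paste0("g", seq_len(G)), length.out = n))
    X <- matrix(rnorm(n * p), n, p)
    list(X = X, y = y)
  })
}

# tiny phantom spec used by fast pipeline tests
tinySpec <- function(effect, seed, nPer = 25, noise = 0.15) {
  synthSpec(imageHeight = 16, imageWidth = 16,
            classNames = c("w", "x", "y", "z"), nPerClass = rep(nPer, 4),
            effectSize = effect, noiseSd = noise, nSignalModes = 3,
            seed = seed)
}

# tiny pipeline configuration matched to tinySpec()
tinyControl <- function(seed, folds = 3) {
  pipelineControl(
    preprocess = list(height = 16L, width = 16L, filter = TRUE, filterSize = 3L),
    pca = list(k = 8L),
    stepwise = stepwiseControl(maxFeatures = 6),
    mlp = list(hiddenDim = 16L, epochs = 15L, batchSize = 16L),
    eval = list(folds = folds, seed = seed))
}
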