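# One-hidden-layer dense network classifier (ReLU, inverted dropout,
# softmax, Adam, categorical cross-entropy). At ~54k parameters the model is
# desk-scale, so it is implemented directly over base matrix algebra, which
# buys full determinism control from a single seed.

#' Hyperparameters of the dense network classifier
#'
#' Defaults are the reference configuration of the pipeline: 512 hidden
#' units, dropout 0.5, Adam with learning rate 0.001, batch size 32, 100
#' epochs, validation split 0.25, and no early stopping. Adam's moment
#' parameters are the conventional beta1 = 0.9, beta2 = 0.999,
#' epsilon = 1e-8.
#'
#' @param inputDim number of input features (the selected feature count).
#' @param hiddenDim hidden layer width.
#' @param outputDim number of classes.
#' @param dropoutRate probability of zeroing a hidden unit during training
#'   (inverted dropout; inference is deterministic).
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param epochs fixed number of training epochs.
#' @param validationSplit fraction of the data held out (stratified) for
#'   per-epoch validation metrics.
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @return list of class `"MLPControl"`.
#' @export
mlpControl <- function(inputDim, hiddenDim = 512, outputDim = 4,
                       dropoutRate = 0.5, learningRate = 0.001,
                       batchSize = 32, epochs = 100, validationSplit = 0.25,
                       seed = 1, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  structure(list(
    inputDim = assertCount(inputDim, "inputDim", min = 1L),
    hiddenDim = assertCount(hiddenDim, "hiddenDim", min = 1L),
    outputDim = assertCount(outputDim, "outputDim", min = 1L),
    dropoutRate = assertNumber(dropoutRate, "dropoutRate", 0, 1 - 1e-12),
    learningRate = assertNumber(learningRate, "learningRate", 1e-12),
    batchSize = assertCount(batchSize, "batchSize", min = 1L),
    epochs = assertCount(epochs, "epochs", min = 1L),
    validationSplit = assertNumber(validationSplit, "validationSplit",
                                   1e-12, 1 - 1e-12),
    seed = assertCount(seed, "seed"),
    beta1 = assertNumber(beta1, "beta1", 0, 1),
    beta2 = assertNumber(beta2, "beta2", 0, 1),
    epsilon = assertNumber(epsilon, "epsilon", 0)),
    class = "MLPControl")
}

#' Trainable parameter count of the dense network
#'
#' `inputDim * hiddenDim + hiddenDim + hiddenDim * outputDim + outputDim`:
#' input-to-hidden weights and hidden biases plus hidden-to-output weights
#' and output biases. Dropout adds no parameters.
#'
#' @param inputDim,hiddenDim,outputDim layer widths (all >= 1).
#' @return integer parameter count.
#' @examples
#' countParameters(100, 512, 4)  # 53764
#' @export
countParameters <- function(inputDim, hiddenDim, outputDim) {
  inputDim <- assertCount(inputDim, "inputDim", min = 1L)
  hiddenDim <- assertCount(hiddenDim, "hiddenDim", min = 1L)
  outputDim <- assertCount(outputDim, "outputDim", min = 1L)
  inputDim * hiddenDim + hiddenDim + hiddenDim * outputDim + outputDim
}

.softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

.xent <- function(P, yIdx) {
  -mean(log(pmax(P[cbind(seq_along(yIdx), yIdx)], 1e-12)))
}

.forwardMLP <- function(w1, b1, w2, b2, X) {
  A <- sweep(X %*% w1, 2L, b1, `+`)
  H <- pmax(A, 0)
  .softmax(sweep(H %*% w2, 2L, b2, `+`))
}

# Stratified split of indices: returns list(train, val) with every class
# represented in the training portion.
.stratifiedSplit <- function(labels, fraction) {
  train <- integer(0); val <- integer(0)
  for (lev in levels(labels)) {
    idx <- sample(which(labels == lev))
    nv <- floor(length(idx) * fraction)
    if (nv >= length(idx))
      stopf("class '%s' would be absent from the training portion; use a smaller validation split or another seed", lev)
    val <- c(val, idx[seq_len(nv)])
    train <- c(train, idx[setdiff(seq_along(idx), seq_len(nv))])
  }
  list(train = sort(train), val = sort(val))
}

#' Train the dense network classifier
#'
#' Applies a stratified validation split, then runs Adam on minibatches of
#' the remaining data for a fixed number of epochs (no early stopping).
#' Inverted dropout is applied to the hidden layer during training only.
#' Weights are initialized from a seeded uniform distribution scaled by
#' fan-in (+/- sqrt(6 / fanIn)); biases start at zero. All randomness flows
#' from `control$seed`, so retraining with the same inputs reproduces the
#' model bit for bit on one platform.
#'
#' @param features n x inputDim numeric matrix (e.g. eigenimage scores
#'   restricted to the selected features).
#' @param labels factor of class labels; all classes must survive the split.
#' @param control an [mlpControl()] list; `inputDim`/`outputDim` must match
#'   the data.
#' @return list with `model` (an [MLPModel-class]) and `history` (data.frame
#'   of per-epoch training loss/accuracy and validation loss/accuracy).
#' @export
trainMLP <- function(features, labels,
                     control = mlpControl(ncol(features),
                                          outputDim = nlevels(as.factor(labels)))) {
  X <- as.matrix(features)
  labels <- as.factor(labels)
  if (!inherits(control, "MLPControl"))
    stopf("control must come from mlpControl()")
  if (ncol(X) != control$inputDim)
    stopf("features have %d columns but control$inputDim is %d",
          ncol(X), control$inputDim)
  if (nlevels(labels) != control$outputDim)
    stopf("labels have %d classes but control$outputDim is %d",
          nlevels(labels), control$outputDim)
  if (any(tabulate(labels, nlevels(labels)) == 0L))
    stopf("every class must be present in the training labels")
  withSeed(control$seed, {
    sp <- .stratifiedSplit(labels, control$validationSplit)
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- labels[sp$train]
    Xva <- X[sp$val, , drop = FALSE];   yva <- labels[sp$val]
    ntr <- nrow(Xtr)
    if (ntr < control$batchSize)
      stopf("training portion (%d) is smaller than one batch (%d)",
            ntr, control$batchSize)
    nin <- control$inputDim; nh <- control$hiddenDim; nout <- control$outputDim
    l1 <- sqrt(6 / nin); l2 <- sqrt(6 / nh)
    w1 <- matrix(runif(nin * nh, -l1, l1), nin, nh); b1 <- numeric(nh)
    w2 <- matrix(runif(nh * nout, -l2, l2), nh, nout); b2 <- numeric(nout)
    mom <- lapply(list(w1, b1, w2, b2), function(p) p * 0)
    vel <- mom
    Ytr <- classIndicator(ytr)
    yIdxTr <- as.integer(ytr); yIdxVa <- as.integer(yva)
    drp <- control$dropoutRate
    hist <- matrix(NA_real_, control$epochs, 4,
                   dimnames = list(NULL, c("loss", "accuracy",
                                           "valLoss", "valAccuracy")))
    t <- 0L
    for (ep in seq_len(control$epochs)) {
      perm <- sample(ntr)
      starts <- seq(1L, ntr, by = control$batchSize)
      for (s in starts) {
        idx <- perm[s:min(s + control$batchSize - 1L, ntr)]
        nb <- length(idx)
        Xb <- Xtr[idx, , drop = FALSE]; Yb <- Ytr[idx, , drop = FALSE]
        A <- sweep(Xb %*% w1, 2L, b1, `+`)
        H <- pmax(A, 0)
        if (drp > 0) {
          mask <- matrix((runif(nb * nh) >= drp) / (1 - drp), nb, nh)
          Hd <- H * mask
        } else Hd <- H
        P <- .softmax(sweep(Hd %*% w2, 2L, b2, `+`))
        dS <- (P - Yb) / nb
        gW2 <- crossprod(Hd, dS); gb2 <- colSums(dS)
        dH <- dS %*% t(w2)
        if (drp > 0) dH <- dH * mask
        dA <- dH * (A > 0)
        gW1 <- crossprod(Xb, dA); gb1 <- colSums(dA)
        t <- t + 1L
        grads <- list(gW1, gb1, gW2, gb2)
        pars <- list(w1, b1, w2, b2)
        for (j in 1:4) {
          mom[[j]] <- control$beta1 * mom[[j]] + (1 - control$beta1) * grads[[j]]
          vel[[j]] <- control$beta2 * vel[[j]] + (1 - control$beta2) * grads[[j]]^2
          mhat <- mom[[j]] / (1 - control$beta1^t)
          vhat <- vel[[j]] / (1 - control$beta2^t)
          pars[[j]] <- pars[[j]] - control$learningRate * mhat /
            (sqrt(vhat) + control$epsilon)
        }
        w1 <- pars[[1]]; b1 <- pars[[2]]; w2 <- pars[[3]]; b2 <- pars[[4]]
      }
      Ptr <- .forwardMLP(w1, b1, w2, b2, Xtr)
      hist[ep, "loss"] <- .xent(Ptr, yIdxTr)
      hist[ep, "accuracy"] <- mean(max.col(Ptr, ties.method = "first") == yIdxTr)
      if (nrow(Xva)) {
        Pva <- .forwardMLP(w1, b1, w2, b2, Xva)
        hist[ep, "valLoss"] <- .xent(Pva, yIdxVa)
        hist[ep, "valAccuracy"] <- mean(max.col(Pva, ties.method = "first") == yIdxVa)
      }
    }
    model <- new("MLPModel", w1 = unname(w1), b1 = unname(b1),
                 w2 = unname(w2), b2 = unname(b2),
                 classNames = levels(labels), control = unclass(control))
    list(model = model,
         history = data.frame(epoch = seq_len(control$epochs), hist))
  })
}

#' Predict classes and class probabilities
#'
#' Dropout is disabled at inference; prediction is deterministic.
#'
#' @param object an [MLPModel-class].
#' @param newdata n x inputDim feature matrix.
#' @param ... ignored.
#' @return list with `class` (factor of predicted labels) and `prob`
#'   (n x G softmax probability matrix; rows sum to 1).
#' @export
setMethod("predict", "MLPModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object@w1))
    stopf("newdata has %d columns but the model expects %d",
          ncol(X), nrow(object@w1))
  P <- .forwardMLP(object@w1, object@b1, object@w2, object@b2, X)
  colnames(P) <- object@classNames
  cls <- factor(object@classNames[max.col(P, ties.method = "first")],
                levels = object@classNames)
  list(class = cls, prob = P)
})

#' Serialize a trained network as flat text arrays plus JSON metadata
#'
#' @param model an [MLPModel-class].
#' @param directory output directory (created if needed).
#' @return Invisibly, `directory`.
#' @export
saveMLPModel <- function(model, directory) {
  stopifnot(is(model, "MLPModel"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", directory)
  wr <- function(x, f)
    writeLines(format(as.vector(x), digits = 17, scientific = TRUE,
                      trim = TRUE), file.path(directory, f))
  wr(model@w1, "w1.txt"); wr(model@b1, "b1.txt")
  wr(model@w2, "w2.txt"); wr(model@b2, "b2.txt")
  jsonlite::write_json(
    c(list(classNames = model@classNames), model@control),
    file.path(directory, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' @rdname saveMLPModel
#' @export
loadMLPModel <- function(directory) {
  meta <- jsonlite::read_json(file.path(directory, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(f) as.numeric(readLines(file.path(directory, f)))
  ctl <- meta[setdiff(names(meta), "classNames")]
  new("MLPModel",
      w1 = matrix(rd("w1.txt"), ctl$inputDim, ctl$hiddenDim),
      b1 = rd("b1.txt"),
      w2 = matrix(rd("w2.txt"), ctl$hiddenDim, ctl$outputDim),
      b2 = rd("b2.txt"),
      classNames = meta$classNames, control = ctl)
}
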