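# Stratified k-fold evaluation of the full pipeline and confusion-matrix
# reporting (recognition-rate tables, sensitivity/specificity).

#' Build a stratified fold plan
#'
#' Within each class, indices are shuffled (seeded) and dealt round-robin
#' into folds, with the starting fold rotating by the cumulative sample
#' count across classes. This guarantees that per-fold class counts differ
#' from perfect proportionality by at most one sample, that all folds are
#' non-empty whenever n >= k, and that any class with at least two members
#' appears in every training fold.
#'
#' @param labels factor (or vector) of class labels.
#' @param k number of folds (default 10); 2 <= k <= n.
#' @param seed integer seed for the shuffles.
#' @return list of class `"FoldPlan"` with elements `k`, `assignments`
#'   (per-sample fold index in 1..k) and `seed`.
#' @export
makeFolds <- function(labels, k = 10, seed = 1) {
  labels <- as.factor(labels)
  n <- length(labels)
  k <- assertCount(k, "k", min = 2L)
  if (k > n) stopf("k = %d exceeds the number of samples (%d)", k, n)
  sizes <- tabulate(labels, nlevels(labels))
  if (any(sizes < 2L))
    stopf("class '%s' has fewer than 2 members",
          levels(labels)[which(sizes < 2L)[1]])
  assignments <- integer(n)
  withSeed(deriveSeed(seed, 3L), {
    offset <- 0L
    for (g in seq_len(nlevels(labels))) {
      idx <- sample(which(labels == levels(labels)[g]))
      assignments[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  if (any(tabulate(assignments, k) == 0L))
    stopf("internal error: empty fold produced")
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "FoldPlan")
}

# per-class one-vs-rest metrics from a counts matrix
.perClassMetrics <- function(counts) {
  n <- sum(counts)
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- n - tp - fn - fp
  data.frame(class = rownames(counts), TP = tp, TN = tn, FP = fp, FN = fn,
             sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
             specificity = ifelse(tn + fp > 0, tn / (tn + fp), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a confusion matrix into a recognition-rate report
#'
#' Rows are the true classes. Row percentages are `100 * count / rowSum` for
#' every supported row (rows without support yield NA). The macro average is
#' the unweighted mean of the diagonal recognition rates; the weighted
#' average weights each class's rate by its support and algebraically equals
#' overall accuracy. Display rounding (half-even, 2 decimals) happens only in
#' the show method; raw values are retained.
#'
#' Alternatively a row-percentage matrix can be summarized directly
#' (`percent = TRUE`), e.g. a published recognition-rate table whose raw
#' counts are unavailable; per-class count metrics are then omitted and the
#' weighted average requires explicit `support`.
#'
#' @param counts G x G non-negative matrix: confusion counts, or row
#'   percentages when `percent = TRUE`.
#' @param percent interpret `counts` as row percentages.
#' @param support optional per-class sample counts used for the weighted
#'   average when `percent = TRUE`.
#' @return A [ConfusionReport-class].
#' @examples
#' summarizeConfusion(diag(c(99.4, 98.0, 100, 100)) +
#'                      (1 - diag(4)) * 0, percent = TRUE)
#' @export
summarizeConfusion <- function(counts, percent = FALSE, support = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stopf("the confusion matrix must be square")
  if (anyNA(counts) || any(counts < 0))
    stopf("the confusion matrix must be non-negative and complete")
  if (is.null(rownames(counts)))
    dimnames(counts) <- list(paste0("class", seq_len(nrow(counts))),
                             paste0("class", seq_len(nrow(counts))))
  if (percent) {
    rp <- counts
    diagRates <- diag(rp)
    wavg <- if (!is.null(support))
      sum(diagRates * support) / sum(support) else NA_real_
    return(new("ConfusionReport",
               counts = matrix(numeric(0), 0, 0), rowPercent = rp,
               perClass = data.frame(), macroAverage = mean(diagRates),
               weightedAverage = wavg))
  }
  if (any(counts != round(counts)))
    stopf("confusion counts must be integers")
  if (sum(counts) == 0) stopf("the confusion matrix has no observations")
  rs <- rowSums(counts)
  rp <- counts / ifelse(rs > 0, rs, NA_real_) * 100
  diagRates <- diag(rp)
  supported <- rs > 0
  new("ConfusionReport", counts = counts, rowPercent = rp,
      perClass = .perClassMetrics(counts),
      macroAverage = mean(diagRates[supported]),
      weightedAverage = sum(diag(counts)) / sum(counts) * 100)
}

# derive the per-fold feature pipeline: eigen model + selection on the
# training rows; returns projected selected scores for train and test.
.foldFeatures <- function(Xtr, ytr, Xte, pcaK, stepControl) {
  k <- min(pcaK, nrow(Xtr) - 1L, ncol(Xtr))
  em <- fitEigenModel(Xtr, k)
  Str <- projectEigen(em, Xtr)
  Ste <- projectEigen(em, Xte)
  sel <- runStepwise(Str, ytr, stepControl)
  ids <- selectedFeatures(sel)
  if (!length(ids)) {
    # degenerate case (no feature cleared the entry threshold): fall back to
    # the leading principal component so the classifier still has an input
    ids <- 1L
  }
  list(train = Str[, ids, drop = FALSE], test = Ste[, ids, drop = FALSE],
       eigen = em, selection = sel, ids = ids)
}

#' Cross-validate the full pipeline
#'
#' For each fold, the eigenimage basis, the stepwise selection and the dense
#' network are fitted on the training folds only (unless
#' `control$eval$globalFit` is TRUE, which reproduces the leakier reading
#' where PCA and selection are fitted once on all data); the held-out fold
#' is projected and predicted, and counts are accumulated over all folds.
#'
#' @param dataset a [LabeledImageSet-class].
#' @param control a [pipelineControl()] list.
#' @param plan optional [makeFolds()] plan; built from
#'   `control$eval$folds`/`control$eval$seed` when omitted.
#' @return A [ConfusionReport-class] over all n samples.
#' @export
crossValidate <- function(dataset, control = pipelineControl(), plan = NULL) {
  stopifnot(is(dataset, "LabeledImageSet"))
  if (!inherits(control, "PipelineControl"))
    stopf("control must come from pipelineControl()")
  y <- classLabels(dataset)
  if (is.null(plan))
    plan <- makeFolds(y, control$eval$folds, control$eval$seed)
  if (length(plan$assignments) != nImages(dataset))
    stopf("fold plan covers %d samples but the dataset has %d",
          length(plan$assignments), nImages(dataset))
  if (control$preprocess$filter)
    dataset <- filterDataset(dataset, control$preprocess$filterSize)
  X <- flattenImages(dataset)
  G <- nlevels(y)
  counts <- matrix(0L, G, G, dimnames = list(levels(y), levels(y)))
  globalFeat <- NULL
  if (isTRUE(control$eval$globalFit))
    globalFeat <- .foldFeatures(X, y, X, control$pca$k, control$stepwise)
  for (f in seq_len(plan$k)) {
    tr <- plan$assignments != f
    te <- !tr
    res <- tryCatch({
      if (is.null(globalFeat)) {
        ft <- .foldFeatures(X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE],
                            control$pca$k, control$stepwise)
        Str <- ft$train; Ste <- ft$test
      } else {
        Str <- globalFeat$train[tr, , drop = FALSE]
        Ste <- globalFeat$train[te, , drop = FALSE]
      }
      mcl <- do.call(mlpControl, c(
        list(inputDim = ncol(Str), outputDim = G,
             seed = deriveSeed(plan$seed, 10L + f)),
        control$mlp))
      fit <- trainMLP(Str, y[tr], mcl)
      predict(fit$model, Ste)$class
    }, error = function(e)
      stopf("fold %d: %s", f, conditionMessage(e)))
    counts <- counts + unclass(table(y[te], res))
  }
  summarizeConfusion(counts)
}

#' Cross-validate a plug-in baseline classifier on eigenimage features
#'
#' Runs the identical cross-validation protocol with the stepwise-selection
#' and dense-network stage replaced by an adapter (the PCA features are still
#' supplied), enabling like-for-like comparisons against off-the-shelf
#' classifiers.
#'
#' @param dataset a [LabeledImageSet-class].
#' @param adapter list with elements `name`, `fit(features, labels)` and
#'   `predict(model, features)` (returning labels); see [adapterMajority()],
#'   [adapterNearestNeighbor()], [adapterRandomForest()].
#' @param control a [pipelineControl()] list (preprocess/pca/eval blocks are
#'   honored).
#' @param plan optional [makeFolds()] plan.
#' @return A [ConfusionReport-class].
#' @export
runBaseline <- function(dataset, adapter, control = pipelineControl(),
                        plan = NULL) {
  stopifnot(is(dataset, "LabeledImageSet"))
  if (!is.list(adapter) || !is.function(adapter$fit) ||
      !is.function(adapter$predict))
    stopf("adapter must provide fit() and predict() functions")
  y <- classLabels(dataset)
  if (is.null(plan))
    plan <- makeFolds(y, control$eval$folds, control$eval$seed)
  if (control$preprocess$filter)
    dataset <- filterDataset(dataset, control$preprocess$filterSize)
  X <- flattenImages(dataset)
  G <- nlevels(y)
  counts <- matrix(0L, G, G, dimnames = list(levels(y), levels(y)))
  for (f in seq_len(plan$k)) {
    tr <- plan$assignments != f
    te <- !tr
    pred <- tryCatch({
      k <- min(control$pca$k, sum(tr) - 1L, ncol(X))
      em <- fitEigenModel(X[tr, , drop = FALSE], k)
      Str <- projectEigen(em, X[tr, , drop = FALSE])
      Ste <- projectEigen(em, X[te, , drop = FALSE])
      m <- adapter$fit(Str, y[tr])
      factor(as.character(adapter$predict(m, Ste)), levels = levels(y))
    }, error = function(e)
      stopf("adapter '%s', fold %d: %s",
            if (is.null(adapter$name)) "unnamed" else adapter$name,
            f, conditionMessage(e)))
    counts <- counts + unclass(table(y[te], pred))
  }
  summarizeConfusion(counts)
}

#' Baseline adapters
#'
#' Simple classifier adapters for [runBaseline()]: a majority-class dummy, a
#' k-nearest-neighbor voter on Euclidean distance, and a random forest
#' (requires the `randomForest` package).
#'
#' @param k neighbor count for the nearest-neighbor adapter.
#' @param ... passed to `randomForest::randomForest()`.
#' @return adapter list with `name`, `fit`, `predict`.
#' @export
adapterMajority <- function() {
  list(name = "majority",
       fit = function(x, y) names(which.max(table(y))),
       predict = function(m, x) rep(m, nrow(x)))
}

#' @rdname adapterMajority
#' @export
adapterNearestNeighbor <- function(k = 1) {
  k <- assertCount(k, "k", min = 1L)
  list(name = sprintf("%d-nearest-neighbor", k),
       fit = function(x, y) list(x = x, y = as.factor(y)),
       predict = function(m, x) {
         d2 <- outer(rowSums(x^2), rowSums(m$x^2), `+`) -
           2 * tcrossprod(x, m$x)
         apply(d2, 1L, function(row) {
           nn <- order(row)[seq_len(k)]
           names(which.max(table(m$y[nn])))
         })
       })
}

#' @rdname adapterMajority
#' @export
adapterRandomForest <- function(...) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stopf("the 'randomForest' package is required for this adapter")
  args <- list(...)
  list(name = "random forest",
       fit = function(x, y)
         do.call(randomForest::randomForest,
                 c(list(x = x, y = as.factor(y)), args)),
       predict = function(m, x) as.character(predict(m, x)))
}

#' Write a confusion report as JSON and CSV
#'
#' @param report a [ConfusionReport-class].
#' @param directory output directory (created if needed).
#' @return Invisibly, `directory`. Files: `report.json` (counts, row
#'   percentages, per-class metrics, both averages), `counts.csv`,
#'   `row_percent.csv`, `per_class.csv`.
#' @export
writeReport <- function(report, directory) {
  stopifnot(is(report, "ConfusionReport"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", directory)
  jsonlite::write_json(
    list(counts = report@counts, rowPercent = report@rowPercent,
         perClass = report@perClass, macroAverage = report@macroAverage,
         weightedAverage = report@weightedAverage),
    file.path(directory, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  utils::write.csv(report@counts, file.path(directory, "counts.csv"))
  utils::write.csv(report@rowPercent, file.path(directory, "row_percent.csv"))
  utils::write.csv(report@perClass, file.path(directory, "per_class.csv"),
                   row.names = FALSE)
  invisible(directory)
}

#' Render a recognition-rate table in the conventional layout
#'
#' @param report a [ConfusionReport-class].
#' @return character vector of text lines (truth rows, prediction columns,
#'   2-decimal display rounding, trailing Average row).
#' @export
formatReport <- function(report) {
  stopifnot(is(report, "ConfusionReport"))
  rp <- round(report@rowPercent, 2)
  cls <- rownames(rp)
  wid <- max(nchar(c(cls, "Average")), 8L)
  fmt <- function(x) formatC(x, width = 9, format = "f", digits = 2)
  lines <- c(
    "Recognition Rates (%)",
    paste0(formatC("", width = wid),
           paste(formatC(cls, width = 9), collapse = "")))
  for (i in seq_along(cls))
    lines <- c(lines, paste0(formatC(cls[i], width = wid, flag = "-"),
                             paste(fmt(rp[i, ]), collapse = "")))
  c(lines, paste0(formatC("Average", width = wid, flag = "-"),
                  fmt(report@macroAverage)))
}
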