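# End-to-end orchestration: configuration, run directories, logging.

.mergeBlock <- function(defaults, user, name) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stopf("config block '%s' must be a list", name)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stopf("unknown option(s) in block '%s': %s", name,
          paste(extra, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Full-pipeline configuration
#'
#' Aggregates the per-stage parameters. Defaults are the reference,
#' full-size configuration: 128 x 128 images, 3 x 3 averaging filter, 150
#' principal components, stepwise thresholds 0.35/0.40 with a 125-feature
#' cap, a 512-unit dense network (dropout 0.5, Adam lr 0.001, batch 32, 100
#' epochs, validation split 0.25), and stratified 10-fold evaluation.
#'
#' @param preprocess list: `height`, `width`, `filter` (logical), `filterSize`.
#' @param pca list: `k` (components to retain).
#' @param stepwise a [stepwiseControl()] list.
#' @param mlp list of [mlpControl()] options excluding `inputDim`/`outputDim`
#'   (sized per run from the selected features and classes).
#' @param eval list: `folds`, `seed`, `globalFit` (fit PCA/selection once on
#'   all data instead of per training fold).
#' @return list of class `"PipelineControl"`.
#' @export
pipelineControl <- function(preprocess = list(), pca = list(),
                            stepwise = stepwiseControl(), mlp = list(),
                            eval = list()) {
  pre <- .mergeBlock(list(height = 128L, width = 128L, filter = TRUE,
                          filterSize = 3L), preprocess, "preprocess")
  pre$height <- assertCount(pre$height, "preprocess$height", 1L)
  pre$width <- assertCount(pre$width, "preprocess$width", 1L)
  pre$filter <- assertFlag(pre$filter, "preprocess$filter")
  pre$filterSize <- assertCount(pre$filterSize, "preprocess$filterSize", 1L)
  pc <- .mergeBlock(list(k = 150L), pca, "pca")
  pc$k <- assertCount(pc$k, "pca$k", 1L)
  if (!inherits(stepwise, "StepwiseControl"))
    stepwise <- do.call(stepwiseControl, stepwise)
  ml <- .mergeBlock(list(hiddenDim = 512L, dropoutRate = 0.5,
                         learningRate = 0.001, batchSize = 32L,
                         epochs = 100L, validationSplit = 0.25),
                    mlp, "mlp")
  ev <- .mergeBlock(list(folds = 10L, seed = 1L, globalFit = FALSE),
                    eval, "eval")
  ev$folds <- assertCount(ev$folds, "eval$folds", 2L)
  ev$seed <- assertCount(ev$seed, "eval$seed")
  ev$globalFit <- assertFlag(ev$globalFit, "eval$globalFit")
  structure(list(preprocess = pre, pca = pc, stepwise = stepwise,
                 mlp = ml, eval = ev),
            class = "PipelineControl")
}

#' Compact pipeline configuration for phantom studies
#'
#' The scaled-down configuration used with the 32 x 32 phantom presets
#' ([highSignalSpec()], [noSignalSpec()]): 40 principal components, default
#' stepwise thresholds, a 64-unit network trained for 40 epochs, 10-fold
#' evaluation. These sizes preserve every stage of the full method while
#' keeping a complete cross-validated run at desk scale.
#'
#' @param seed evaluation seed (drives fold shuffling and, via sub-streams,
#'   the per-fold network seeds).
#' @param folds number of cross-validation folds.
#' @return A [pipelineControl()] list.
#' @export
compactPipelineControl <- function(seed = 1, folds = 10) {
  pipelineControl(
    preprocess = list(height = 32L, width = 32L, filter = TRUE, filterSize = 3L),
    pca = list(k = 40L),
    mlp = list(hiddenDim = 64L, epochs = 40L),
    eval = list(folds = folds, seed = seed))
}

#' Hash of a resolved configuration
#'
#' Serializes the control list to canonical (name-sorted) JSON and returns
#' its MD5 digest; any parameter change changes the hash.
#'
#' @param control a [pipelineControl()] list (any serializable list works).
#' @return character MD5 hash.
#' @export
configHash <- function(control) {
  sortNames <- function(x) {
    if (is.list(x) && !is.null(names(x)))
      x <- lapply(x[order(names(x))], sortNames)
    x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(sortNames(unclass(control)), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline and write a self-describing run directory
#'
#' Resolves the input (a [synthSpec()] or a manifest path/data.frame),
#' cross-validates the full pipeline, then refits every stage on the
#' complete dataset and serializes the artifacts: resolved config with its
#' hash, cross-validation report (JSON/CSV plus a rendered text table), the
#' eigenimage model, the selection trace, the trained network and its
#' training history. Stage dimensions and timings are logged via `message()`.
#'
#' @param control a [pipelineControl()] list.
#' @param input a [synthSpec()] object, a manifest data.frame, or the path
#'   of a manifest CSV.
#' @param outputDir run directory (created if needed).
#' @return Invisibly, a list with `report` (the [ConfusionReport-class]),
#'   `dir` and `hash`.
#' @export
runPipeline <- function(control, input, outputDir) {
  if (!inherits(control, "PipelineControl"))
    stopf("control must come from pipelineControl()")
  if (!dir.exists(outputDir) &&
      !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create run directory '%s'", outputDir)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    v
  }
  dataset <- stage("input", {
    if (inherits(input, "SynthSpec")) generateDataset(input)
    else if (is(input, "LabeledImageSet")) input
    else loadDataset(input, control$preprocess$height, control$preprocess$width)
  })
  message(sprintf("dataset: %d images of %d x %d, %d classes",
                  nImages(dataset), imageDim(dataset)[1], imageDim(dataset)[2],
                  nlevels(classLabels(dataset))))
  hash <- configHash(control)
  jsonlite::write_json(c(list(configHash = hash), unclass(control)),
                       file.path(outputDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!control$preprocess$filter)
    message("averaging filter disabled by configuration; skipping")
  report <- stage("cross-validation", crossValidate(dataset, control))
  writeReport(report, outputDir)
  writeLines(formatReport(report), file.path(outputDir, "report.txt"))
  stage("final-fit", {
    ds <- if (control$preprocess$filter)
      filterDataset(dataset, control$preprocess$filterSize) else dataset
    X <- flattenImages(ds)
    y <- classLabels(ds)
    k <- min(control$pca$k, nrow(X) - 1L, ncol(X))
    em <- fitEigenModel(X, k)
    saveEigenModel(em, file.path(outputDir, "eigen_model"))
    S <- projectEigen(em, X)
    sel <- runStepwise(S, y, control$stepwise)
    saveSelection(sel, file.path(outputDir, "selection.json"))
    ids <- selectedFeatures(sel)
    if (!length(ids)) ids <- 1L
    message(sprintf("selected %d of %d features", length(ids), ncol(S)))
    mcl <- do.call(mlpControl, c(
      list(inputDim = length(ids), outputDim = nlevels(y),
           seed = deriveSeed(control$eval$seed, 99L)),
      control$mlp))
    fit <- trainMLP(S[, ids, drop = FALSE], y, mcl)
    saveMLPModel(fit$model, file.path(outputDir, "mlp_model"))
    utils::write.csv(fit$history, file.path(outputDir, "history.csv"),
                     row.names = FALSE)
  })
  invisible(list(report = report, dir = outputDir, hash = hash))
}
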