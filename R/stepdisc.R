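# Stepwise linear discriminant feature selection.
#
# Class labels are indicator-coded and regressed on the candidate features;
# a feature's contribution conditional on the already-selected set is judged
# by the partial F statistic obtained from the Wilks'-lambda ratio of
# residual scatter determinants with and without that feature. For two
# classes this reduces exactly to the squared partial t of the feature's
# regression coefficient, the classical SWLDA criterion. Forward entry
# admits the candidate with the smallest p-value below alphaEnter; backward
# elimination drops the selected feature with the largest p-value above
# alphaRemove; the two alternate until neither rule fires or the feature cap
# is reached.

#' Indicator coding of class labels
#'
#' @param labels factor of class labels.
#' @param drop if `TRUE`, return n x (G - 1) dummy coding (last level
#'   dropped), the non-degenerate response block used by the partial F
#'   machinery; if `FALSE`, the full n x G one-hot matrix.
#' @return numeric indicator matrix.
#' @export
classIndicator <- function(labels, drop = FALSE) {
  labels <- as.factor(labels)
  G <- nlevels(labels)
  Y <- matrix(0, length(labels), G,
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  if (drop) Y[, -G, drop = FALSE] else Y
}

#' Fisher-style discriminant weights by indicator least squares
#'
#' Solves the normal-equations problem `(M'M)^{-1} M'y` for each indicator
#' response column via a QR factorization. When `M'M` is singular the
#' minimum-norm pseudoinverse solution is returned and a warning is issued.
#'
#' @param features n x p feature matrix `M` (no intercept column is added).
#' @param labels a factor (expanded to a one-hot indicator response per
#'   class), or a numeric vector/matrix used directly as the response.
#' @return p x G matrix of weights, one column per response.
#' @examples
#' fldWeights(cbind(c(1, 2, 3)), c(1, 2, 3))   # single weight 1
#' @export
fldWeights <- function(features, labels) {
  M <- as.matrix(features)
  if (!is.numeric(M) || ncol(M) < 1L || nrow(M) < 1L)
    stopf("features must be a non-empty numeric matrix")
  Y <- if (is.factor(labels) || is.character(labels))
    classIndicator(as.factor(labels)) else as.matrix(labels)
  if (nrow(Y) != nrow(M))
    stopf("features and labels disagree in length")
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    warning("M'M is singular; returning the minimum-norm pseudoinverse solution")
    W <- MASS::ginv(M) %*% Y
  } else {
    W <- qr.coef(qrM, Y)
  }
  dimnames(W) <- list(colnames(M), colnames(Y))
  W
}

# Partial F of one candidate column given an already-fitted block.
# Xother: n x p0 matrix (may have 0 columns); xcand: n-vector; Y: n x m dummy
# responses (m = G - 1). An intercept is always included. Returns
# list(statistic, p.value, df1, df2).
.partialF <- function(Xother, xcand, Y, featureName = "candidate") {
  n <- nrow(Y); m <- ncol(Y)
  Z <- cbind(rep(1, n), Xother)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stopf("selected feature block is rank deficient")
  Yr <- qr.resid(qz, Y)
  xr <- qr.resid(qz, xcand)
  cx <- sum(xr^2)
  if (cx <= 1e-12 * max(sum(xcand^2), 1))
    stopf("feature %s is collinear with the selected set", featureName)
  Ered <- crossprod(Yr)
  detE <- det(Ered)
  if (!is.finite(detE) || detE <= 0)
    stopf("degenerate residual scatter when testing feature %s", featureName)
  b <- crossprod(Yr, xr)
  lam <- 1 - drop(crossprod(b, solve(Ered, b))) / cx
  lam <- min(1, max(lam, .Machine$double.xmin))
  nuE <- n - ncol(Z) - 1L          # residual df of the model with the candidate
  df2 <- nuE - m + 1L
  if (df2 < 1L)
    stopf("not enough residual degrees of freedom to test feature %s",
          featureName)
  f <- (1 - lam) / lam * df2 / m
  list(statistic = f,
       p.value = stats::pf(f, m, df2, lower.tail = FALSE),
       df1 = m, df2 = df2)
}

#' Partial F statistic of one feature conditional on a selected set
#'
#' Computes the significance of `candidate`'s contribution to the indicator
#' regression of the class labels, given the features in `selected`. The
#' statistic is identical for entry and removal tests (`mode` documents the
#' caller's intent and validates the preconditions): it compares the
#' residual scatter of the model with and without the candidate through
#' Wilks' lambda and converts it to an exact F with (G - 1, n - p - 1 -
#' (G - 1)) degrees of freedom, where p counts the model's feature columns.
#'
#' @param selected n x p0 matrix of the other selected feature columns (or
#'   `NULL` for an empty model).
#' @param candidate numeric column being tested (not among `selected`).
#' @param labels factor of class labels (all classes present).
#' @param mode `"enter"` or `"remove"`; the conditional statistic is the
#'   same in both directions.
#' @param featureName label used in error messages.
#' @return list with `statistic` (partial F), `p.value`, `df1`, `df2`.
#' @export
partialStatistic <- function(selected, candidate, labels,
                             mode = c("enter", "remove"),
                             featureName = "candidate") {
  mode <- match.arg(mode)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stopf("at least two classes are required")
  if (any(tabulate(labels, nlevels(labels)) == 0L))
    stopf("every class must be present in the training labels")
  Y <- classIndicator(labels, drop = TRUE)
  Xother <- if (is.null(selected)) NULL else as.matrix(selected)
  .partialF(Xother, as.numeric(candidate), Y, featureName)
}

#' Control parameters for stepwise selection
#'
#' Defaults follow the method's stated execution thresholds: alpha-to-enter
#' 0.35, alpha-to-remove 0.40, and a cap of 125 selected features. A more
#' conservative preset sometimes quoted for the initial model,
#' `alphaEnter = 0.15, alphaRemove = 0.2`, can be requested explicitly. The
#' constraint `alphaEnter <= alphaRemove` prevents enter/remove cycling.
#'
#' @param alphaEnter p-value below which the best candidate is admitted.
#' @param alphaRemove p-value above which the worst selected feature is
#'   dropped; must be >= `alphaEnter`.
#' @param maxFeatures cap on the number of selected features (>= 0).
#' @param maxIterations safeguard on the total number of enter/remove steps;
#'   tripping it is reported as termination reason "iteration-guard" with a
#'   warning.
#' @return list of class `"StepwiseControl"`.
#' @export
stepwiseControl <- function(alphaEnter = 0.35, alphaRemove = 0.40,
                            maxFeatures = 125, maxIterations = 1000) {
  alphaEnter <- assertNumber(alphaEnter, "alphaEnter")
  alphaRemove <- assertNumber(alphaRemove, "alphaRemove")
  if (!(alphaEnter > 0 && alphaEnter <= alphaRemove && alphaRemove < 1))
    stopf("need 0 < alphaEnter <= alphaRemove < 1 (got %g, %g)",
          alphaEnter, alphaRemove)
  structure(list(alphaEnter = alphaEnter, alphaRemove = alphaRemove,
                 maxFeatures = assertCount(maxFeatures, "maxFeatures"),
                 maxIterations = assertCount(maxIterations, "maxIterations",
                                             min = 1L)),
            class = "StepwiseControl")
}

# Vectorized forward scan: enter-mode partial F for every candidate column.
# Returns data.frame(id, statistic, p) over eligible candidates.
.forwardScan <- function(X, selected, candidates, Y) {
  n <- nrow(Y); m <- ncol(Y)
  Z <- cbind(rep(1, n), X[, selected, drop = FALSE])
  nuE <- n - ncol(Z) - 1L
  df2 <- nuE - m + 1L
  if (df2 < 1L) return(NULL)
  qz <- qr(Z)
  Yr <- qr.resid(qz, Y)
  Xr <- qr.resid(qz, X[, candidates, drop = FALSE])
  cx <- colSums(Xr^2)
  scale <- pmax(colSums(X[, candidates, drop = FALSE]^2), 1)
  ok <- cx > 1e-12 * scale
  Ered <- crossprod(Yr)
  if (!is.finite(det(Ered)) || det(Ered) <= 0) return(NULL)
  B <- crossprod(Yr, Xr)                      # m x C
  q <- colSums(B * solve(Ered, B))
  lam <- pmin(1, pmax(1 - q / cx, .Machine$double.xmin))
  f <- (1 - lam) / lam * df2 / m
  p <- stats::pf(f, m, df2, lower.tail = FALSE)
  out <- data.frame(id = candidates, statistic = f, p = p)[ok, , drop = FALSE]
  if (nrow(out)) out else NULL
}

# Vectorized backward scan: remove-mode partial F for every selected column,
# from the full model's coefficients and (Z'Z)^{-1} diagonal.
.backwardScan <- function(X, selected, Y) {
  n <- nrow(Y); m <- ncol(Y)
  Z <- cbind(rep(1, n), X[, selected, drop = FALSE])
  nuE <- n - ncol(Z)                # residual df of the model incl. feature
  df2 <- nuE - m + 1L
  if (df2 < 1L) return(NULL)
  ZtZinv <- tryCatch(chol2inv(chol(crossprod(Z))), error = function(e) NULL)
  if (is.null(ZtZinv)) return(NULL)
  coef <- ZtZinv %*% crossprod(Z, Y)
  E <- crossprod(Y - Z %*% coef)
  Einv <- tryCatch(solve(E), error = function(e) NULL)
  if (is.null(Einv)) return(NULL)
  B <- coef[-1, , drop = FALSE]               # p x m, feature rows only
  d <- diag(ZtZinv)[-1]
  tstat <- rowSums((B %*% Einv) * B) / d      # beta_i E^{-1} beta_i' / d_i
  f <- tstat * df2 / m
  p <- stats::pf(f, m, df2, lower.tail = FALSE)
  data.frame(id = selected, statistic = f, p = p)
}

#' Forward/backward stepwise discriminant feature selection
#'
#' Starting from an empty model, each iteration (a) admits the unselected
#' feature with the smallest enter-mode p-value if it is below
#' `alphaEnter` (ties broken by smaller p, then lower feature id), then (b)
#' drops the selected feature with the largest remove-mode p-value if it
#' exceeds `alphaRemove`. Iteration stops when neither rule fires
#' ("no-candidate"), when the selected set reaches `maxFeatures`
#' ("cap-reached"), or when the iteration safeguard trips
#' ("iteration-guard", with a warning). The procedure is deterministic: the
#' same inputs always reproduce the identical trace.
#'
#' @param features n x p numeric feature matrix (e.g. eigenimage scores from
#'   [projectEigen()]).
#' @param labels factor of class labels; every class must be present and
#'   n must exceed the number of classes.
#' @param control a [stepwiseControl()] list.
#' @return A [SelectionResult-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 5), 200, 5)
#' y <- factor(rep(c("a", "b"), each = 100))
#' X[, 2] <- X[, 2] + 3 * (y == "b")
#' selectedFeatures(runStepwise(X, y))
#' @export
runStepwise <- function(features, labels, control = stepwiseControl()) {
  X <- as.matrix(features)
  if (!is.numeric(X) || ncol(X) < 1L)
    stopf("at least one feature column is required")
  if (!inherits(control, "StepwiseControl"))
    stopf("control must come from stepwiseControl()")
  labels <- as.factor(labels)
  G <- nlevels(labels)
  if (G < 2L) stopf("at least two classes are required")
  if (any(tabulate(labels, G) == 0L))
    stopf("every class must be present in the training labels")
  if (nrow(X) <= G) stopf("need more samples than classes")
  Y <- classIndicator(labels, drop = TRUE)
  p <- ncol(X)
  selected <- integer(0)
  rec <- list()
  reason <- NULL
  iter <- 0L
  repeat {
    if (length(selected) >= control$maxFeatures) { reason <- "cap-reached"; break }
    iter <- iter + 1L
    if (iter > control$maxIterations) {
      warning("stepwise iteration guard tripped; selection may be incomplete")
      reason <- "iteration-guard"; break
    }
    fired <- FALSE
    candidates <- setdiff(seq_len(p), selected)
    if (length(candidates)) {
      scan <- .forwardScan(X, selected, candidates, Y)
      if (!is.null(scan)) {
        best <- scan[order(scan$p, scan$id)[1], ]
        if (best$p < control$alphaEnter) {
          selected <- c(selected, best$id)
          rec[[length(rec) + 1L]] <- list(action = "enter", feature = best$id,
                                          statistic = best$statistic,
                                          p_value = best$p)
          fired <- TRUE
        }
      }
    }
    if (length(selected)) {
      scan <- .backwardScan(X, selected, Y)
      if (!is.null(scan)) {
        worst <- scan[order(-scan$p, scan$id)[1], ]
        if (worst$p > control$alphaRemove) {
          selected <- setdiff(selected, worst$id)
          rec[[length(rec) + 1L]] <- list(action = "remove",
                                          feature = worst$id,
                                          statistic = worst$statistic,
                                          p_value = worst$p)
          fired <- TRUE
        }
      }
    }
    if (!fired) { reason <- "no-candidate"; break }
  }
  rec[[length(rec) + 1L]] <- list(action = "stop", feature = NA_integer_,
                                  statistic = NA_real_, p_value = NA_real_)
  trace <- data.frame(
    step = seq_along(rec),
    action = vapply(rec, `[[`, "", "action"),
    feature = vapply(rec, function(r) as.integer(r$feature), 1L),
    statistic = vapply(rec, function(r) as.numeric(r$statistic), 1),
    p_value = vapply(rec, function(r) as.numeric(r$p_value), 1),
    stringsAsFactors = FALSE)
  new("SelectionResult", selected = as.integer(selected), trace = trace,
      terminatedReason = reason)
}

#' Serialize a selection result to JSON
#'
#' @param result a [SelectionResult-class].
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
saveSelection <- function(result, path) {
  stopifnot(is(result, "SelectionResult"))
  jsonlite::write_json(
    list(selected = result@selected, terminatedReason = result@terminatedReason,
         trace = result@trace),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
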