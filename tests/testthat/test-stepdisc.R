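test_that("discriminant weights solve the indicator least-squares problem", {
  # identity design returns the response exactly
  M <- diag(4)
  y <- c(1, 0, 1, 0)
  expect_equal(unname(fldWeights(M, y)), unname(cbind(y)))
  # single column (1,2,3) against y = (1,2,3): (M'M)^-1 M'y = 14/14 = 1
  expect_equal(unname(fldWeights(cbind(c(1, 2, 3)), c(1, 2, 3))), cbind(1))
  # random design matches the brute-force normal equations
  withr::with_seed(20, {
    M <- matrix(rnorm(20 * 4), 20, 4)
    y <- factor(rep(c("a", "b"), 10))
    W <- fldWeights(M, y)
    Y <- classIndicator(y)
    expect_lt(max(abs(W - solve(crossprod(M), crossprod(M, Y)))), 1e-8)
  })
  # a singular design warns and returns the minimum-norm solution
  Ms <- cbind(1:4, 2 * (1:4))
  expect_warning(Wm <- fldWeights(Ms, c(1, 2, 3, 4)), "singular")
  expect_equal(unname(Wm), MASS::ginv(Ms) %*% cbind(c(1, 2, 3, 4)),
               tolerance = 1e-8)
  expect_error(fldWeights(matrix(numeric(0), 3, 0), c(1, 2, 3)), "non-empty")
})

test_that("a candidate orthogonal to the class indicator is null", {
  y <- factor(rep(c("a", "b"), 6))
  x <- rep(c(1, -1), 6) * rep(c(1, 1, -1, -1), 3)   # orthogonal to indicator
  x <- x - mean(x)
  # force exact orthogonality to the centered indicator
  ind <- classIndicator(y, drop = TRUE)[, 1]
  x <- x - sum(x * (ind - mean(ind))) / sum((ind - mean(ind))^2) * (ind - mean(ind))
  r <- partialStatistic(NULL, x, y)
  expect_lt(r$statistic, 1e-10)
  expect_gt(r$p.value, 1 - 1e-6)
})

test_that("partial F reduces to the squared OLS partial t for two classes", {
  for (s in 1:20) {
    d <- randomDesign(12, 2, 2, seed = 300 + s)
    r <- partialStatistic(d$X[, 1, drop = FALSE], d$X[, 2], d$y)
    ynum <- as.numeric(d$y == levels(d$y)[1])
    sm <- summary(stats::lm(ynum ~ d$X))
    tt <- stats::coef(sm)[3, "t value"]
    expect_lt(abs(r$statistic - tt^2), 1e-8)
    expect_lt(abs(r$p.value - stats::coef(sm)[3, "Pr(>|t|)"]), 1e-10)
  }
})

test_that("a perfectly separating candidate is overwhelmingly significant", {
  y <- factor(rep(c("a", "b"), each = 10))
  x <- as.numeric(y == "b")                     # noise-free separation
  r <- partialStatistic(NULL, x, y)
  expect_lt(r$p.value, 1e-6)
})

test_that("collinear candidates raise a named error", {
  withr::with_seed(31, {
    X <- matrix(rnorm(30), 15, 2)
    y <- factor(rep(c("a", "b", "c"), 5))
    expect_error(partialStatistic(X, X[, 1] + X[, 2], y, featureName = "PC7"),
                 "PC7")
  })
})

test_that("stepwise control enforces threshold and cap invariants", {
  ctl <- stepwiseControl()
  expect_equal(ctl$alphaEnter, 0.35)
  expect_equal(ctl$alphaRemove, 0.40)
  expect_equal(ctl$maxFeatures, 125L)
  expect_error(stepwiseControl(alphaEnter = 0.5, alphaRemove = 0.4),
               "alphaEnter <= alphaRemove")
  expect_error(stepwiseControl(alphaEnter = 0), "alphaEnter")
  expect_error(stepwiseControl(maxFeatures = -1), "maxFeatures")
})

test_that("a zero-feature cap terminates immediately as cap-reached", {
  d <- randomDesign(30, 4, 2, seed = 40)
  res <- runStepwise(d$X, d$y, stepwiseControl(maxFeatures = 0))
  expect_length(selectedFeatures(res), 0)
  expect_equal(res@terminatedReason, "cap-reached")
})

test_that("planted informative features are recovered first", {
  withr::with_seed(50, {
    n <- 200
    y <- factor(rep(c("a", "b", "c", "d"), each = n / 4))
    X <- matrix(rnorm(n * 10), n, 10)
    shift <- cbind(c(3, 0, -3, 0), c(0, 3, 0, -3))   # effect 3 sd
    X[, 1] <- X[, 1] + shift[as.integer(y), 1]
    X[, 2] <- X[, 2] + shift[as.integer(y), 2]
    res <- runStepwise(X, y, stepwiseControl(maxFeatures = 5))
    tr <- selectionTrace(res)
    entered <- tr$feature[tr$action == "enter"]
    expect_setequal(intersect(selectedFeatures(res), 1:2), 1:2)
    expect_setequal(entered[1:2], 1:2)
    # exhaustive best-pair oracle: the planted pair minimizes the joint Wilks
    Y <- classIndicator(y, drop = TRUE)
    pairs <- utils::combn(10, 2)
    wilks <- apply(pairs, 2, function(pr) {
      E1 <- crossprod(stats::resid(stats::lm(Y ~ X[, pr])))
      E0 <- crossprod(stats::resid(stats::lm(Y ~ 1)))
      det(E1) / det(E0)
    })
    expect_equal(sort(pairs[, which.min(wilks)]), c(1, 2))
  })
})

test_that("the first forward entry equals the exhaustive minimizer", {
  for (s in 1:10) {
    G <- 2 + (s %% 3)
    d <- randomDesign(60, 6, G, seed = 500 + s)
    d$X[, 3] <- d$X[, 3] + 0.7 * as.integer(d$y)   # mild signal
    res <- runStepwise(d$X, d$y, stepwiseControl(maxFeatures = 1))
    ps <- vapply(seq_len(ncol(d$X)),
                 function(j) wilksEnterOracle(NULL, d$X[, j], d$y), 1)
    first <- selectionTrace(res)$feature[1]
    expect_equal(first, which.min(ps))
  }
})

test_that("selection is deterministic and scale invariant", {
  d <- randomDesign(80, 8, 3, seed = 61)
  d$X[, 4] <- d$X[, 4] + as.integer(d$y)
  r1 <- runStepwise(d$X, d$y)
  r2 <- runStepwise(d$X, d$y)
  expect_identical(selectionTrace(r1), selectionTrace(r2))
  Xs <- d$X; Xs[, 4] <- Xs[, 4] * 1000
  r3 <- runStepwise(Xs, d$y)
  expect_identical(selectedFeatures(r3), selectedFeatures(r1))
  expect_equal(selectionTrace(r3)$p_value, selectionTrace(r1)$p_value,
               tolerance = 1e-8)
})

test_that("the iteration guard surfaces as a warning, never silently", {
  d <- randomDesign(100, 6, 3, seed = 62)
  d$X[, 1] <- d$X[, 1] + as.integer(d$y)
  d$X[, 2] <- d$X[, 2] + 2 * (d$y == levels(d$y)[1])
  expect_warning(res <- runStepwise(d$X, d$y,
                                    stepwiseControl(maxIterations = 1)),
                 "guard")
  expect_equal(res@terminatedReason, "iteration-guard")
})

test_that("enter/remove trace records honor their thresholds", {
  for (s in 1:5) {
    d <- randomDesign(70, 7, 3, seed = 700 + s)
    d$X[, 2] <- d$X[, 2] + 0.8 * as.integer(d$y)
    res <- runStepwise(d$X, d$y)
    tr <- selectionTrace(res)
    expect_true(all(tr$p_value[tr$action == "enter"] < 0.35))
    expect_true(all(tr$p_value[tr$action == "remove"] > 0.40))
    expect_false(anyDuplicated(selectedFeatures(res)) > 0)
    expect_true(res@terminatedReason %in% c("no-candidate", "cap-reached"))
  }
})

test_that("selection results serialize to JSON", {
  d <- randomDesign(40, 4, 2, seed = 80)
  res <- runStepwise(d$X, d$y)
  path <- withr::local_tempfile(fileext = ".json")
  saveSelection(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$selected, selectedFeatures(res))
  expect_equal(back$terminatedReason, res@terminatedReason)
})
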