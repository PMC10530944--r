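test_that("parameter counting follows the layer arithmetic", {
  expect_equal(countParameters(1, 1, 1), 4L)
  expect_error(countParameters(0, 1, 1), "inputDim")
  # matches a brute-force enumeration of an instantiated model's entries
  withr::with_seed(90, {
    for (rep in 1:20) {
      i <- sample(1:50, 1); h <- sample(1:50, 1); o <- sample(1:10, 1)
      m <- new("MLPModel", w1 = matrix(0, i, h), b1 = numeric(h),
               w2 = matrix(0, h, o), b2 = numeric(o),
               classNames = paste0("c", seq_len(o)), control = list())
      expect_equal(countParameters(i, h, o),
                   length(m@w1) + length(m@b1) + length(m@w2) + length(m@b2))
    }
  })
})

test_that("control defaults reproduce the reference hyperparameters", {
  ctl <- mlpControl(inputDim = 100)
  expect_equal(ctl$hiddenDim, 512L)
  expect_equal(ctl$outputDim, 4L)
  expect_equal(ctl$dropoutRate, 0.5)
  expect_equal(ctl$learningRate, 0.001)
  expect_equal(ctl$batchSize, 32L)
  expect_equal(ctl$epochs, 100L)
  expect_equal(ctl$validationSplit, 0.25)
})

# separable two-class toy reused across training tests
sepToy <- function(n = 40) {
  withr::with_seed(91, {
    y <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(rnorm(n * 2, sd = 0.3), n, 2)
    X[, 1] <- X[, 1] + ifelse(y == "b", 2, -2)
    list(X = X, y = y)
  })
}

test_that("the network fits a linearly separable toy to 100% training accuracy", {
  d <- sepToy()
  fit <- trainMLP(d$X, d$y,
                  mlpControl(2, hiddenDim = 16, outputDim = 2,
                             dropoutRate = 0.2, epochs = 200, batchSize = 8,
                             seed = 4))
  h <- fit$history
  expect_equal(nrow(h), 200L)
  expect_equal(h$accuracy[200], 1.0)
  # loss decreases overall
  expect_lt(h$loss[200], h$loss[1])
  # held-out style check: predictions on fresh separable points
  withr::with_seed(92, {
    Xnew <- matrix(rnorm(60, sd = 0.3), 30, 2)
    ynew <- factor(rep(c("a", "b"), length.out = 30), levels = c("a", "b"))
    Xnew[, 1] <- Xnew[, 1] + ifelse(ynew == "b", 2, -2)
  })
  pr <- predict(fit$model, Xnew)
  expect_gt(mean(pr$class == ynew), 0.9)
})

test_that("softmax outputs are probability rows and inference is deterministic", {
  d <- sepToy()
  fit <- trainMLP(d$X, d$y, mlpControl(2, hiddenDim = 8, outputDim = 2,
                                       epochs = 5, batchSize = 8, seed = 1))
  withr::with_seed(93, Xr <- matrix(rnorm(50), 25, 2))
  p1 <- predict(fit$model, Xr)
  p2 <- predict(fit$model, Xr)
  expect_identical(p1, p2)
  expect_lt(max(abs(rowSums(p1$prob) - 1)), 1e-6)
  expect_error(predict(fit$model, matrix(0, 3, 5)), "expects")
})

test_that("the seed fixes the trained model bit for bit", {
  d <- sepToy()
  ctl <- mlpControl(2, hiddenDim = 8, outputDim = 2, epochs = 10,
                    batchSize = 8, seed = 77)
  f1 <- trainMLP(d$X, d$y, ctl)
  f2 <- trainMLP(d$X, d$y, ctl)
  expect_identical(f1$model@w1, f2$model@w1)
  expect_identical(f1$model@w2, f2$model@w2)
  expect_identical(f1$history, f2$history)
})

test_that("the stratified split keeps every class in training; short data is rejected", {
  # a singleton class stays in the training portion even at a 50% split
  y <- factor(c("a", "a", "a", "b"))
  X <- matrix(rnorm(8), 4, 2)
  fit <- trainMLP(X, y, mlpControl(2, hiddenDim = 4, outputDim = 2,
                                   validationSplit = 0.5, batchSize = 2,
                                   epochs = 2, seed = 1))
  expect_s4_class(fit$model, "MLPModel")
  # too little data for a single batch is a validation error
  y2 <- factor(rep(c("a", "b"), each = 10))
  X2 <- matrix(rnorm(40), 20, 2)
  expect_error(trainMLP(X2, y2, mlpControl(2, hiddenDim = 4, outputDim = 2,
                                           batchSize = 64, seed = 1)),
               "batch")
})

test_that("trained networks serialize losslessly to flat text", {
  d <- sepToy()
  fit <- trainMLP(d$X, d$y, mlpControl(2, hiddenDim = 6, outputDim = 2,
                                       epochs = 3, batchSize = 8, seed = 2))
  dir <- withr::local_tempdir()
  saveMLPModel(fit$model, dir)
  back <- loadMLPModel(dir)
  expect_equal(back@w1, fit$model@w1)
  expect_equal(back@b2, fit$model@b2)
  expect_equal(back@classNames, fit$model@classNames)
  withr::with_seed(94, Xr <- matrix(rnorm(20), 10, 2))
  expect_equal(predict(back, Xr)$prob, predict(fit$model, Xr)$prob)
})
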