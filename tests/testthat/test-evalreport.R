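test_that("fold plans are stratified, disjoint and complete", {
  withr::with_seed(100, {
    y <- factor(rep(c("a", "b", "c"), times = c(33, 21, 10)))
    plan <- makeFolds(y, k = 5, seed = 3)
    expect_equal(sort(unique(plan$assignments)), 1:5)
    expect_length(plan$assignments, length(y))
    # per-fold class counts within 1 of proportionality
    for (g in levels(y)) {
      counts <- tabulate(plan$assignments[y == g], 5)
      expect_lte(diff(range(counts)), 1)
    }
  })
})

test_that("the scaled-down imbalanced design keeps every class in every training fold", {
  y <- factor(rep(c("ND", "VMD", "MID", "MD"), times = c(320, 224, 90, 8)))
  plan <- makeFolds(y, k = 10, seed = 1)
  for (f in 1:10) {
    trainClasses <- unique(y[plan$assignments != f])
    expect_setequal(as.character(trainClasses), levels(y))
  }
})

test_that("k = n produces a leave-one-out partition", {
  y <- factor(rep(c("a", "b"), each = 4))
  plan <- makeFolds(y, k = 8, seed = 2)
  expect_equal(sort(plan$assignments), 1:8)
})

test_that("fold preconditions are enforced", {
  y <- factor(c("a", "a", "b"))
  expect_error(makeFolds(y, k = 2), "fewer than 2")
  expect_error(makeFolds(factor(rep(c("a", "b"), 3)), k = 7), "exceeds")
  expect_error(makeFolds(factor(rep(c("a", "b"), 3)), k = 1), "'k'")
})

test_that("an identity counts matrix summarizes to perfection", {
  rep <- summarizeConfusion(diag(5L))
  expect_true(all(diag(rowPercent(rep)) == 100))
  expect_equal(macroAverage(rep), 100)
  expect_equal(weightedAverage(rep), 100)
  pc <- perClassMetrics(rep)
  expect_true(all(pc$sensitivity == 1))
  expect_true(all(pc$specificity == 1))
})

test_that("summaries reject degenerate matrices", {
  expect_error(summarizeConfusion(matrix(0L, 3, 3)), "no observations")
  expect_error(summarizeConfusion(matrix(-1L, 2, 2)), "non-negative")
  expect_error(summarizeConfusion(matrix(1L, 2, 3)), "square")
})

test_that("per-class metrics match hand-computed one-vs-rest tallies", {
  counts <- rbind(c(8, 2, 0),
                  c(1, 5, 1),
                  c(0, 3, 10))
  dimnames(counts) <- list(letters[1:3], letters[1:3])
  rep <- summarizeConfusion(counts)
  pc <- perClassMetrics(rep)
  expect_equal(pc$TP, c(8, 5, 10))
  expect_equal(pc$FN, c(2, 2, 3))
  expect_equal(pc$FP, c(1, 5, 1))
  expect_equal(pc$TN, c(19, 18, 16))
  expect_equal(pc$sensitivity, c(8 / 10, 5 / 7, 10 / 13))
  expect_equal(pc$specificity, c(19 / 20, 18 / 23, 16 / 17))
  expect_equal(weightedAverage(rep), 23 / 30 * 100)
})

test_that("summaries are equivariant under class permutation", {
  withr::with_seed(110, {
    counts <- matrix(rpois(16, 20), 4, 4,
                     dimnames = list(letters[1:4], letters[1:4]))
    perm <- c(3, 1, 4, 2)
    r1 <- summarizeConfusion(counts)
    r2 <- summarizeConfusion(counts[perm, perm])
    expect_equal(rowPercent(r2), rowPercent(r1)[perm, perm])
    expect_equal(macroAverage(r2), macroAverage(r1))
    expect_equal(weightedAverage(r2), weightedAverage(r1))
  })
})

test_that("percent-mode summaries carry published-table style input", {
  rp <- rbind(c(98.9, 0.6, 0.5, 0.0),
              c(3.6, 96.4, 0.0, 0.0),
              c(2.0, 1.5, 96.5, 0.0),
              c(0.0, 4.2, 4.2, 91.6))
  rep <- summarizeConfusion(rp, percent = TRUE)
  expect_equal(macroAverage(rep), 95.85)
  expect_true(is.na(weightedAverage(rep)))
  repW <- summarizeConfusion(rp, percent = TRUE,
                             support = c(3200, 2240, 896, 64))
  expect_false(is.na(weightedAverage(repW)))
})

test_that("cross-validation conserves counts and nails a separable phantom", {
  spec <- synthSpec(imageHeight = 16, imageWidth = 16,
                    classNames = c("a", "b", "c", "d"),
                    nPerClass = rep(25, 4), effectSize = 1.5, noiseSd = 0.02,
                    nSignalModes = 3, seed = 42)
  ds <- generateDataset(spec)
  ctl <- tinyControl(seed = 5)
  # limit-case capacity check: train to convergence with light regularization
  ctl$mlp$epochs <- 150L
  ctl$mlp$dropoutRate <- 0.1
  ctl$mlp$learningRate <- 0.003
  rep <- crossValidate(ds, ctl)
  expect_equal(sum(confusionCounts(rep)), nImages(ds))
  expect_gte(macroAverage(rep), 99)   # near-perfect separation by construction
})

test_that("baseline adapters run under the identical protocol", {
  spec <- synthSpec(imageHeight = 16, imageWidth = 16,
                    classNames = c("a", "b", "c", "d"),
                    nPerClass = rep(25, 4), effectSize = 2, noiseSd = 0.02,
                    nSignalModes = 3, seed = 43)
  ds <- generateDataset(spec)
  ctl <- tinyControl(seed = 6)
  maj <- runBaseline(ds, adapterMajority(), ctl)
  # balanced classes, dummy vote: accuracy sits at the 100/G chance level
  expect_lt(abs(weightedAverage(maj) - 25), 3)
  nn <- runBaseline(ds, adapterNearestNeighbor(1), ctl)
  expect_gte(macroAverage(nn), 99)
  expect_equal(sum(confusionCounts(nn)), nImages(ds))
  # adapter failures are wrapped with the adapter name
  broken <- list(name = "broken", fit = function(x, y) stop("boom"),
                 predict = function(m, x) NULL)
  expect_error(runBaseline(ds, broken, ctl), "broken")
})

test_that("reports serialize to JSON/CSV and render as a rate table", {
  counts <- matrix(c(9L, 1L, 2L, 8L), 2, 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("a", "b")))
  rep <- summarizeConfusion(counts)
  dir <- withr::local_tempdir()
  writeReport(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("report.json", "counts.csv", "row_percent.csv", "per_class.csv")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$macroAverage, macroAverage(rep))
  txt <- formatReport(rep)
  expect_match(txt[1], "Recognition Rates")
  expect_match(txt[length(txt)], "Average")
})
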