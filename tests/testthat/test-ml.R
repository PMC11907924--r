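# PLS selection, random-forest prediction, the repeated-split workflow and
# its pooled ROC summaries.

test_that("a perfectly predictive feature always earns importance 100", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(200 + s, {
      X <- matrix(rnorm(30 * 20), 30, 20,
                  dimnames = list(NULL, paste0("f", 1:20)))
      y <- rep(c("sensitive", "resistant"), each = 15)
      X[, "f1"] <- ifelse(y == "resistant", 1, -1)
      sel <- plsSelect(X, y, nComponents = 2, importanceThreshold = 75)
      sel$importance[["f1"]] == 100 && "f1" %in% sel$selected
    })
  }, logical(1))
  expect_true(all(hits))
})

test_that("constant features take importance 0 and are never selected", {
  withr::with_seed(22, {
    X <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c("sensitive", "resistant"), 10)
    X[, "f2"] <- ifelse(y == "resistant", 1, -1)  # something selectable
    X[, "f5"] <- 3
    sel <- plsSelect(X, y, importanceThreshold = 10)
    expect_equal(sel$importance[["f5"]], 0)
    expect_false("f5" %in% sel$selected)
  })
})

test_that("degenerate selection inputs raise typed errors", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(plsSelect(X, rep("resistant", 10)), "two classes")
  expect_error(plsSelect(X, rep(c("a", "b"), 5), nComponents = 20),
               "exceeds")
  yy <- rep(c("sensitive", "resistant"), 5)
  expect_error(plsSelect(matrix(1, 10, 3,
                                dimnames = list(NULL, paste0("f", 1:3))),
                         yy, importanceThreshold = 75),
               class = "phosflow_empty_selection")
})

test_that("component-1 weights agree with an independent PLS-DA fit", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(23, {
    X <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(NULL, paste0("f", 1:12)))
    y <- rep(c("sensitive", "resistant"), each = 15)
    X[, 1] <- ifelse(y == "resistant", 1, -1) + rnorm(30, sd = 0.5)
    X[, 2] <- ifelse(y == "resistant", 1, -1) + rnorm(30, sd = 0.8)
  })
  Xs <- scale(X)
  fit <- phosflow:::.plsFit(Xs, as.numeric(y == "resistant"), 2)
  ref <- mixOmics::plsda(X, factor(y), ncomp = 2)
  w1 <- fit$W[, 1]
  r1 <- ref$loadings$X[, 1]
  expect_gt(abs(cor(w1, r1)), 0.99)
})

test_that("random-forest probabilities are vote fractions of resistant", {
  withr::with_seed(24, {
    Xtr <- matrix(rnorm(20 * 3), 20, 3,
                  dimnames = list(paste0("tr", 1:20), paste0("f", 1:3)))
    y <- rep(c("sensitive", "resistant"), each = 10)
    Xtr[, 1] <- ifelse(y == "resistant", 2, -2) + rnorm(20, sd = 0.2)
    Xte <- Xtr[c(1, 11), , drop = FALSE]
    rownames(Xte) <- c("teS", "teR")
  })
  p <- fitRfPredict(Xtr, y, Xte, nTrees = 200, seed = 3)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(p[["teS"]], 0.5)
  expect_gt(p[["teR"]], 0.5)
  # single tree shown a training point memorizes its class
  p1 <- fitRfPredict(Xtr, y, Xtr["tr11", , drop = FALSE], nTrees = 1,
                     seed = 5)
  expect_true(p1 %in% c(0, 1))
  expect_error(fitRfPredict(Xtr[, 0], y, Xte[, 0]), "empty")
})

test_that("held-out resistant samples score above 0.5 on separable data", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      X <- matrix(rnorm(24 * 5), 24, 5,
                  dimnames = list(paste0("s", 1:24), paste0("f", 1:5)))
      y <- rep(c("sensitive", "resistant"), each = 12)
      X[, 1] <- ifelse(y == "resistant", 2, -2)
      test <- c(3, 15)
      p <- fitRfPredict(X[-test, ], y[-test], X[test, , drop = FALSE],
                        nTrees = 100, seed = s)
      p[[2]] > 0.5
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the repeated-split workflow is deterministic and well-formed", {
  led1 <- makeSmallLedger(seed = 7)
  led2 <- makeSmallLedger(seed = 7)
  expect_identical(ledgerCycles(led1), ledgerCycles(led2))
  expect_identical(ledgerLabels(led1), ledgerLabels(led2))

  for (cy in ledgerCycles(led1)) {
    expect_length(intersect(cy$train, cy$test), 0L)
    expect_setequal(c(cy$train, cy$test), ledgerLabels(led1)$sample)
    expect_true(all(cy$prob >= 0 & cy$prob <= 1))
    thr <- led1@params$importanceThreshold
    expect_true(all(cy$importance[cy$selected] > thr))
  }
})

test_that("all samples are eventually held out across many cycles", {
  cohort <- simulateCohort(36, 80, 5, effectSdUnits = 2, seed = 31)
  led <- repeatedSplitWorkflow(
    t(log2(SummarizedExperiment::assay(cohort$sites))),
    cohort$sensitivity, nCycles = 50, nTrain = 27, nTrees = 20,
    masterSeed = 31)
  tested <- unique(unlist(lapply(ledgerCycles(led), `[[`, "test")))
  expect_setequal(tested, names(cohort$sensitivity))
})

test_that("pooled AUC equals the all-pairs concordance oracle exactly", {
  led <- makeSmallLedger(seed = 9, nCycles = 6, nTrees = 25)
  roc <- rocFromLedger(led)
  lab <- setNames(as.character(ledgerLabels(led)$class),
                  ledgerLabels(led)$sample)
  oracle <- concordanceOracle(roc$pooled$prob,
                              lab[roc$pooled$sample] == "resistant")
  expect_equal(roc$auc, oracle, tolerance = 1e-12)
  # vote fractions over 25 trees guarantee ties in the pooled pool
  expect_gt(sum(duplicated(roc$pooled$prob)), 0)

  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(
    response = lab[roc$pooled$sample], predictor = roc$pooled$prob,
    levels = c("sensitive", "resistant"), direction = "<", quiet = TRUE))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("the ROC staircase is monotone and perfect ranking gives AUC 1", {
  led <- makeSmallLedger(seed = 12, nCycles = 5, nTrees = 40)
  # overwrite probabilities with a perfect ranking
  lab <- setNames(as.character(ledgerLabels(led)$class),
                  ledgerLabels(led)$sample)
  led@cycles <- lapply(ledgerCycles(led), function(cy) {
    cy$prob <- setNames(ifelse(lab[cy$test] == "resistant", 0.9, 0.1),
                        cy$test)
    cy
  })
  roc <- rocFromLedger(led)
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$roc$sensitivity) >= 0))
  expect_true(all(diff(roc$roc$specificity) <= 0))
})

test_that("AUC is invariant under strictly increasing probability maps", {
  led <- makeSmallLedger(seed = 13, nCycles = 5, nTrees = 30)
  base <- rocFromLedger(led)$auc
  led@cycles <- lapply(ledgerCycles(led), function(cy) {
    cy$prob <- cy$prob^3
    cy
  })
  expect_equal(rocFromLedger(led)$auc, base, tolerance = 1e-12)
})

test_that("feature frequency counts importance exceedances per cycle", {
  led <- makeSmallLedger(seed = 14, nCycles = 6, nTrees = 25)
  freq <- featureFrequency(led, importanceCutoff = 70)
  counts <- setNames(freq$count, freq$feature_id)
  cycles <- ledgerCycles(led)
  for (f in names(counts)) {
    oracle <- sum(vapply(cycles, function(cy)
      isTRUE(cy$importance[[f]] > 70), logical(1)))
    expect_identical(unname(counts[[f]]), oracle)
  }
  expect_true(all(diff(freq$count) <= 0))
  # a feature below the cutoff everywhere keeps count 0
  expect_true(any(freq$count == 0L))
})

test_that("ledger serialization round-trips to identical ROC output", {
  led <- makeSmallLedger(seed = 15, nCycles = 5, nTrees = 30)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLedger(led, path)
  back <- readLedger(path)
  expect_identical(rocFromLedger(back), rocFromLedger(led))
  expect_identical(featureFrequency(back), featureFrequency(led))
})

test_that("removing the top-frequency feature does not improve the AUC", {
  cohort <- simulateCohort(30, 120, 4, effectSdUnits = 2, seed = 41)
  X <- t(log2(SummarizedExperiment::assay(cohort$sites)))
  led <- repeatedSplitWorkflow(X, cohort$sensitivity, nCycles = 12,
                               nTrain = 22, nTrees = 100, masterSeed = 41)
  top <- featureFrequency(led)$feature_id[1]
  aucWith <- rocFromLedger(led)$auc
  led2 <- repeatedSplitWorkflow(X[, colnames(X) != top],
                                cohort$sensitivity, nCycles = 12,
                                nTrain = 22, nTrees = 100, masterSeed = 41)
  expect_lte(rocFromLedger(led2)$auc, aucWith + 0.02)
})
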