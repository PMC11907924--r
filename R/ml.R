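# Repeated-split classification of ex vivo drug sensitivity:
# mean-threshold labels on the full cohort, PLS-importance feature
# selection (importance scaled 0-100, selection > 75 by default), a random
# forest on the selected features, held-out probabilities of the resistant
# class pooled over cycles into one ROC.

.labelLevels <- c("sensitive", "resistant")   # "resistant" is positive

# NIPALS PLS1 on standardized X against the centred 0/1 class indicator.
# Returns the loading-weight matrix W (p x A) and the per-component
# inner regression weights b.
.plsFit <- function(Xs, y01, nComponents) {
  E <- Xs
  f <- y01 - mean(y01)
  p <- ncol(Xs)
  W <- matrix(0, p, nComponents)
  b <- numeric(nComponents)
  used <- 0L
  for (k in seq_len(nComponents)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) break   # residual exhausted
    w <- w / nw
    tk <- E %*% w
    tt <- sum(tk^2)
    if (tt < .Machine$double.eps) break
    pload <- crossprod(E, tk) / tt
    b[k] <- sum(tk * f) / tt
    W[, k] <- w
    E <- E - tk %*% t(pload)
    f <- f - b[k] * tk
    used <- k
  }
  list(W = W[, seq_len(max(used, 1L)), drop = FALSE],
       b = b[seq_len(max(used, 1L))], nUsed = used)
}

#' PLS-importance feature selection
#'
#' Fits a two-class partial-least-squares discriminant model on
#' standardized training features and scores every feature by the
#' aggregated absolute contribution
#' `sum_k |loading weight_k * component regression weight_k|`, min-max
#' scaled to \[0, 100\] across features. Features with importance strictly
#' above `importanceThreshold` are selected. Zero-variance features cannot
#' be standardized, take raw importance 0 and are never selected.
#'
#' @param X numeric matrix, training samples in rows, features in columns.
#' @param y two-class labels (`sensitive`/`resistant` or any 2-level
#'   factor), one per row of `X`; both classes must be present.
#' @param nComponents latent components (default 2); must be at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param importanceThreshold selection cutoff on the 0-100 scale
#'   (default 75).
#' @return list with `importance` (named numeric, all features, 0-100),
#'   `selected` (character, features above the threshold) and
#'   `nComponents` (components actually extracted). When no feature
#'   exceeds the threshold an error of class
#'   `phosflow_empty_selection` is raised.
#' @examples
#' X <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(NULL, paste0("f", 1:10)))
#' y <- rep(c("sensitive", "resistant"), each = 10)
#' X[, 1] <- ifelse(y == "resistant", 1, -1) + rnorm(20, sd = 0.1)
#' plsSelect(X, y, importanceThreshold = 50)$selected
#' @export
plsSelect <- function(X, y, nComponents = 2, importanceThreshold = 75) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("feat%05d", seq_len(ncol(X)))
  y <- factor(as.character(y))
  if (nlevels(y) != 2L)
    stop("'y' must contain exactly two classes", call. = FALSE)
  if (length(y) != nrow(X))
    stop("'y' must have one label per row of 'X'", call. = FALSE)
  nComponents <- .checkCount(nComponents, "nComponents")
  if (nComponents > min(nrow(X) - 1L, ncol(X)))
    stop("'nComponents' exceeds what the training data can support",
         call. = FALSE)
  if (importanceThreshold < 0 || importanceThreshold > 100)
    stop("'importanceThreshold' must be in [0, 100]", call. = FALSE)
  mu <- colMeans(X)
  sds <- apply(X, 2L, sd)
  ok <- sds > 0 & !is.na(sds)
  raw <- setNames(numeric(ncol(X)), colnames(X))
  posLevel <- if ("resistant" %in% levels(y)) "resistant" else levels(y)[2L]
  if (any(ok)) {
    Xs <- scale(X[, ok, drop = FALSE], center = mu[ok], scale = sds[ok])
    fit <- .plsFit(Xs, as.numeric(y == posLevel), nComponents)
    raw[ok] <- as.numeric(abs(fit$W) %*% abs(fit$b))
    nUsed <- fit$nUsed
  } else nUsed <- 0L
  rng <- range(raw)
  importance <- if (diff(rng) > 0) (raw - rng[1L]) / diff(rng) * 100
                else raw * 0
  selected <- names(importance)[importance > importanceThreshold]
  if (!length(selected))
    stop(errorCondition("no feature exceeds the importance threshold",
                        class = "phosflow_empty_selection"))
  list(importance = importance, selected = selected, nComponents = nUsed)
}

#' Random-forest classification of held-out samples
#'
#' Fits a random forest on the selected training features and returns, for
#' every test sample, the fraction of trees voting for the resistant
#' class. The class orientation is fixed: `resistant` is the positive
#' class throughout the package.
#'
#' @param XTrain,XTest numeric matrices with identical feature columns.
#' @param yTrain labels for the training rows; both classes required.
#' @param nTrees number of trees (default 500).
#' @param seed integer seed making the forest deterministic.
#' @param mtry variables tried per split; default `floor(sqrt(p))`.
#' @return named numeric, probability of `resistant` per test sample.
#' @export
fitRfPredict <- function(XTrain, yTrain, XTest, nTrees = 500, seed = 1,
                         mtry = NULL) {
  XTrain <- as.matrix(XTrain); XTest <- as.matrix(XTest)
  if (ncol(XTrain) == 0L)
    stop("the selected feature set is empty", call. = FALSE)
  if (!identical(colnames(XTrain), colnames(XTest)))
    stop("train and test feature columns must match", call. = FALSE)
  y <- factor(as.character(yTrain), levels = .labelLevels)
  if (anyNA(y)) y <- factor(as.character(yTrain))
  if (nlevels(droplevels(y)) != 2L)
    stop("'yTrain' must contain both classes", call. = FALSE)
  posLevel <- if ("resistant" %in% levels(y)) "resistant" else levels(y)[2L]
  nTrees <- .checkCount(nTrees, "nTrees")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(XTrain))))
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = XTrain, y = y, ntree = nTrees,
                               mtry = min(mtry, ncol(XTrain))))
  prob <- predict(fit, XTest, type = "prob")[, posLevel]
  setNames(as.numeric(prob), rownames(XTest))
}

#' Repeated random-split PLS + random-forest workflow
#'
#' Labels the full cohort once at the mean of the sensitivity metric, then
#' for each cycle draws a uniform random train/test partition (re-drawn,
#' with a count, when the training set is single-class), selects features
#' with [plsSelect()] and scores the held-out samples with
#' [fitRfPredict()]. Per-cycle seeds are `masterSeed + cycle`, making the
#' whole run reproducible. Cycles where no feature passes the selection
#' threshold are recorded as failed.
#'
#' @param X numeric matrix, samples in rows and features in columns
#'   (e.g. `t(log2(assay(siteQuant)))`).
#' @param sensitivity named numeric metric per sample (row of `X`).
#' @param nCycles modelling cycles (default 50).
#' @param nTrain training-set size (default 27, leaving 9 of a 36-sample
#'   cohort for testing).
#' @param nComponents PLS components (default 2).
#' @param importanceThreshold selection cutoff (default 75).
#' @param nTrees random-forest trees (default 500).
#' @param masterSeed integer master seed.
#' @param labelMode `"cohort"` (default; threshold from the full cohort)
#'   or `"training"` (threshold recomputed from each training set, which
#'   avoids the mild information leakage of the cohort-wide threshold).
#' @return An [MLRunLedger-class].
#' @seealso [rocFromLedger()], [featureFrequency()], [writeLedger()]
#' @export
repeatedSplitWorkflow <- function(X, sensitivity, nCycles = 50, nTrain = 27,
                                  nComponents = 2, importanceThreshold = 75,
                                  nTrees = 500, masterSeed = 1,
                                  labelMode = c("cohort", "training")) {
  X <- as.matrix(X)
  labelMode <- match.arg(labelMode)
  if (is.null(rownames(X)))
    stop("'X' must have sample rownames", call. = FALSE)
  sensitivity <- sensitivity[rownames(X)]
  if (anyNA(sensitivity))
    stop("'sensitivity' must cover every sample in 'X'", call. = FALSE)
  nCycles <- .checkCount(nCycles, "nCycles")
  nTrain <- .checkCount(nTrain, "nTrain", min = 4L)
  n <- nrow(X)
  if (nTrain >= n)
    stop("'nTrain' must be smaller than the cohort size", call. = FALSE)
  labels <- classifySensitivity(sensitivity)
  y <- setNames(labels$class, labels$sample)
  if (any(table(y) < 2L))
    stop("cohort needs at least 2 samples of each class", call. = FALSE)
  cycles <- vector("list", nCycles)
  for (i in seq_len(nCycles)) {
    cycleSeed <- masterSeed + i
    cycles[[i]] <- withr::with_seed(cycleSeed, {
      redraws <- 0L
      repeat {
        train <- sort(sample.int(n, nTrain))
        yTr <- if (labelMode == "cohort") y[rownames(X)[train]] else
          setNames(classifySensitivity(sensitivity[rownames(X)[train]])$class,
                   rownames(X)[train])
        if (nlevels(droplevels(yTr)) == 2L) break
        redraws <- redraws + 1L
        if (redraws > 1000L)
          stop("could not draw a two-class training set", call. = FALSE)
      }
      test <- setdiff(seq_len(n), train)
      sel <- tryCatch(
        plsSelect(X[train, , drop = FALSE], yTr, nComponents,
                  importanceThreshold),
        phosflow_empty_selection = function(e) NULL)
      rec <- list(cycle = i, seed = cycleSeed,
                  train = rownames(X)[train], test = rownames(X)[test],
                  redraws = redraws)
      if (is.null(sel)) {
        rec$failed <- TRUE
        rec$importance <- numeric()
        rec$selected <- character()
        rec$prob <- numeric()
      } else {
        prob <- fitRfPredict(X[train, sel$selected, drop = FALSE], yTr,
                             X[test, sel$selected, drop = FALSE],
                             nTrees = nTrees, seed = cycleSeed)
        rec$failed <- FALSE
        rec$importance <- sel$importance
        rec$selected <- sel$selected
        rec$prob <- prob
      }
      rec
    })
  }
  nFailed <- sum(vapply(cycles, `[[`, logical(1), "failed"))
  if (nFailed)
    message(sprintf("%d of %d cycle(s) failed feature selection", nFailed,
                    nCycles))
  methods::new("MLRunLedger", cycles = cycles,
               labels = labels,
               params = list(nCycles = nCycles, nTrain = nTrain,
                             nTest = n - nTrain, nComponents = nComponents,
                             importanceThreshold = importanceThreshold,
                             nTrees = nTrees, masterSeed = masterSeed,
                             labelMode = labelMode))
}

#' Pooled ROC curve and AUC from a run ledger
#'
#' Pools every (held-out probability, true label) pair across cycles,
#' sweeps the observed probabilities as thresholds (a sample is called
#' resistant when its probability is at least the threshold) and reports
#' sensitivity/specificity per threshold, the trapezoidal AUC -- which
#' equals the Mann-Whitney concordance with ties counted 1/2 -- and the
#' per-sample mean probability across the cycles that held the sample out.
#'
#' @param ledger an [MLRunLedger-class].
#' @param labels optional label data.frame as in [classifySensitivity()];
#'   defaults to the labels stored in the ledger.
#' @return list with `roc` (data.frame `threshold`, `sensitivity`,
#'   `specificity`), `auc`, `pooled` (data.frame `sample`, `cycle`,
#'   `prob`, `class`) and `perSampleMeanProb` (named numeric).
#' @export
rocFromLedger <- function(ledger, labels = NULL) {
  stopifnot(methods::is(ledger, "MLRunLedger"))
  if (is.null(labels)) labels <- ledgerLabels(ledger)
  lab <- setNames(as.character(labels$class), labels$sample)
  cycles <- Filter(function(cy) !isTRUE(cy$failed), ledgerCycles(ledger))
  if (!length(cycles)) stop("ledger has no successful cycles", call. = FALSE)
  pooled <- do.call(rbind, lapply(cycles, function(cy)
    data.frame(sample = names(cy$prob), cycle = cy$cycle,
               prob = as.numeric(cy$prob),
               class = lab[names(cy$prob)], row.names = NULL)))
  pos <- pooled$class == "resistant"
  if (!any(pos) || all(pos))
    stop("pooled predictions contain a single class only", call. = FALSE)
  thr <- sort(unique(pooled$prob), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(pooled$prob[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(pooled$prob[!pos] < t), numeric(1))
  fpr <- c(0, 1 - spec)
  tpr <- c(0, sens)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  meanProb <- tapply(pooled$prob, pooled$sample, mean)
  list(roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
       auc = as.numeric(auc),
       pooled = pooled,
       perSampleMeanProb = setNames(as.numeric(meanProb), names(meanProb)))
}

#' Cross-cycle feature selection frequency
#'
#' Counts, per feature, the cycles in which its PLS importance exceeded
#' `importanceCutoff`. The default cutoff of 70 is the frequency-reporting
#' threshold and is deliberately distinct from the stricter selection
#' threshold (75) used when building the models.
#'
#' @param ledger an [MLRunLedger-class].
#' @param importanceCutoff importance cutoff on the 0-100 scale.
#' @return data.frame `feature_id`, `count`, sorted by decreasing count;
#'   features never exceeding the cutoff have count 0.
#' @export
featureFrequency <- function(ledger, importanceCutoff = 70) {
  stopifnot(methods::is(ledger, "MLRunLedger"))
  cycles <- Filter(function(cy) !isTRUE(cy$failed), ledgerCycles(ledger))
  if (!length(cycles)) stop("ledger has no successful cycles", call. = FALSE)
  feats <- unique(unlist(lapply(cycles, function(cy) names(cy$importance))))
  counts <- setNames(integer(length(feats)), feats)
  for (cy in cycles) {
    hit <- names(cy$importance)[cy$importance > importanceCutoff]
    counts[hit] <- counts[hit] + 1L
  }
  ord <- order(-counts, names(counts))
  data.frame(feature_id = names(counts)[ord],
             count = as.integer(counts[ord]), row.names = NULL)
}

#' Serialize / restore a run ledger as JSON lines
#'
#' `writeLedger()` writes one JSON object per line: a header record with
#' the cohort labels and run parameters, then one record per cycle at full
#' numeric precision, so a reloaded ledger reproduces downstream ROC
#' results bitwise. `readLedger()` restores the [MLRunLedger-class].
#'
#' @param ledger an [MLRunLedger-class].
#' @param path file path.
#' @return `writeLedger()` returns `path` invisibly; `readLedger()` the
#'   restored ledger.
#' @export
writeLedger <- function(ledger, path) {
  stopifnot(methods::is(ledger, "MLRunLedger"))
  header <- list(type = "header",
                 labels = list(sample = ledgerLabels(ledger)$sample,
                               value = ledgerLabels(ledger)$value,
                               class = as.character(ledgerLabels(ledger)$class),
                               threshold = attr(ledgerLabels(ledger),
                                                "threshold")),
                 params = ledger@params)
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)),
             vapply(ledgerCycles(ledger), function(cy) {
               cy$type <- "cycle"
               # named numerics must become objects, not bare arrays
               cy$importance <- as.list(cy$importance)
               cy$prob <- as.list(cy$prob)
               as.character(jsonlite::toJSON(cy, auto_unbox = TRUE,
                                             digits = I(17)))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeLedger
#' @export
readLedger <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  types <- vapply(recs, `[[`, character(1), "type")
  header <- recs[[which(types == "header")[1L]]]
  labels <- data.frame(sample = header$labels$sample,
                       value = header$labels$value,
                       class = factor(header$labels$class,
                                      levels = .labelLevels),
                       row.names = NULL)
  attr(labels, "threshold") <- header$labels$threshold
  cycles <- lapply(recs[types == "cycle"], function(cy) {
    cy$type <- NULL
    cy$importance <- unlist(cy$importance) %||% numeric()
    cy$prob <- unlist(cy$prob) %||% numeric()
    cy$selected <- as.character(unlist(cy$selected) %||% character())
    cy
  })
  methods::new("MLRunLedger", cycles = cycles, labels = labels,
               params = header$params)
}
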