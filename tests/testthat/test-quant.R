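# Quantification post-processing: every operation is checked against a
# direct recomputation oracle on both hand-built and randomized tables.

test_that("total normalization divides by per-sample quantified sums", {
  p <- makeToyPeptides(cbind(s1 = c(2, 3, 5)))
  expect_equal(unname(SummarizedExperiment::assay(normalizeTotal(p))[, 1]),
               c(0.2, 0.3, 0.5))

  p2 <- makeToyPeptides(cbind(s1 = c(4, NA, 6)))
  n2 <- SummarizedExperiment::assay(normalizeTotal(p2))[, 1]
  expect_equal(unname(n2), c(0.4, NA, 0.6))

  r <- randomPeptides(200, 8, missingRate = 0.2)
  nr <- normalizeTotal(r)
  expect_true(isNormalized(nr))
  sums <- colSums(SummarizedExperiment::assay(nr), na.rm = TRUE)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("renormalizing an already-normalized table is a no-op", {
  nr <- normalizeTotal(randomPeptides(100, 5, missingRate = 0.1))
  twice <- normalizeTotal(nr)
  d <- abs(SummarizedExperiment::assay(twice) -
             SummarizedExperiment::assay(nr))
  expect_lt(max(d, na.rm = TRUE), 1e-12)
})

test_that("a sample without quantified intensities is rejected by name", {
  m <- cbind(s1 = c(1, 2), bad = c(NA_real_, NA_real_))
  expect_error(normalizeTotal(makeToyPeptides(m)), "bad")
})

test_that("imputation fills missing cells with row minimum over 10", {
  p <- makeToyPeptides(cbind(s1 = 0.10, s2 = NA_real_, s3 = 0.50))
  S4Vectors::metadata(p)$normalized <- TRUE
  expect_equal(unname(SummarizedExperiment::assay(imputeMissing(p))[1, ]),
               c(0.10, 0.01, 0.50))

  complete <- makeToyPeptides(matrix(1:6 / 10, 2, 3))
  S4Vectors::metadata(complete)$normalized <- TRUE
  expect_equal(SummarizedExperiment::assay(imputeMissing(complete)),
               SummarizedExperiment::assay(complete))

  r <- normalizeTotal(randomPeptides(300, 6, missingRate = 0.2))
  m <- SummarizedExperiment::assay(r)
  imp <- SummarizedExperiment::assay(imputeMissing(r))
  expect_false(anyNA(imp))
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (any(miss))
      expect_equal(unname(imp[i, miss]),
                   rep(min(m[i, !miss]) / 10, sum(miss)))
    expect_equal(imp[i, !miss], m[i, !miss])
  }
})

test_that("fully-missing peptide ions are dropped with a warning", {
  m <- rbind(a = c(1, 2), b = c(NA_real_, NA_real_))
  colnames(m) <- c("s1", "s2")
  p <- makeToyPeptides(m)
  S4Vectors::metadata(p)$normalized <- TRUE
  expect_warning(out <- imputeMissing(p), "no quantified value")
  expect_equal(nrow(out), 1L)
})

test_that("technical replicate averaging matches the arithmetic mean", {
  p <- makeToyPeptides(cbind(a1 = 0.2, a2 = 0.4))
  avg <- averageTechnicalReplicates(p, c(a1 = "A", a2 = "A"))
  expect_equal(unname(SummarizedExperiment::assay(avg)[1, ]), 0.3)

  solo <- makeToyPeptides(cbind(a1 = c(1, 2), b1 = c(3, 4)))
  out <- averageTechnicalReplicates(solo, c(a1 = "A", b1 = "B"))
  expect_equal(unname(SummarizedExperiment::assay(out)),
               unname(SummarizedExperiment::assay(solo)))

  r <- randomPeptides(50, 3, missingRate = 0)
  map <- setNames(rep("bio1", 3), colnames(r))
  m3 <- SummarizedExperiment::assay(averageTechnicalReplicates(r, map))
  expect_equal(unname(m3[, 1]),
               unname(rowMeans(SummarizedExperiment::assay(r))))

  expect_error(averageTechnicalReplicates(r, c(s1 = "A")), "missing from")
})

test_that("site roll-up sums all ions carrying a site", {
  p <- makeToyPeptides(cbind(s1 = c(5, 7)),
                       sites = c("PAK1(S144)", "PAK1(S144)"))
  expect_equal(unname(SummarizedExperiment::assay(rollupSites(p))[1, 1]), 12)

  multi <- makeToyPeptides(cbind(s1 = 4), sites = "PAK1(S144);PAK1(T146)")
  pp <- SummarizedExperiment::assay(rollupSites(multi))
  expect_equal(unname(pp[, 1]), c(4, 4))
  expect_setequal(rownames(pp), c("PAK1(S144)", "PAK1(T146)"))

  bare <- makeToyPeptides(cbind(s1 = c(1, 2)))
  expect_warning(empty <- rollupSites(bare), "no peptide ion")
  expect_equal(nrow(empty), 0L)
})

test_that("random roll-ups equal brute-force accumulation oracles", {
  r <- imputeMissing(normalizeTotal(randomPeptides(200, 8, 0.2)))
  m <- SummarizedExperiment::assay(r)
  rd <- SummarizedExperiment::rowData(r)

  pp <- SummarizedExperiment::assay(rollupSites(r))
  siteList <- strsplit(rd$sites, ";", fixed = TRUE)
  allSites <- sort(unique(unlist(siteList)))
  oracle <- matrix(0, length(allSites), ncol(m),
                   dimnames = list(allSites, colnames(m)))
  for (i in seq_len(nrow(m)))
    for (s in siteList[[i]])
      if (nzchar(s)) oracle[s, ] <- oracle[s, ] + m[i, ]
  expect_equal(pp, oracle[rownames(pp), ], tolerance = 1e-12)

  pr <- SummarizedExperiment::assay(rollupProteins(r))
  prOracle <- matrix(0, length(unique(rd$protein)), ncol(m),
                     dimnames = list(sort(unique(rd$protein)), colnames(m)))
  for (i in seq_len(nrow(m)))
    prOracle[rd$protein[i], ] <- prOracle[rd$protein[i], ] + m[i, ]
  expect_equal(pr, prOracle[rownames(pr), ], tolerance = 1e-12)

  # conservation: protein totals equal the peptide totals per sample
  expect_equal(colSums(pr), colSums(m), tolerance = 1e-12)
})

test_that("protein roll-up of single-peptide proteins is the identity", {
  p <- makeToyPeptides(cbind(s1 = c(1, 2, 3)), protein = c("A", "A", "B"))
  pr <- SummarizedExperiment::assay(rollupProteins(p))
  expect_equal(unname(pr[, 1]), c(3, 3))
})

test_that("differential statistics match the reference t implementation", {
  withr::with_seed(21, {
    m <- matrix(2^rnorm(30 * 8, 20, 1), 30, 8,
                dimnames = list(paste0("f", 1:30), paste0("s", 1:8)))
  })
  grp <- rep(c("control", "treated"), each = 4)

  res <- differentialTest(m, grp)
  for (i in seq_len(nrow(m))) {
    ref <- t.test(log2(m[i, 5:8]), log2(m[i, 1:4]), var.equal = TRUE)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(res$log2fc[i],
                 mean(log2(m[i, 5:8])) - mean(log2(m[i, 1:4])),
                 tolerance = 1e-12)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))

  pairing <- rep(paste0("pt", 1:4), 2)
  resP <- differentialTest(m, grp, paired = TRUE, pairing = pairing)
  for (i in seq_len(nrow(m))) {
    ref <- t.test(log2(m[i, 5:8]), log2(m[i, 1:4]), paired = TRUE)
    expect_equal(resP$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(resP$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give zero fold change and p = 1", {
  half <- matrix(2^rnorm(20, 20), 5, 4)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("f", 1:5), paste0("s", 1:8))
  res <- differentialTest(m, rep(c("control", "treated"), each = 4))
  expect_equal(res$log2fc, rep(0, 5))
  expect_equal(res$p, rep(1, 5))
  expect_true(all(sign(res$log2fc) ==
                    sign(res$mean_trt - res$mean_ctrl)))
})

test_that("invalid differential designs are rejected", {
  m <- matrix(2^rnorm(12, 20), 2, 6,
              dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_error(differentialTest(m, c("x", "x", "x", "x", "x", "y")),
               "at least 2")
  expect_error(differentialTest(m, rep(c("c", "t"), each = 3),
                                paired = TRUE,
                                pairing = c("p1", "p1", "p2", "p1", "p2",
                                            "p3")),
               "1:1 pairing")
  expect_error(differentialTest(m, rep(c("c", "t", "u"), each = 2)),
               "two groups")
})
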