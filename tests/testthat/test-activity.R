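# Set-based activity inference: degenerate cases, permutation-null
# correctness against exhaustive enumeration, and planted-signal recovery.

test_that("ksea delta is zero for degenerate contrasts", {
  fc <- setNames(rep(0, 50), paste0("f", 1:50))
  db <- SetDb(list(K1 = paste0("f", 1:10), K2 = paste0("f", 11:30)),
              source = "pSite", universe = names(fc))
  res <- ksea(fc, db, nPermutations = 50, seed = 1)
  expect_equal(res$delta, c(0, 0))

  fc2 <- setNames(rnorm(50), paste0("f", 1:50))
  whole <- SetDb(list(ALL = names(fc2)), universe = names(fc2))
  expect_equal(ksea(fc2, whole, nPermutations = 50, seed = 1)$delta, 0)
})

test_that("ksea delta is invariant to constant fold-change offsets", {
  withr::with_seed(3, fc <- setNames(rnorm(200), paste0("f", 1:200)))
  db <- SetDb(list(K1 = paste0("f", 1:15), K2 = paste0("f", 40:60)),
              universe = names(fc))
  a <- ksea(fc, db, nPermutations = 100, seed = 9)
  b <- ksea(fc + 5, db, nPermutations = 100, seed = 9)
  expect_equal(a$delta, b$delta, tolerance = 1e-12)
  expect_identical(a$p, b$p)
})

test_that("permutation p-values are reproducible, bounded and smoothed", {
  withr::with_seed(4, fc <- setNames(rnorm(100), paste0("f", 1:100)))
  db <- SetDb(list(K1 = paste0("f", 1:8)), universe = names(fc))
  a <- ksea(fc, db, nPermutations = 500, seed = 11)
  b <- ksea(fc, db, nPermutations = 500, seed = 11)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 501)
  expect_lte(a$p, 1)
})

test_that("permutation p matches exhaustive subset enumeration", {
  withr::with_seed(5, fc <- setNames(rnorm(9), paste0("f", 1:9)))
  db <- SetDb(list(K1 = c("f1", "f3", "f7")), universe = names(fc))
  m <- 3L
  delta <- mean(fc[db[["K1"]]]) - mean(fc)
  subs <- utils::combn(length(fc), m)
  nullDeltas <- apply(subs, 2, function(ix) mean(fc[ix]) - mean(fc))
  exactP <- mean(abs(nullDeltas) >= abs(delta))
  res <- ksea(fc, db, minSubstrates = 3, nPermutations = 20000, seed = 2)
  expect_equal(res$delta, delta, tolerance = 1e-12)
  expect_lt(abs(res$p - exactP), 0.02)
})

test_that("undersized sets are skipped with a note", {
  fc <- setNames(rnorm(20), paste0("f", 1:20))
  db <- SetDb(list(big = paste0("f", 1:5), tiny = c("f1", "f2")),
              universe = names(fc))
  expect_message(res <- ksea(fc, db, minSubstrates = 3,
                             nPermutations = 50, seed = 1),
                 "tiny")
  expect_identical(res$set, "big")
  expect_error(ksea(numeric(0), db), "named by feature id|empty")
})

test_that("the z-test null agrees with permutation on large sets", {
  withr::with_seed(6, fc <- setNames(rnorm(2000), paste0("f", 1:2000)))
  db <- SetDb(list(K1 = paste0("f", 1:40)), universe = names(fc))
  pz <- ksea(fc, db, method = "ztest")$p
  pp <- ksea(fc, db, nPermutations = 4000, seed = 3)$p
  expect_lt(abs(pz - pp), 0.05)
})

test_that("ctam recovers a planted per-sample signature shift", {
  withr::with_seed(8, {
    prof <- matrix(rnorm(300 * 4, 0, 0.3), 300, 4,
                   dimnames = list(paste0("f", 1:300), paste0("s", 1:4)))
  })
  sig <- paste0("f", 1:25)
  prof[sig, ] <- prof[sig, ] - 2
  db <- SetDb(list(PF = sig), source = "CTAM", universe = rownames(prof))
  res <- ctamScore(prof, db, nPermutations = 200, seed = 4)
  expect_equal(nrow(res), 4L)         # one score per signature per sample
  # background mean includes the planted sites; compare to the oracle
  for (s in paste0("s", 1:4)) {
    oracle <- mean(prof[sig, s]) - mean(prof[, s])
    expect_equal(res$delta[res$sample == s], oracle, tolerance = 1e-12)
  }
  expect_true(all(abs(res$delta + 2 * (1 - 25 / 300)) < 0.3))

  disjoint <- SetDb(list(other = paste0("x", 1:10)))
  expect_message(none <- ctamScore(prof, disjoint, nPermutations = 50),
                 "skipping")
  expect_equal(nrow(none), 0L)
})

test_that("tf activity rows sum to zero and reduce to single-gene z-scores", {
  withr::with_seed(10, {
    m <- matrix(2^rnorm(30 * 6, 20, 1), 30, 6,
                dimnames = list(paste0("G", 1:30), paste0("s", 1:6)))
  })
  db <- SetDb(list(TF1 = paste0("G", 1:5), TF2 = "G9"), source = "omni")
  act <- tfActivity(m, db, minGenes = 1)
  expect_true(all(abs(rowSums(act)) < 1e-8))
  lm2 <- log2(m["G9", ])
  expect_equal(unname(act["TF2", ]),
               unname((lm2 - mean(lm2)) / sd(lm2)), tolerance = 1e-12)
  expect_identical(attr(act, "geneCount"), c(TF1 = 5L, TF2 = 1L))
})

test_that("zero-variance genes are dropped and single samples rejected", {
  m <- rbind(G1 = c(1, 1, 1), G2 = c(1, 2, 3), G3 = c(2, 1, 4))
  colnames(m) <- paste0("s", 1:3)
  db <- SetDb(list(TF = c("G1", "G2", "G3")))
  expect_message(act <- tfActivity(m, db, minGenes = 2,
                                   log2Transform = FALSE),
                 "zero variance")
  expect_identical(attr(act, "geneCount"), c(TF = 2L))
  expect_error(tfActivity(m[, 1, drop = FALSE], db), "at least 2")
})

test_that("a planted transcription factor ranks first by group mean", {
  ranksFirst <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      genes <- paste0("G", 1:200)
      m <- matrix(rnorm(200 * 10, 20, 1), 200, 10,
                  dimnames = list(genes, paste0("s", 1:10)))
      sets <- split(genes, rep(1:20, each = 10))
      names(sets) <- paste0("TF", 1:20)
      m[sets$TF1, 1:5] <- m[sets$TF1, 1:5] + 1.5
      act <- tfActivity(m, SetDb(sets), log2Transform = FALSE)
      names(which.max(rowMeans(act[, 1:5]))) == "TF1"
    })
  }, logical(1))
  expect_gte(sum(ranksFirst), 9L)
})
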