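# Fixtures built in code: small peptide tables and cohorts reused across
# test files.

makeToyPeptides <- function(intensity, sites = NULL, protein = NULL,
                            group = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("s", seq_len(ncol(intensity)))
  n <- nrow(intensity)
  if (is.null(sites)) sites <- rep("", n)
  if (is.null(protein)) protein <- ifelse(nzchar(sites),
                                          sub("\\(.*$", "", sites),
                                          paste0("P", seq_len(n)))
  cd <- if (!is.null(group))
    S4Vectors::DataFrame(group = group, row.names = colnames(intensity))
  PeptideQuant(intensity, ionId = paste0("ion", seq_len(n)),
               protein = protein, sites = sites, colData = cd)
}

randomPeptides <- function(nIons = 200, nSamples = 8, missingRate = 0.2,
                           seed = 42, multiSite = TRUE) {
  withr::with_seed(seed, {
    m <- matrix(2^rnorm(nIons * nSamples, 20, 2), nIons, nSamples,
                dimnames = list(paste0("ion", seq_len(nIons)),
                                paste0("s", seq_len(nSamples))))
    if (missingRate > 0) {
      drop <- matrix(runif(length(m)) < missingRate, nIons)
      # keep at least one observation per row so min/10 is defined
      keepCol <- sample.int(nSamples, nIons, replace = TRUE)
      drop[cbind(seq_len(nIons), keepCol)] <- FALSE
      m[drop] <- NA
    }
    prot <- paste0("P", sample.int(40, nIons, replace = TRUE))
    sites <- vapply(seq_len(nIons), function(i) {
      k <- if (multiSite) sample(0:2, 1, prob = c(0.2, 0.6, 0.2)) else 1L
      if (k == 0L) return("")
      paste(sprintf("%s(S%d)", prot[i], sample.int(500, k)), collapse = ";")
    }, character(1))
    PeptideQuant(m, ionId = rownames(m), protein = prot, sites = sites)
  })
}

# Mann-Whitney concordance with ties counted 1/2: brute-force all-pairs
# oracle for the pooled ROC AUC.
concordanceOracle <- function(prob, isPositive) {
  pos <- prob[isPositive]
  neg <- prob[!isPositive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# small ledger on a separable cohort, reused by ROC and serialization tests
makeSmallLedger <- function(seed = 7, nCycles = 8, nTrees = 60) {
  cohort <- simulateCohort(20, 60, 4, effectSdUnits = 2, seed = seed)
  X <- t(log2(SummarizedExperiment::assay(cohort$sites)))
  repeatedSplitWorkflow(X, cohort$sensitivity, nCycles = nCycles,
                        nTrain = 14, nComponents = 2,
                        importanceThreshold = 75, nTrees = nTrees,
                        masterSeed = seed)
}
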