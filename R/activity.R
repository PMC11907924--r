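# Set-based activity inference. The enrichment statistic ("delta") is the
# difference between the mean log2 fold change of a set's matched features
# and the mean over all quantified features; its null is either a
# permutation distribution over random feature draws of the same size or a
# normal approximation (z = delta * sqrt(m) / sd(all fold changes)).

.fcVector <- function(contrast) {
  if (is.numeric(contrast)) {
    if (is.null(names(contrast)))
      stop("a fold-change vector must be named by feature id", call. = FALSE)
    return(contrast)
  }
  df <- as.data.frame(contrast)
  if (!all(c("feature_id", "log2fc") %in% colnames(df)))
    stop("contrast must have 'feature_id' and 'log2fc'", call. = FALSE)
  setNames(df$log2fc, df$feature_id)
}

.enrichScores <- function(fc, setDb, minFeatures, nPermutations, seed,
                          method, what) {
  if (!length(fc)) stop("empty contrast", call. = FALSE)
  method <- match.arg(method, c("permutation", "ztest"))
  globalMean <- mean(fc)
  sets <- featureSets(setDb)
  matched <- lapply(sets, intersect, y = names(fc))
  m <- lengths(matched)
  skip <- m < minFeatures
  if (any(skip))
    message(sprintf("skipping %d %s(s) with fewer than %d matched feature(s): %s",
                    sum(skip), what, minFeatures,
                    paste(names(sets)[skip], collapse = ", ")))
  keep <- names(sets)[!skip]
  if (!length(keep))
    return(data.frame(set = character(), source = character(),
                      m = integer(), delta = numeric(), p = numeric(),
                      direction = numeric()))
  delta <- vapply(matched[keep], function(f) mean(fc[f]) - globalMean,
                  numeric(1))
  if (method == "permutation") {
    nPermutations <- .checkCount(nPermutations, "nPermutations")
    p <- rep(NA_real_, length(keep))
    names(p) <- keep
    doDraws <- function() {
      # equal-sized sets share one permutation null per contrast
      for (mm in unique(m[keep])) {
        null <- vapply(seq_len(nPermutations), function(i)
          mean(fc[sample.int(length(fc), mm)]), numeric(1)) - globalMean
        for (s in keep[m[keep] == mm])
          p[s] <<- (sum(abs(null) >= abs(delta[[s]])) + 1) /
            (nPermutations + 1)
      }
    }
    if (is.null(seed)) doDraws() else withr::with_seed(seed, doDraws())
  } else {
    z <- delta * sqrt(m[keep]) / sd(fc)
    p <- 2 * pnorm(-abs(z))
  }
  data.frame(set = keep, source = unname(setSource(setDb)[keep]),
             m = unname(m[keep]), delta = unname(delta),
             p = unname(p[keep]), direction = sign(unname(delta)),
             row.names = NULL)
}

#' Kinase-substrate enrichment analysis (KSEA)
#'
#' Scores each kinase of `setDb` on a differential contrast: `delta` is the
#' mean log2 fold change of the kinase's matched substrate sites minus the
#' mean over all quantified sites, and `p` a two-tailed permutation
#' p-value with add-one smoothing, `p = (b + 1) / (nPermutations + 1)`
#' where `b` counts random same-size draws whose `|delta|` is at least the
#' observed one. `method = "ztest"` replaces the permutation null with the
#' normal approximation.
#'
#' @param contrast a result of [differentialTest()] (or any data.frame with
#'   `feature_id` and `log2fc`, or a named numeric fold-change vector).
#' @param setDb a [SetDb-class] linking kinases to substrate site ids.
#' @param minSubstrates smallest matched substrate count scored; sets below
#'   it are skipped with a note.
#' @param nPermutations permutation draws for the null.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param method `"permutation"` (default) or `"ztest"`.
#' @return data.frame with columns `set`, `source`, `m`, `delta`, `p`,
#'   `direction`.
#' @examples
#' fc <- setNames(rnorm(100), paste0("f", 1:100))
#' db <- SetDb(list(K1 = paste0("f", 1:10)), source = "pSite",
#'             universe = names(fc))
#' ksea(fc, db, nPermutations = 200, seed = 1)
#' @export
ksea <- function(contrast, setDb, minSubstrates = 3, nPermutations = 1000,
                 seed = NULL, method = c("permutation", "ztest")) {
  stopifnot(methods::is(setDb, "SetDb"))
  .enrichScores(.fcVector(contrast), setDb,
                .checkCount(minSubstrates, "minSubstrates"),
                nPermutations, seed, match.arg(method), "set")
}

#' Compound-target activity marker (CTAM) scores
#'
#' The KSEA statistic applied to compound signatures: sets of phosphosites
#' empirically inhibited by a compound. Accepts either a differential
#' contrast (one score per signature) or a matrix of per-sample log2
#' changes (features in rows, samples in columns; one score per signature
#' and sample).
#'
#' @param x a contrast as in [ksea()], or a numeric matrix for per-sample
#'   scoring.
#' @param signatureDb a [SetDb-class] of compound target-site signatures.
#' @param minFeatures smallest matched signature size scored.
#' @inheritParams ksea
#' @return data.frame as in [ksea()]; in per-sample mode an additional
#'   `sample` column with one row per signature and sample.
#' @export
ctamScore <- function(x, signatureDb, minFeatures = 3, nPermutations = 1000,
                      seed = NULL, method = c("permutation", "ztest")) {
  stopifnot(methods::is(signatureDb, "SetDb"))
  method <- match.arg(method)
  minFeatures <- .checkCount(minFeatures, "minFeatures")
  if (is.matrix(x) || methods::is(x, "SummarizedExperiment")) {
    m <- .assayMatrix(x)
    if (is.null(rownames(m)))
      stop("per-sample profiles must have feature rownames", call. = FALSE)
    out <- lapply(colnames(m), function(s) {
      res <- .enrichScores(setNames(m[, s], rownames(m)), signatureDb,
                           minFeatures, nPermutations, seed, method,
                           "signature")
      if (nrow(res)) cbind(sample = s, res) else res
    })
    return(do.call(rbind, out[vapply(out, nrow, integer(1)) > 0]) %||%
             data.frame())
  }
  .enrichScores(.fcVector(x), signatureDb, minFeatures, nPermutations,
                seed, method, "signature")
}

#' Transcription-factor activity from target-gene z-scores
#'
#' For every gene, the (log2) protein intensity is z-scored across samples;
#' the activity of a transcription factor in a sample is the sum of the
#' z-scores of its matched target genes in that sample. Genes with zero
#' variance across samples carry no information and are dropped with a
#' note; factors with fewer than `minGenes` matched genes are skipped.
#'
#' @param x a [ProteinQuant-class] or numeric matrix (genes in rows,
#'   samples in columns); at least 2 samples.
#' @param tfDb a [SetDb-class] linking transcription factors to target
#'   genes.
#' @param minGenes smallest matched gene count scored.
#' @param log2Transform log2-transform intensities before z-scoring.
#' @return numeric matrix, factors in rows and samples in columns, with a
#'   `geneCount` attribute (matched genes per factor). Every row sums to
#'   zero across samples by construction.
#' @export
tfActivity <- function(x, tfDb, minGenes = 3, log2Transform = TRUE) {
  stopifnot(methods::is(tfDb, "SetDb"))
  minGenes <- .checkCount(minGenes, "minGenes")
  m <- .assayMatrix(x)
  if (ncol(m) < 2L)
    stop("z-scores across samples need at least 2 samples", call. = FALSE)
  if (log2Transform) {
    if (any(m <= 0, na.rm = TRUE))
      stop("non-positive intensities cannot be log2-transformed",
           call. = FALSE)
    m <- log2(m)
  }
  sds <- apply(m, 1L, sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    message(sprintf("dropping %d gene(s) with zero variance across samples",
                    sum(flat)))
    m <- m[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  z <- (m - rowMeans(m)) / sds   # sample (n - 1) standard deviation
  sets <- featureSets(tfDb)
  matched <- lapply(sets, intersect, y = rownames(z))
  keep <- lengths(matched) >= minGenes
  if (any(!keep))
    message(sprintf("skipping %d factor(s) with fewer than %d matched gene(s)",
                    sum(!keep), minGenes))
  if (!any(keep))
    return(structure(matrix(numeric(), 0, ncol(z),
                            dimnames = list(NULL, colnames(z))),
                     geneCount = integer()))
  act <- t(vapply(matched[keep], function(g)
    colSums(z[g, , drop = FALSE]), numeric(ncol(z))))
  dimnames(act) <- list(names(sets)[keep], colnames(z))
  structure(act, geneCount = setNames(lengths(matched[keep]),
                                      names(sets)[keep]))
}
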