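#' @name accessors
#' @title Accessors for phosflow classes
#' @description Small accessor generics: `featureSets()` returns the named
#'   list of member ids of a [SetDb-class]; `setSource()` its source
#'   labels; `setUniverse()` its feature universe; `isNormalized()` /
#'   `isImputed()` the processing flags of a [PeptideQuant-class];
#'   `ledgerCycles()` the per-cycle records and `ledgerLabels()` the cohort
#'   labels of an [MLRunLedger-class].
#' @param x the object.
#' @return See description; each accessor returns the corresponding slot
#'   content.
NULL

#' @rdname accessors
#' @export
setGeneric("featureSets", function(x) standardGeneric("featureSets"))
#' @rdname accessors
#' @export
setMethod("featureSets", "SetDb", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("setSource", function(x) standardGeneric("setSource"))
#' @rdname accessors
#' @export
setMethod("setSource", "SetDb", function(x) x@source)

#' @rdname accessors
#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))
#' @rdname accessors
#' @export
setMethod("setUniverse", "SetDb", function(x) {
  if (length(x@universe)) x@universe else unique(unlist(x@sets, use.names = FALSE))
})

#' @rdname accessors
#' @export
setMethod("length", "SetDb", function(x) length(x@sets))
#' @rdname accessors
#' @export
setMethod("names", "SetDb", function(x) names(x@sets))

#' @rdname accessors
#' @param i set name or index.
#' @export
setMethod("[[", "SetDb", function(x, i) x@sets[[i]])

setMethod("show", "SetDb", function(object) {
  cat(sprintf("SetDb with %d set(s) over %d feature(s)\n",
              length(object@sets), length(setUniverse(object))))
  cat("sources:", paste(unique(object@source), collapse = ", "), "\n")
  n <- min(3L, length(object@sets))
  for (nm in names(object@sets)[seq_len(n)])
    cat(sprintf("  %s [%s]: %d member(s)\n", nm, object@source[[nm]],
                length(object@sets[[nm]])))
  if (length(object@sets) > n) cat("  ...\n")
})

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "PeptideQuant", function(x)
  isTRUE(S4Vectors::metadata(x)$normalized))

#' @rdname accessors
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))
#' @rdname accessors
#' @export
setMethod("isImputed", "PeptideQuant", function(x)
  isTRUE(S4Vectors::metadata(x)$imputed))

#' @rdname accessors
#' @export
setGeneric("ledgerCycles", function(x) standardGeneric("ledgerCycles"))
#' @rdname accessors
#' @export
setMethod("ledgerCycles", "MLRunLedger", function(x) x@cycles)

#' @rdname accessors
#' @export
setGeneric("ledgerLabels", function(x) standardGeneric("ledgerLabels"))
#' @rdname accessors
#' @export
setMethod("ledgerLabels", "MLRunLedger", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("length", "MLRunLedger", function(x) length(x@cycles))

setMethod("show", "MLRunLedger", function(object) {
  nf <- sum(vapply(object@cycles, function(cy) isTRUE(cy$failed), logical(1)))
  cat(sprintf("MLRunLedger: %d cycle(s) (%d failed), cohort of %d sample(s)\n",
              length(object@cycles), nf, nrow(object@labels)))
  cat(sprintf("  split %d/%d, %d PLS component(s), selection > %s, %d tree(s)\n",
              object@params$nTrain %||% NA,
              object@params$nTest %||% NA,
              object@params$nComponents %||% NA,
              format(object@params$importanceThreshold %||% NA),
              object@params$nTrees %||% NA))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:\n")
  if (length(object@plantedKinaseShifts))
    cat("  planted kinase shifts:",
        paste(sprintf("%s=%g", names(object@plantedKinaseShifts),
                      object@plantedKinaseShifts), collapse = ", "), "\n")
  if (length(object@informativeSites))
    cat(sprintf("  %d informative site(s)\n", length(object@informativeSites)))
  if (length(object@trueSensitivity))
    cat(sprintf("  latent sensitivity for %d sample(s)\n",
                length(object@trueSensitivity)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
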