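#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays rowData colData assayNames
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm runif sd pt pnorm p.adjust cor predict setNames
#' @importFrom utils head tail write.table read.delim packageVersion
NULL

#' PeptideQuant: peptide-ion by sample intensity matrix
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"intensity"` assay (raw or normalized label-free intensities, `NA` for
#' unquantified cells) plus per-ion annotation in `rowData`: `ion_id`,
#' `sequence`, `protein` and `sites` (semicolon-separated phosphosite ids,
#' empty string for unmodified peptides). Two processing flags live in
#' `metadata()`: `normalized` and `imputed`.
#'
#' @aliases PeptideQuant-class
#' @seealso [normalizeTotal()], [imputeMissing()], [rollupSites()]
#' @export
setClass("PeptideQuant", contains = "SummarizedExperiment")

#' SiteQuant: phosphosite by sample ppIndex matrix
#'
#' SummarizedExperiment subclass with a single `"ppIndex"` assay, the summed
#' intensity of all peptide ions carrying the same modification site.
#'
#' @aliases SiteQuant-class
#' @export
setClass("SiteQuant", contains = "SummarizedExperiment")

#' ProteinQuant: protein by sample summed-intensity matrix
#'
#' SummarizedExperiment subclass with a single `"intensity"` assay, the sum
#' of all peptide-ion intensities of each protein.
#'
#' @aliases ProteinQuant-class
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

.validQuant <- function(object, assayName) {
  msg <- character()
  if (!assayName %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, sprintf("assay '%s' is required", assayName))
  else {
    a <- SummarizedExperiment::assay(object, assayName)
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
}

setValidity("PeptideQuant", function(object) {
  msg <- .validQuant(object, "intensity")
  if (!isTRUE(msg)) return(msg)
  rd <- SummarizedExperiment::rowData(object)
  need <- c("ion_id", "protein", "sites")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(sprintf("rowData is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(rd$ion_id)) return("ion ids must be unique")
  TRUE
})

setValidity("SiteQuant", function(object) .validQuant(object, "ppIndex"))
setValidity("ProteinQuant", function(object) .validQuant(object, "intensity"))

#' SetDb: named feature-set collections
#'
#' Container for GMT-style databases linking kinases to substrate
#' phosphosites, compounds to target sites, or transcription factors to
#' genes. Each set has a name, a source label (e.g. `"PDTs"`, `"pSite"`,
#' `"Signor"`) and a character vector of member feature ids. An optional
#' `universe` records the full feature id space the sets were drawn from.
#'
#' @slot sets named list of character vectors (member feature ids).
#' @slot source named character vector of source labels, one per set.
#' @slot universe character vector of all feature ids (may be empty).
#' @aliases SetDb-class
#' @seealso [readGmt()], [writeGmt()], [ksea()], [tfActivity()]
#' @export
setClass("SetDb",
  representation(sets = "list", source = "character", universe = "character"))

setValidity("SetDb", function(object) {
  msg <- character()
  if (length(object@sets) == 0L) msg <- c(msg, "at least one set is required")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)) ||
      any(!nzchar(names(object@sets))))
    msg <- c(msg, "sets must have unique non-empty names")
  if (any(lengths(object@sets) == 0L)) msg <- c(msg, "sets must be non-empty")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "set members must be character ids")
  if (length(object@source) != length(object@sets))
    msg <- c(msg, "one source label per set is required")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted parameters of a synthetic data set
#'
#' Record of what a synthetic generator planted, used to verify recovery
#' downstream. Slots not applicable to a particular generator are left
#' empty.
#'
#' @slot plantedKinaseShifts named numeric, log2 shift per planted kinase.
#' @slot informativeSites character, site ids that determine sensitivity.
#' @slot trueSensitivity named numeric, latent sensitivity per sample.
#' @slot trueLabels named character, `"sensitive"`/`"resistant"` per sample.
#' @slot trueTfActivities numeric matrix, TF by sample planted activity.
#' @slot trueAac named numeric in \[0,1\] per sample.
#' @aliases GroundTruth-class
#' @export
setClass("GroundTruth",
  representation(plantedKinaseShifts = "numeric",
                 informativeSites = "character",
                 trueSensitivity = "numeric",
                 trueLabels = "character",
                 trueTfActivities = "matrix",
                 trueAac = "numeric"),
  prototype(trueTfActivities = matrix(numeric(), 0, 0)))

#' MLRunLedger: per-cycle record of the repeated-split workflow
#'
#' One entry per modelling cycle: the train/test partition, the per-feature
#' PLS importances (0-100), the selected feature names, and the predicted
#' probability of the resistant class for every test sample. Cohort labels
#' and run parameters are stored alongside so ROC and frequency summaries
#' can be recomputed from the ledger alone.
#'
#' @slot cycles list of per-cycle records (see [repeatedSplitWorkflow()]).
#' @slot labels data.frame with columns `sample`, `value`, `class`.
#' @slot params list of run parameters (cycles, split sizes, seeds, ...).
#' @aliases MLRunLedger-class
#' @seealso [repeatedSplitWorkflow()], [rocFromLedger()], [writeLedger()]
#' @export
setClass("MLRunLedger",
  representation(cycles = "list", labels = "data.frame", params = "list"))

setValidity("MLRunLedger", function(object) {
  msg <- character()
  if (!all(c("sample", "value", "class") %in% colnames(object@labels)))
    msg <- c(msg, "labels must have columns sample, value, class")
  ok <- vapply(object@cycles, function(cy) {
    is.list(cy) && all(c("cycle", "train", "test", "failed") %in% names(cy))
  }, logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "each cycle record needs cycle, train, test, failed")
  if (length(msg)) msg else TRUE
})
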