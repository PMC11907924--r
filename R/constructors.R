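#' Construct a PeptideQuant object
#'
#' @param intensity numeric matrix, ions in rows, samples in columns;
#'   `NA` marks unquantified cells.
#' @param ionId character, unique ion ids (defaults to rownames).
#' @param protein character, protein id per ion.
#' @param sites character, semicolon-separated phosphosite ids per ion
#'   (empty string for unmodified peptides).
#' @param sequence optional character, peptide sequence per ion.
#' @param colData optional DataFrame of sample annotation (e.g. `group`).
#' @param normalized,imputed logical processing flags.
#' @return A [PeptideQuant-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 7), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("s1", "s2")))
#' PeptideQuant(m, protein = c("PAK1", "PAK1"),
#'              sites = c("PAK1(S144)", ""))
#' @export
PeptideQuant <- function(intensity, ionId = rownames(intensity),
                         protein, sites, sequence = NULL, colData = NULL,
                         normalized = FALSE, imputed = FALSE) {
  intensity <- as.matrix(intensity)
  if (is.null(ionId)) ionId <- sprintf("ion%05d", seq_len(nrow(intensity)))
  rd <- S4Vectors::DataFrame(ion_id = as.character(ionId),
                             protein = as.character(protein),
                             sites = as.character(sites))
  if (!is.null(sequence)) rd$sequence <- as.character(sequence)
  rownames(intensity) <- rd$ion_id
  args <- list(assays = list(intensity = intensity), rowData = rd,
               metadata = list(normalized = normalized, imputed = imputed))
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  methods::new("PeptideQuant", se)
}

#' Construct a SiteQuant object
#'
#' @param ppIndex numeric matrix of phosphorylation indices, sites in rows
#'   (rownames = site ids), samples in columns.
#' @param colData optional DataFrame of sample annotation.
#' @return A [SiteQuant-class] object.
#' @export
SiteQuant <- function(ppIndex, colData = NULL) {
  args <- list(assays = list(ppIndex = as.matrix(ppIndex)))
  if (!is.null(colData)) args$colData <- colData
  methods::new("SiteQuant",
               do.call(SummarizedExperiment::SummarizedExperiment, args))
}

#' Construct a ProteinQuant object
#'
#' @param intensity numeric matrix of summed protein intensities, proteins
#'   in rows (rownames = protein ids), samples in columns.
#' @param colData optional DataFrame of sample annotation.
#' @return A [ProteinQuant-class] object.
#' @export
ProteinQuant <- function(intensity, colData = NULL) {
  args <- list(assays = list(intensity = as.matrix(intensity)))
  if (!is.null(colData)) args$colData <- colData
  methods::new("ProteinQuant",
               do.call(SummarizedExperiment::SummarizedExperiment, args))
}

#' Construct a SetDb
#'
#' @param sets named list of character vectors of member feature ids.
#' @param source character source label(s), recycled to one per set.
#' @param universe optional character vector of the full feature space.
#' @return A [SetDb-class] object.
#' @examples
#' db <- SetDb(list(PAK1 = c("PAK1(S144)", "STMN1(S38)")), source = "pSite")
#' featureSets(db)
#' @export
SetDb <- function(sets, source = "custom", universe = character()) {
  source <- rep_len(as.character(source), length(sets))
  names(source) <- names(sets)
  methods::new("SetDb", sets = lapply(sets, as.character),
               source = source, universe = as.character(universe))
}
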