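# Plain-text interchange formats: TSV tables (missing = empty field) and
# GMT set files (set name, source/description, tab-separated member ids).

#' Read / write a peptide-ion quantification TSV
#'
#' Columns `ion_id`, `sequence`, `protein`, `sites` (semicolon-separated
#' site ids) followed by one column per sample; missing intensities are
#' encoded as empty fields.
#'
#' @param path file path.
#' @param x a [PeptideQuant-class].
#' @return `readPeptideTable()` returns a [PeptideQuant-class];
#'   `writePeptideTable()` returns `path` invisibly.
#' @export
readPeptideTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA,
                   na.strings = "")
  anno <- c("ion_id", "sequence", "protein", "sites")
  miss <- setdiff(c("ion_id", "protein", "sites"), colnames(df))
  if (length(miss))
    stop("peptide table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sampleCols <- setdiff(colnames(df), anno)
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  mode(m) <- "numeric"
  df$sites[is.na(df$sites)] <- ""
  PeptideQuant(m, ionId = df$ion_id, protein = df$protein, sites = df$sites,
               sequence = if ("sequence" %in% colnames(df)) df$sequence)
}

#' @rdname readPeptideTable
#' @export
writePeptideTable <- function(x, path) {
  stopifnot(methods::is(x, "PeptideQuant"))
  rd <- SummarizedExperiment::rowData(x)
  df <- data.frame(ion_id = rd$ion_id,
                   sequence = if ("sequence" %in% colnames(rd)) rd$sequence
                              else "",
                   protein = rd$protein, sites = rd$sites,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(SummarizedExperiment::assay(x, "intensity")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write a site or protein quantification TSV
#'
#' First column `site_id` (or `protein_id`), then one column per sample.
#'
#' @param path file path.
#' @param x a [SiteQuant-class] or [ProteinQuant-class].
#' @return `readSiteTable()` returns a [SiteQuant-class];
#'   `writeSiteTable()` / `writeProteinTable()` return `path` invisibly.
#' @export
readSiteTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  SiteQuant(m)
}

#' @rdname readSiteTable
#' @export
writeSiteTable <- function(x, path) {
  m <- .assayMatrix(x)
  df <- cbind(data.frame(site_id = rownames(m)), as.data.frame(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname readSiteTable
#' @export
writeProteinTable <- function(x, path) {
  m <- .assayMatrix(x)
  df <- cbind(data.frame(protein_id = rownames(m)), as.data.frame(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read / write GMT set files
#'
#' One set per line: name, source/description, then tab-separated member
#' ids.
#'
#' @param path file path.
#' @param db a [SetDb-class].
#' @param universe optional universe to attach to the read [SetDb-class].
#' @return `readGmt()` returns a [SetDb-class]; `writeGmt()` returns
#'   `path` invisibly.
#' @export
readGmt <- function(path, universe = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop(sprintf("malformed GMT line(s): %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  SetDb(sets, source = vapply(parts, `[[`, character(1), 2L),
        universe = universe)
}

#' @rdname readGmt
#' @export
writeGmt <- function(db, path) {
  stopifnot(methods::is(db, "SetDb"))
  lines <- vapply(names(db), function(nm)
    paste(c(nm, setSource(db)[[nm]], db[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential contrast as TSV
#'
#' Columns `feature_id`, `log2fc`, `t`, `p`, `q`, `mean_ctrl`, `mean_trt`.
#'
#' @param contrast a [differentialTest()] result.
#' @param path file path.
#' @return `path`, invisibly. `readContrast()` returns the data.frame.
#' @export
writeContrast <- function(contrast, path) {
  write.table(as.data.frame(contrast), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeContrast
#' @export
readContrast <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = "")
}
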