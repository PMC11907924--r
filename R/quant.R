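# Post-identification quantification processing. The intended order of
# operations mirrors the label-free workflow the package models:
# normalize -> impute -> (average technical replicates) -> roll up ->
# log2 -> differential test.

#' Normalize each sample to its total quantified intensity
#'
#' Divides every present intensity by the sum of present intensities of its
#' sample, so each sample's quantified signal sums to one. Missing cells
#' stay missing and are excluded from the totals.
#'
#' @param x a [PeptideQuant-class].
#' @return A [PeptideQuant-class] with the `normalized` flag set.
#' @examples
#' m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(NULL, "s1"))
#' p <- PeptideQuant(m, ionId = paste0("i", 1:3),
#'                   protein = rep("P1", 3), sites = rep("", 3))
#' SummarizedExperiment::assay(normalizeTotal(p))
#' @export
normalizeTotal <- function(x) {
  stopifnot(methods::is(x, "PeptideQuant"))
  m <- SummarizedExperiment::assay(x, "intensity")
  if (nrow(m) == 0L) stop("empty peptide table", call. = FALSE)
  tot <- colSums(m, na.rm = TRUE)
  none <- colSums(!is.na(m)) == 0L | tot == 0
  if (any(none))
    stop("sample(s) with no quantified intensity: ",
         paste(colnames(m)[none], collapse = ", "), call. = FALSE)
  SummarizedExperiment::assay(x, "intensity") <- sweep(m, 2L, tot, `/`)
  S4Vectors::metadata(x)$normalized <- TRUE
  methods::validObject(x)
  x
}

#' Impute missing intensities as row minimum / 10
#'
#' Each missing cell of a peptide ion is replaced by the minimum intensity
#' quantified for that ion across all samples, divided by 10 -- a small
#' left-censored placeholder. Ions with no quantified value at all cannot
#' be imputed and are dropped with a warning.
#'
#' @param x a [PeptideQuant-class], normally already normalized (a warning
#'   is issued otherwise).
#' @return A [PeptideQuant-class] without missing cells; `imputed` flag set.
#' @export
imputeMissing <- function(x) {
  stopifnot(methods::is(x, "PeptideQuant"))
  if (!isNormalized(x))
    warning("imputing a table that is not flagged as normalized",
            call. = FALSE)
  m <- SummarizedExperiment::assay(x, "intensity")
  if (nrow(m) == 0L) stop("empty peptide table", call. = FALSE)
  allMissing <- rowSums(!is.na(m)) == 0L
  if (any(allMissing)) {
    warning(sprintf("dropping %d peptide ion(s) with no quantified value",
                    sum(allMissing)), call. = FALSE)
    x <- x[!allMissing, ]
    m <- SummarizedExperiment::assay(x, "intensity")
  }
  miss <- is.na(m)
  if (any(miss)) {
    rowMin <- apply(m, 1L, min, na.rm = TRUE)
    m[miss] <- (rowMin / 10)[row(m)[miss]]
    SummarizedExperiment::assay(x, "intensity") <- m
  }
  S4Vectors::metadata(x)$imputed <- TRUE
  x
}

#' Average technical replicates into biological samples
#'
#' Collapses technical replicate columns to their arithmetic mean
#' (post-imputation values), one output column per biological sample.
#'
#' @param x a [PeptideQuant-class].
#' @param replicateMap named character: names are sample (column) ids,
#'   values the biological sample id each column belongs to. Every column
#'   of `x` must be mapped.
#' @return A [PeptideQuant-class] with one column per biological sample, in
#'   first-appearance order of the mapped ids.
#' @export
averageTechnicalReplicates <- function(x, replicateMap) {
  stopifnot(methods::is(x, "PeptideQuant"))
  m <- SummarizedExperiment::assay(x, "intensity")
  unmapped <- setdiff(colnames(m), names(replicateMap))
  if (length(unmapped))
    stop("sample(s) missing from 'replicateMap': ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  bio <- as.character(replicateMap[colnames(m)])
  if (anyNA(bio) || any(!nzchar(bio)))
    stop("'replicateMap' assigns no biological sample to some column(s)",
         call. = FALSE)
  out <- vapply(unique(bio), function(b)
    rowMeans(m[, bio == b, drop = FALSE]), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), unique(bio)))
  rd <- SummarizedExperiment::rowData(x)
  PeptideQuant(out, ionId = rd$ion_id, protein = rd$protein,
               sites = rd$sites,
               sequence = if ("sequence" %in% colnames(rd)) rd$sequence,
               normalized = isNormalized(x), imputed = isImputed(x))
}

#' Roll peptide ions up to phosphosite ppIndex values
#'
#' The phosphorylation index (ppIndex) of a site is the sum of the
#' intensities of all peptide ions whose modification-site list contains
#' that site. An ion carrying k sites contributes its full intensity to
#' each of the k sites; unmodified ions are ignored.
#'
#' @param x an imputed [PeptideQuant-class] (no missing cells).
#' @return A [SiteQuant-class]; empty (with a warning) when no ion carries
#'   a modification site.
#' @export
rollupSites <- function(x) {
  stopifnot(methods::is(x, "PeptideQuant"))
  m <- SummarizedExperiment::assay(x, "intensity")
  if (anyNA(m))
    stop("missing intensities present; run imputeMissing() first",
         call. = FALSE)
  sitesList <- .splitSites(SummarizedExperiment::rowData(x)$sites)
  k <- lengths(sitesList)
  if (all(k == 0L)) {
    warning("no peptide ion carries a modification site", call. = FALSE)
    return(SiteQuant(matrix(numeric(), 0, ncol(m),
                            dimnames = list(NULL, colnames(m))),
                     colData = SummarizedExperiment::colData(x)))
  }
  idx <- rep.int(seq_along(sitesList), k)
  site <- unlist(sitesList, use.names = FALSE)
  pp <- rowsum(m[idx, , drop = FALSE], group = site, reorder = TRUE)
  SiteQuant(pp, colData = SummarizedExperiment::colData(x))
}

#' Roll peptide ions up to protein intensities
#'
#' Protein intensity is the sum of the intensities of all peptide ions
#' derived from that protein.
#'
#' @param x an imputed [PeptideQuant-class] (no missing cells).
#' @return A [ProteinQuant-class].
#' @export
rollupProteins <- function(x) {
  stopifnot(methods::is(x, "PeptideQuant"))
  m <- SummarizedExperiment::assay(x, "intensity")
  if (anyNA(m))
    stop("missing intensities present; run imputeMissing() first",
         call. = FALSE)
  prot <- as.character(SummarizedExperiment::rowData(x)$protein)
  out <- rowsum(m, group = prot, reorder = TRUE)
  ProteinQuant(out, colData = SummarizedExperiment::colData(x))
}

#' Two-group differential test on log2 intensities
#'
#' Per-feature log2 fold change (treated minus control group mean on the
#' log2 scale) with a two-tailed Student's t-test: the equal-variance
#' two-sample form for unpaired designs, or a one-sample t on paired log2
#' differences when `paired = TRUE`. Benjamini-Hochberg q-values are
#' reported alongside the raw p-values.
#'
#' @param x a [SiteQuant-class], [ProteinQuant-class] or numeric matrix
#'   (features in rows, samples in columns).
#' @param group factor-like of length `ncol(x)` with exactly two levels;
#'   taken from `colData(x)$group` when omitted.
#' @param ref the control (reference) level; default the first level.
#' @param paired logical; use the paired test.
#' @param pairing factor-like of length `ncol(x)` identifying pairs;
#'   required (and checked for completeness) when `paired = TRUE`.
#' @param log2Transform log2-transform intensities first (default TRUE;
#'   set FALSE if `x` is already on the log2 scale).
#' @return A [S4Vectors::DataFrame] with columns `feature_id`, `log2fc`,
#'   `t`, `p`, `q`, `mean_ctrl`, `mean_trt` and metadata recording the
#'   design. Zero-variance features get `t = 0`, `p = 1` when the group
#'   means are equal, `NA` statistics otherwise being impossible here.
#' @examples
#' m <- matrix(2^rnorm(40, 20), 5, 8)
#' rownames(m) <- paste0("f", 1:5)
#' colnames(m) <- paste0("s", 1:8)
#' differentialTest(m, rep(c("control", "treated"), each = 4))
#' @export
differentialTest <- function(x, group = NULL, ref = NULL, paired = FALSE,
                             pairing = NULL, log2Transform = TRUE) {
  m <- .assayMatrix(x)
  if (is.null(group) && methods::is(x, "SummarizedExperiment"))
    group <- SummarizedExperiment::colData(x)$group
  if (is.null(group)) stop("'group' is required", call. = FALSE)
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (length(group) != ncol(m))
    stop("'group' must have one entry per sample", call. = FALSE)
  if (is.null(ref)) ref <- levels(group)[1L]
  group <- stats::relevel(group, ref = ref)
  if (any(table(group) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  if (log2Transform) {
    if (any(m <= 0, na.rm = TRUE))
      stop("non-positive intensities cannot be log2-transformed",
           call. = FALSE)
    m <- log2(m)
  }
  ctrl <- m[, group == levels(group)[1L], drop = FALSE]
  trt <- m[, group == levels(group)[2L], drop = FALSE]
  meanC <- rowMeans(ctrl)
  meanT <- rowMeans(trt)
  fc <- meanT - meanC
  if (paired) {
    if (is.null(pairing))
      stop("'pairing' is required for a paired test", call. = FALSE)
    pairing <- as.character(pairing)
    pc <- pairing[group == levels(group)[1L]]
    ptr <- pairing[group == levels(group)[2L]]
    if (anyDuplicated(pc) || anyDuplicated(ptr) ||
        !setequal(pc, ptr) || length(pc) != length(ptr))
      stop("paired design requires a complete 1:1 pairing", call. = FALSE)
    d <- trt[, match(pc, ptr), drop = FALSE] - ctrl
    n <- ncol(d)
    md <- rowMeans(d)
    sdd <- apply(d, 1L, sd)
    tt <- md / (sdd / sqrt(n))
    df <- n - 1L
  } else {
    n1 <- ncol(ctrl); n2 <- ncol(trt)
    v1 <- apply(ctrl, 1L, stats::var)
    v2 <- apply(trt, 1L, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (meanT - meanC) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2L
  }
  # zero spread with zero difference: no evidence against the null
  tt[is.nan(tt) & abs(fc) < .Machine$double.eps^0.5] <- 0
  p <- 2 * pt(-abs(tt), df = df)
  res <- S4Vectors::DataFrame(
    feature_id = rownames(m), log2fc = unname(fc), t = unname(tt),
    p = unname(p), q = unname(p.adjust(p, method = "BH")),
    mean_ctrl = unname(meanC), mean_trt = unname(meanT),
    row.names = rownames(m))
  S4Vectors::metadata(res) <- list(
    paired = paired, ref = ref,
    n = as.integer(table(group)[c(1L, 2L)]), df = df)
  res
}
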