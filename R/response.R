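# Drug-response summarization and feature-response association.

#' Area above a dose-viability curve
#'
#' Trapezoidal area between viability 1 and the (clipped to \[0, 1\])
#' viability curve over log10(dose), divided by the log10-dose range. The
#' result is a unitless score in \[0, 1\]: 0 means no effect at any dose,
#' 1 complete kill at all doses; higher values mean a more sensitive
#' sample.
#'
#' @param doses strictly ascending positive doses (>= 2 values).
#' @param viability matching viability fractions; values outside \[0, 1\]
#'   are clipped before integration.
#' @return A single number in \[0, 1\].
#' @examples
#' d <- 10^seq(-3, 1, length.out = 8)
#' computeAac(d, rep(1, 8))                       # 0: no effect
#' computeAac(d, seq(1, 0, length.out = 8))       # 0.5: linear decline
#' @export
computeAac <- function(doses, viability) {
  if (length(doses) < 2L)
    stop("at least 2 doses are required", call. = FALSE)
  if (length(viability) != length(doses))
    stop("'doses' and 'viability' lengths differ", call. = FALSE)
  if (any(doses <= 0) || any(diff(doses) <= 0))
    stop("'doses' must be positive and strictly ascending", call. = FALSE)
  v <- pmin(1, pmax(0, viability))
  x <- log10(doses)
  above <- 1 - v
  area <- sum(diff(x) * (head(above, -1L) + tail(above, -1L)) / 2)
  area / (x[length(x)] - x[1L])
}

#' Label samples sensitive or resistant at the cohort mean
#'
#' The threshold is the arithmetic mean of all sensitivity values; samples
#' strictly above it are `sensitive`, the rest `resistant` (values exactly
#' at the mean fall to `resistant` -- the documented tie rule). For metrics
#' where smaller means more sensitive, set `direction = "below"`.
#'
#' @param values named numeric sensitivity metric (e.g. AAC), >= 2 samples.
#' @param direction `"above"` (default; higher value = sensitive) or
#'   `"below"`.
#' @return data.frame with columns `sample`, `value`, `class` (factor with
#'   levels `sensitive`, `resistant`) and a `threshold` attribute.
#' @examples
#' classifySensitivity(c(a = 0.2, b = 0.4, c = 0.9))
#' @export
classifySensitivity <- function(values, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) stop("at least 2 samples required", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be named by sample id", call. = FALSE)
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  thr <- mean(values)
  if (all(values == values[[1L]]))
    stop("all sensitivity values identical; cohort cannot be split",
         call. = FALSE)
  sensitive <- if (direction == "above") values > thr else values < thr
  out <- data.frame(sample = names(values), value = unname(values),
                    class = factor(ifelse(sensitive, "sensitive",
                                          "resistant"),
                                   levels = c("sensitive", "resistant")),
                    row.names = NULL)
  attr(out, "threshold") <- thr
  attr(out, "direction") <- direction
  out
}

#' Spearman correlation of features with a sensitivity metric
#'
#' Per-feature Spearman rank correlation (average-rank tie handling)
#' against the sensitivity values of overlapping samples, with a two-tailed
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Features with fewer than `minSamples` overlapping quantified samples are
#' skipped (NA statistics) with a note.
#'
#' @param x a [SiteQuant-class], activity matrix or numeric matrix
#'   (features in rows, samples in columns; sample names must match
#'   `names(sensitivity)`).
#' @param sensitivity named numeric metric per sample.
#' @param minSamples minimum overlapping samples per feature (default 4).
#' @return data.frame with columns `feature_id`, `n`, `rho`, `p`.
#' @export
correlateFeatures <- function(x, sensitivity, minSamples = 4) {
  m <- .assayMatrix(x)
  minSamples <- .checkCount(minSamples, "minSamples", min = 3L)
  common <- intersect(colnames(m), names(sensitivity))
  if (!length(common))
    stop("no overlapping samples between features and sensitivity",
         call. = FALSE)
  m <- m[, common, drop = FALSE]
  s <- sensitivity[common]
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    ok <- !is.na(m[i, ]) & !is.na(s)
    n <- sum(ok)
    if (n < minSamples) return(c(n = n, rho = NA_real_, p = NA_real_))
    rho <- cor(rank(m[i, ok]), rank(s[ok]))
    if (is.na(rho)) return(c(n = n, rho = NA_real_, p = NA_real_))
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tt), df = n - 2)
    }
    c(n = n, rho = rho, p = p)
  }, numeric(3)))
  skipped <- sum(res[, "n"] < minSamples)
  if (skipped)
    message(sprintf("skipping %d feature(s) with fewer than %d overlapping samples",
                    skipped, minSamples))
  data.frame(feature_id = rownames(m), n = as.integer(res[, "n"]),
             rho = res[, "rho"], p = res[, "p"], row.names = NULL)
}

#' Intersect differential features with gene dependency scores
#'
#' Keeps features whose log2 fold change and p-value pass the configured
#' cutoffs and whose dependency score is at or below `depCutoff` in every
#' requested cell line (negative dependency scores mean the gene is needed
#' for proliferation). All three cutoffs must be supplied explicitly.
#'
#' @param contrast a [differentialTest()] result whose `feature_id` shares
#'   a namespace with the dependency table's `gene` column.
#' @param dependency data.frame with a `gene` column plus one numeric
#'   column per cell line.
#' @param fcCutoff keep features with `log2fc <= fcCutoff`.
#' @param pCutoff keep features with `p <= pCutoff`.
#' @param depCutoff keep genes with dependency `<= depCutoff` in all
#'   requested cell lines.
#' @param cellLines character, cell-line columns to require.
#' @return data.frame of hits: `feature_id`, `log2fc`, `p` and one
#'   dependency column per requested cell line; empty (with a warning)
#'   when the namespaces do not intersect.
#' @export
integrateDependency <- function(contrast, dependency, fcCutoff, pCutoff,
                                depCutoff, cellLines) {
  if (missing(fcCutoff) || missing(pCutoff) || missing(depCutoff))
    stop("'fcCutoff', 'pCutoff' and 'depCutoff' must all be supplied",
         call. = FALSE)
  df <- as.data.frame(contrast)
  if (!all(c("feature_id", "log2fc", "p") %in% colnames(df)))
    stop("contrast must have 'feature_id', 'log2fc' and 'p'", call. = FALSE)
  if (!"gene" %in% colnames(dependency))
    stop("dependency table needs a 'gene' column", call. = FALSE)
  absent <- setdiff(cellLines, colnames(dependency))
  if (length(absent))
    stop("cell line(s) absent from the dependency table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  shared <- intersect(df$feature_id, dependency$gene)
  if (!length(shared)) {
    warning("contrast and dependency tables share no gene ids",
            call. = FALSE)
    return(cbind(data.frame(feature_id = character(), log2fc = numeric(),
                            p = numeric()),
                 stats::setNames(as.data.frame(
                   matrix(numeric(), 0, length(cellLines))), cellLines)))
  }
  df <- df[df$feature_id %in% shared, c("feature_id", "log2fc", "p")]
  dep <- dependency[match(df$feature_id, dependency$gene), cellLines,
                    drop = FALSE]
  pass <- df$log2fc <= fcCutoff & df$p <= pCutoff &
    rowSums(as.matrix(dep) <= depCutoff) == length(cellLines)
  pass[is.na(pass)] <- FALSE
  out <- cbind(df[pass, , drop = FALSE], dep[pass, , drop = FALSE])
  rownames(out) <- NULL
  out
}
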