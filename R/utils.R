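# Internal helpers shared across modules.

# Site id convention: <PROTEIN>(<residue><position>), e.g. PAK1(S144).
.makeSiteIds <- function(n) {
  prot <- sprintf("PR%04d", seq_len(n))
  res <- sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(0.85, 0.12, 0.03))
  pos <- sample.int(999L, n, replace = TRUE)
  sprintf("%s(%s%d)", prot, res, pos)
}

.siteProtein <- function(siteIds) sub("\\(.*$", "", siteIds)

.randomPeptide <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(7:20, 1L)
    paste0(paste(sample(aa, len, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

.splitSites <- function(sites) {
  out <- strsplit(as.character(sites), ";", fixed = TRUE)
  lapply(out, function(s) s[nzchar(s)])
}

.assayMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L)
  else as.matrix(x)
}

.checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

.checkFraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}
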