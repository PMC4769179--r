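#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
#' @importFrom IRanges IRanges width pintersect ranges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats rpois rbinom runif rnorm p.adjust lowess approx
#'   pt median quantile sd var setNames
#' @importFrom utils read.table write.table head tail
NULL

# Convert a 0-based half-open interval table to GRanges (1-based internally).
.as_granges <- function(df, chrom = "chrom", start = "start", end = "end",
                        strand_col = NULL) {
  stopifnot(all(c(chrom, start, end) %in% names(df)))
  str <- if (!is.null(strand_col) && strand_col %in% names(df)) {
    s <- as.character(df[[strand_col]])
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df[[chrom]]),
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]]),
    strand = str
  )
}

# findOverlaps with harmonized sequence levels, so queries and subjects on
# disjoint chromosome sets compare silently (no overlaps, no warning)
.find_overlaps <- function(a, b, ...) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lev
  GenomeInfoDb::seqlevels(b) <- lev
  GenomicRanges::findOverlaps(a, b, ...)
}

.stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Geometric-mean-centred scaling used by TMM factor normalisation.
.geo_centre <- function(x) x / exp(mean(log(x)))

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
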