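# Transposon expression quantification: rRNA/exon filters, weighted
# multi-map family counts, unique-mode element counts, CPM/RPKM and chimeric
# transcript detection.

# records: one row per candidate hit of a read
# (read_id, chrom, start, end, strand, n_hits, flags)

#' Remove rRNA-flagged reads
#'
#' Drops every read whose `flags` field contains `rRNA`. The number of reads
#' removed is attached as attribute `n_removed`.
#'
#' @param records Alignment hit table (one row per hit).
#' @return Filtered records.
#' @export
filter_rrna <- function(records) {
  if (!nrow(records)) return(records)
  bad_reads <- unique(records$read_id[grepl("rRNA", records$flags)])
  out <- records[!records$read_id %in% bad_reads, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- length(bad_reads)
  out
}

#' Remove reads with any exonic hit
#'
#' A read is removed when any of its hits overlaps an annotated exon by at
#' least 1 bp, so that only autonomously transcribed transposons are
#' counted downstream. The whole read (all hits) is removed; set
#' `drop_hits_only = TRUE` to remove only the exonic hits instead (the
#' per-hit weight is still 1/n over the original hit count).
#'
#' @param records Alignment hit table.
#' @param exons Interval table with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param drop_hits_only Remove only exonic hits rather than whole reads.
#' @return Filtered records.
#' @export
exclude_exonic <- function(records, exons, drop_hits_only = FALSE) {
  if (!nrow(records) || is.null(exons) || !nrow(exons)) return(records)
  hits_gr <- .as_granges(records)
  ex_gr <- .as_granges(exons)
  ov <- .find_overlaps(hits_gr, ex_gr, minoverlap = 1L)
  exonic <- unique(S4Vectors::queryHits(ov))
  out <- if (drop_hits_only) {
    if (length(exonic)) records[-exonic, , drop = FALSE] else records
  } else {
    bad <- unique(records$read_id[exonic])
    records[!records$read_id %in% bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assign read hits to reconstructed elements under the 80% rule
#'
#' A hit is assigned to an element when the overlap covers at least
#' `min_overlap_frac` of the read length (inclusive at the boundary). Each
#' assignment carries the read's per-hit weight `1 / n_hits`, so a read
#' assigned at k of its n hits contributes k/n in total. Strand is ignored
#' by default (unstranded protocol); set `stranded = TRUE` to require
#' matching strands.
#'
#' When `elements` carries the `fragment_intervals` attribute set by
#' [merge_fragments()], overlap is measured against the element's member
#' fragments rather than its whole span, so reads inside a nested insertion
#' are not credited to the host element.
#'
#' @param records Alignment hit table.
#' @param elements Element table from [merge_fragments()] (or any table with
#'   `element_id`, `chrom`, `start`, `end`, `strand`, `family`).
#' @param min_overlap_frac Minimum fraction of the read covered, in (0, 1].
#' @param stranded Require hit and element strands to match.
#' @return `data.frame` of assignments: `read_id`, `element_id`, `family`,
#'   `weight`.
#' @export
assign_to_elements <- function(records, elements, min_overlap_frac = 0.8,
                               stranded = FALSE) {
  if (min_overlap_frac <= 0 || min_overlap_frac > 1)
    stop("min_overlap_frac must be in (0, 1]", call. = FALSE)
  empty <- data.frame(read_id = character(), element_id = character(),
                      family = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(records) || !nrow(elements)) return(empty)
  hits_gr <- .as_granges(records)
  fi <- attr(elements, "fragment_intervals")
  if (is.null(fi)) {
    fi <- elements[, c("element_id", "chrom", "start", "end")]
  }
  el_row <- match(fi$element_id, elements$element_id)
  fi_gr <- .as_granges(fi)
  ov <- .find_overlaps(hits_gr, fi_gr)
  if (!length(ov)) return(empty)
  qh0 <- S4Vectors::queryHits(ov); fh <- S4Vectors::subjectHits(ov)
  w0 <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(hits_gr)[qh0], IRanges::ranges(fi_gr)[fh]))
  # total overlap of each hit with each element (over its fragments)
  key <- paste(qh0, el_row[fh])
  agg <- tapply(w0, key, sum)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  qh <- as.integer(vapply(parts, `[`, character(1), 1))
  sh <- as.integer(vapply(parts, `[`, character(1), 2))
  ov_w <- as.numeric(agg)
  read_len <- records$end[qh] - records$start[qh]
  keep <- ov_w >= min_overlap_frac * read_len
  if (stranded) keep <- keep & records$strand[qh] == elements$strand[sh]
  qh <- qh[keep]; sh <- sh[keep]
  data.frame(read_id = records$read_id[qh],
             element_id = elements$element_id[sh],
             family = elements$family[sh],
             weight = 1 / records$n_hits[qh],
             stringsAsFactors = FALSE)
}

#' Weighted family-level counts (multi-map mode)
#'
#' Per-family count is the sum of assignment weights: a read weighted by its
#' number of mapping sites contributes `1/n` at each assigned hit.
#'
#' @param assignments From [assign_to_elements()].
#' @param families Optional character vector fixing the output families
#'   (zero-filled where absent).
#' @return Named numeric vector of weighted counts.
#' @export
family_counts <- function(assignments, families = NULL) {
  counts <- tapply(assignments$weight, assignments$family, sum)
  counts <- setNames(as.numeric(counts), names(counts))
  if (!is.null(families)) {
    out <- setNames(numeric(length(families)), families)
    shared <- intersect(names(counts), families)
    out[shared] <- counts[shared]
    counts <- out
  }
  counts
}

#' Unique-mode per-element counts with the minimum-read filter
#'
#' Counts only uniquely mapping reads (`n_hits == 1`) per element across
#' samples, keeps elements with at least `min_reads` reads in at least one
#' sample, and returns counts together with CPM (counts normalized by the
#' library size, where the library size is the number of unique reads
#' surviving the upstream filters in each sample).
#'
#' @param record_list Named list of per-sample alignment hit tables (already
#'   rRNA/exon filtered).
#' @param elements Element table.
#' @param min_reads Keep an element when max count across samples is at
#'   least this (default 10).
#' @param min_overlap_frac Assignment rule, as in [assign_to_elements()].
#' @return List with `counts` (elements x samples matrix), `cpm` and
#'   `library_sizes`.
#' @export
element_counts <- function(record_list, elements, min_reads = 10,
                           min_overlap_frac = 0.8) {
  stopifnot(length(record_list) >= 1)
  samples <- names(record_list)
  if (is.null(samples)) samples <- paste0("sample", seq_along(record_list))
  counts <- matrix(0, nrow(elements), length(record_list),
                   dimnames = list(elements$element_id, samples))
  libsize <- setNames(numeric(length(record_list)), samples)
  for (j in seq_along(record_list)) {
    rec <- record_list[[j]]
    rec <- rec[rec$n_hits == 1L, , drop = FALSE]
    libsize[j] <- length(unique(rec$read_id))
    asg <- assign_to_elements(rec, elements, min_overlap_frac)
    if (nrow(asg)) {
      tab <- tapply(asg$weight, asg$element_id, sum)
      counts[names(tab), j] <- as.numeric(tab)
    }
  }
  keep <- apply(counts, 1, max) >= min_reads
  counts <- counts[keep, , drop = FALSE]
  cpm_mat <- counts * NA_real_
  ok <- libsize > 0
  if (any(ok))
    cpm_mat[, ok] <- cpm(counts[, ok, drop = FALSE], libsize[ok])
  list(counts = counts, cpm = cpm_mat, library_sizes = libsize)
}

#' Counts per million
#'
#' @param counts Count matrix (features x samples) or vector.
#' @param library_sizes Per-sample library sizes.
#' @return CPM on the same shape.
#' @export
cpm <- function(counts, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  if (is.matrix(counts)) sweep(counts, 2, library_sizes / 1e6, "/")
  else counts / (library_sizes / 1e6)
}

#' Reads per kilobase per million
#'
#' `count * 1e9 / (length * library_size)`.
#'
#' @param counts Count matrix (features x samples) or vector.
#' @param lengths Feature lengths in bp (> 0).
#' @param library_sizes Per-sample library sizes (> 0).
#' @return RPKM on the same shape.
#' @export
rpkm <- function(counts, lengths, library_sizes) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  if (is.matrix(counts))
    sweep(counts / lengths, 2, library_sizes, "/") * 1e9
  else counts * 1e9 / (lengths * library_sizes)
}

#' Read transcript exons from a GTF file
#'
#' Imports `exon` records and returns them in the exon-table layout
#' [detect_chimeric()] consumes (coordinates converted to 0-based
#' half-open).
#'
#' @param path GTF file path.
#' @return `data.frame` with `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_transcripts_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  data.frame(transcript_id = gr$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Detect chimeric transposon-gene transcripts
#'
#' A transcript is chimeric when its 5'-most exon (strand-aware: the
#' highest-coordinate exon on the minus strand) overlaps a reconstructed
#' transposon element and at least one of its other exons overlaps an
#' annotated gene exon — the signature of a transcript initiated in an LTR
#' and spliced into a gene.
#'
#' @param transcripts `data.frame` of transcript exons: `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (one row per exon).
#' @param elements Element table.
#' @param gene_exons Gene exon table (`gene_id`, `chrom`, `start`, `end`).
#' @return `data.frame` of calls: `transcript_id`, `element_id`, `gene_id`.
#'   Transcripts without strand are skipped with a warning; mono-exonic
#'   transcripts are never chimeric.
#' @export
detect_chimeric <- function(transcripts, elements, gene_exons) {
  empty <- data.frame(transcript_id = character(), element_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (!nrow(transcripts)) return(empty)
  calls <- list()
  for (tid in unique(transcripts$transcript_id)) {
    tx <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
    if (nrow(tx) < 2L) next
    strand <- unique(tx$strand)
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      warning("transcript ", tid, " has no usable strand; skipped")
      next
    }
    first <- if (strand == "+") which.min(tx$start) else which.max(tx$end)
    f_gr <- .as_granges(tx[first, , drop = FALSE])
    o_gr <- .as_granges(tx[-first, , drop = FALSE])
    el_ov <- .find_overlaps(f_gr, .as_granges(elements))
    if (!length(el_ov)) next
    gx_ov <- .find_overlaps(o_gr, .as_granges(gene_exons))
    if (!length(gx_ov)) next
    calls[[length(calls) + 1L]] <- data.frame(
      transcript_id = tid,
      element_id = elements$element_id[S4Vectors::subjectHits(el_ov)[1]],
      gene_id = gene_exons$gene_id[S4Vectors::subjectHits(gx_ov)[1]],
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}
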