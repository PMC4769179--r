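# DNA methylation summarization: LUMA global methylation, per-CpG filtering,
# compartment and element means, and residually methylated regions.

#' LUMA global CpG methylation from a pyrogram pair
#'
#' Global methylation is `1 - sqrt(R_HpaII / R_MspI)` where
#' `R = (p8 * p14) / (p7 * p13)` are peak-height ratios of the
#' methylation-sensitive (HpaII/EcoRI) and -insensitive (MspI/EcoRI)
#' digests at dispensation positions 7, 8, 13 and 14. The result is clamped
#' to \[0, 1\]; a HpaII/MspI ratio above 1 yields 0 with a warning.
#'
#' @param hpaii,mspi `pyrogram` objects (see [pyrogram()]).
#' @return Global methylation fraction in \[0, 1\].
#' @export
luma_global_methylation <- function(hpaii, mspi) {
  stopifnot(inherits(hpaii, "pyrogram"), inherits(mspi, "pyrogram"))
  if (hpaii$p7 * hpaii$p13 <= 0 || mspi$p7 * mspi$p13 <= 0)
    stop("reference peaks p7 * p13 must be positive", call. = FALSE)
  r_hp <- (hpaii$p8 * hpaii$p14) / (hpaii$p7 * hpaii$p13)
  r_ms <- (mspi$p8 * mspi$p14) / (mspi$p7 * mspi$p13)
  if (r_ms <= 0)
    stop("MspI peak ratio must be positive", call. = FALSE)
  ratio <- r_hp / r_ms
  if (ratio > 1) {
    warning("HpaII/MspI ratio above 1; clamping methylation to 0")
    return(0)
  }
  min(1, max(0, 1 - sqrt(ratio)))
}

#' Filter CpG calls by minimum coverage
#'
#' Only CpG dinucleotides covered by at least `min_cov` reads are retained.
#'
#' @param calls CpG table with a `coverage` column.
#' @param min_cov Minimum coverage (default 10).
#' @return Filtered table.
#' @export
filter_cpg <- function(calls, min_cov = 10) {
  out <- calls[calls$coverage >= min_cov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build genomic compartments from gene and repeat annotations
#'
#' Promoters are the strand-aware \[TSS - 1000, TSS + 100\] window; exons
#' and introns come from the gene model; repeats from the reconstructed
#' elements; CGIs may be supplied. Intergenic is defined downstream as the
#' complement of all the others, so it is not materialized here.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param exons Exon table (`gene_id`, `chrom`, `start`, `end`).
#' @param elements Element table (repeats compartment), or `NULL`.
#' @param cgi Optional CGI interval table.
#' @return Named list of interval `data.frame`s (`chrom`, `start`, `end`),
#'   class `compartment_set`.
#' @export
make_compartments <- function(genes, exons, elements = NULL, cgi = NULL) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  prom <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, ifelse(genes$strand == "+", tss - 1000, tss - 100)),
    end = ifelse(genes$strand == "+", tss + 100, tss + 1000),
    stringsAsFactors = FALSE)
  intr <- list()
  for (g in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1)
      intr[[g]] <- data.frame(chrom = ex$chrom[-1],
                              start = ex$end[-nrow(ex)],
                              end = ex$start[-1], stringsAsFactors = FALSE)
  }
  introns <- if (length(intr)) do.call(rbind, intr)
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric())
  comp <- list(promoter = prom,
               CGI = if (is.null(cgi))
                 data.frame(chrom = character(), start = numeric(),
                            end = numeric()) else cgi,
               exon = exons[, c("chrom", "start", "end")],
               intron = introns,
               repeat_ = if (is.null(elements))
                 data.frame(chrom = character(), start = numeric(),
                            end = numeric())
                 else elements[, c("chrom", "start", "end")])
  structure(comp, class = "compartment_set")
}

#' Mean CpG methylation per genomic compartment
#'
#' Unweighted mean of per-site methylation fractions in each compartment. A
#' CpG falling in several compartments counts in each; intergenic is the
#' exclusive complement (sites overlapping no compartment).
#'
#' @param calls Filtered CpG table (`chrom`, `pos`, `meth_fraction`).
#' @param compartments `compartment_set` from [make_compartments()].
#' @return `data.frame` with `compartment`, `mean_methylation`, `n_cpg`.
#' @export
compartment_summary <- function(calls, compartments) {
  stopifnot(inherits(compartments, "compartment_set"))
  sites <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos + 1L, width = 1L))
  in_any <- rep(FALSE, nrow(calls))
  rows <- list()
  for (nm in names(compartments)) {
    iv <- compartments[[nm]]
    label <- sub("_$", "", nm)
    if (!nrow(iv)) {
      rows[[nm]] <- data.frame(compartment = label, mean_methylation = NA_real_,
                               n_cpg = 0L, stringsAsFactors = FALSE)
      next
    }
    ov <- .find_overlaps(sites, .as_granges(iv))
    idx <- unique(S4Vectors::queryHits(ov))
    in_any[idx] <- TRUE
    rows[[nm]] <- data.frame(
      compartment = label,
      mean_methylation = if (length(idx)) mean(calls$meth_fraction[idx])
                         else NA_real_,
      n_cpg = length(idx), stringsAsFactors = FALSE)
  }
  inter <- which(!in_any)
  rows$intergenic <- data.frame(
    compartment = "intergenic",
    mean_methylation = if (length(inter)) mean(calls$meth_fraction[inter])
                       else NA_real_,
    n_cpg = length(inter), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean CpG methylation per element and per family
#'
#' Unweighted mean of site fractions over each reconstructed element;
#' elements without a covered CpG are reported as `NA`, not 0. Family means
#' average the per-site fractions over all copies of the family.
#'
#' @param calls Filtered CpG table.
#' @param elements Element table.
#' @return List with `element` (`element_id`, `family`, `mean_methylation`,
#'   `n_cpg`) and `family` tables.
#' @export
element_summary <- function(calls, elements) {
  sites <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos + 1L, width = 1L))
  ov <- .find_overlaps(sites, .as_granges(elements))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  per_el <- data.frame(element_id = elements$element_id,
                       family = elements$family,
                       mean_methylation = NA_real_, n_cpg = 0L,
                       stringsAsFactors = FALSE)
  if (length(ov)) {
    agg_m <- tapply(calls$meth_fraction[qh], sh, mean)
    agg_n <- tapply(qh, sh, length)
    i <- as.integer(names(agg_m))
    per_el$mean_methylation[i] <- as.numeric(agg_m)
    per_el$n_cpg[i] <- as.integer(agg_n)
  }
  fam <- if (length(ov)) {
    fm <- tapply(calls$meth_fraction[qh], elements$family[sh], mean)
    fn <- tapply(qh, elements$family[sh], length)
    data.frame(family = names(fm), mean_methylation = as.numeric(fm),
               n_cpg = as.integer(fn), stringsAsFactors = FALSE)
  } else data.frame(family = character(), mean_methylation = numeric(),
                    n_cpg = integer())
  rownames(fam) <- NULL
  list(element = per_el, family = fam)
}

#' Detect residually methylated regions by tiling windows
#'
#' Tiles each chromosome with fixed windows, flags windows holding at least
#' `min_cpg` covered CpGs with mean methylation at least `min_meth`, and
#' joins maximal runs of adjacent flagged windows into regions. Interval
#' bounds are tightened to the first/last contributing CpG.
#'
#' @param calls Filtered CpG table, sorted by `chrom`, `pos`.
#' @param window Window width in bp (default 1000).
#' @param min_cpg Minimum covered CpGs per window (default 5).
#' @param min_meth Minimum mean methylation per window (default 0.1).
#' @return `data.frame` of regions: `chrom`, `start`, `end`,
#'   `mean_methylation`, `n_cpg`.
#' @export
detect_rmr <- function(calls, window = 1000L, min_cpg = 5L, min_meth = 0.1) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mean_methylation = numeric(), n_cpg = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  out <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, ]
    cc <- cc[order(cc$pos), ]
    win <- cc$pos %/% window
    m <- tapply(cc$meth_fraction, win, mean)
    n <- tapply(cc$pos, win, length)
    wid <- as.numeric(names(m))
    flag <- m >= min_meth & n >= min_cpg
    if (!any(flag)) next
    # runs of consecutive flagged window indices
    fw <- wid[flag]
    run <- cumsum(c(1, diff(fw) > 1))
    for (r in split(fw, run)) {
      in_run <- cc$pos %/% window %in% r
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(cc$pos[in_run]),
        end = max(cc$pos[in_run]) + 1,
        mean_methylation = mean(cc$meth_fraction[in_run]),
        n_cpg = sum(in_run), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}

#' Concatenate residually methylated regions closer than 1 kb
#'
#' Regions separated by strictly less than `max_gap` bp are merged and their
#' statistics recomputed as CpG-count-weighted means; merged regions are
#' therefore pairwise at least `max_gap` apart. Idempotent.
#'
#' @param rmrs Region table from [detect_rmr()].
#' @param max_gap Merge regions with gap `< max_gap` (default 1000).
#' @return Merged region table.
#' @export
merge_rmr <- function(rmrs, max_gap = 1000L) {
  if (nrow(rmrs) < 2) return(rmrs)
  rmrs <- rmrs[order(rmrs$chrom, rmrs$start), ]
  out <- list(); cur <- rmrs[1, ]
  for (i in 2:nrow(rmrs)) {
    nxt <- rmrs[i, ]
    if (nxt$chrom == cur$chrom && nxt$start - cur$end < max_gap) {
      tot <- cur$n_cpg + nxt$n_cpg
      cur$mean_methylation <- (cur$mean_methylation * cur$n_cpg +
                               nxt$mean_methylation * nxt$n_cpg) / tot
      cur$end <- max(cur$end, nxt$end)
      cur$n_cpg <- tot
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
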