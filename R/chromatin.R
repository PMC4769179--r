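# ChIP enrichment per element, composite metaprofiles over repeats,
# peak-to-compartment annotation and A/B/C repressive-chromatin
# classification.

# sum of track counts over an interval set, prorated by bin overlap
.track_counts <- function(track, iv) {
  res <- numeric(nrow(iv))
  tr_gr <- .as_granges(track)
  iv_gr <- .as_granges(iv)
  ov <- .find_overlaps(iv_gr, tr_gr)
  if (!length(ov)) return(res)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(iv_gr)[qh],
                                          IRanges::ranges(tr_gr)[sh]))
  frac <- w / (track$end[sh] - track$start[sh])
  contrib <- track$count[sh] * frac
  agg <- tapply(contrib, qh, sum)
  res[as.integer(names(agg))] <- as.numeric(agg)
  res
}

#' Per-element ChIP enrichment over input
#'
#' For each element, ChIP and input read counts are collected from the
#' coverage tracks, converted to per-bp densities, scaled by the respective
#' library sizes (total track counts) and divided, with a pseudocount of one
#' read added to both counts. Elements on chromosomes absent from the tracks
#' get `NA`.
#'
#' @param chip_cov,input_cov Coverage tables (`chrom`, `start`, `end`,
#'   `count`).
#' @param elements Element table.
#' @param mark,timepoint Labels carried through to the output.
#' @return `data.frame` with `element_id`, `family`, `mark`, `timepoint`,
#'   `chip_count`, `input_count`, `enrichment`, `log2_enrichment`.
#' @export
element_enrichment <- function(chip_cov, input_cov, elements,
                               mark = "H3K9me3", timepoint = "D0") {
  chip_lib <- sum(chip_cov$count)
  input_lib <- sum(input_cov$count)
  iv <- elements[, c("chrom", "start", "end")]
  cc <- .track_counts(chip_cov, iv)
  ic <- .track_counts(input_cov, iv)
  len <- elements$end - elements$start
  enr <- ((cc + 1) / len / chip_lib) / ((ic + 1) / len / input_lib)
  covered <- elements$chrom %in% unique(chip_cov$chrom) &
             elements$chrom %in% unique(input_cov$chrom)
  enr[!covered] <- NA_real_
  data.frame(element_id = elements$element_id, family = elements$family,
             mark = mark, timepoint = timepoint,
             chip_count = cc, input_count = ic, enrichment = enr,
             log2_enrichment = log2(enr), stringsAsFactors = FALSE)
}

#' Classify repressive chromatin categories from H3K9me3/H3K27me3
#'
#' At the late time point of the conversion, a family (or single element) is
#' category A when both marks are above the threshold (H3K9me3 retained,
#' H3K27me3 gained), B when only H3K9me3 is (IAPEz-like constitutive
#' heterochromatin), C when only H3K27me3 is (MERVL-like complete switch),
#' and unmarked otherwise. At family level the summaries are medians of the
#' per-element log2 enrichments.
#'
#' @param k9,k27 Enrichment tables from [element_enrichment()] for the two
#'   marks, same elements.
#' @param tau Threshold on the log2 enrichment scale (default 0.5).
#' @param level `"element"` or `"family"`.
#' @return `data.frame` with `id`, `category`, `k9`, `k27` (per-element
#'   log2 enrichments or family medians).
#' @export
classify_categories <- function(k9, k27, tau = 0.5,
                                level = c("element", "family")) {
  level <- match.arg(level)
  if (!identical(k9$element_id, k27$element_id))
    stop("k9 and k27 must cover the same elements in the same order",
         call. = FALSE)
  if (level == "element") {
    a <- k9$log2_enrichment; b <- k27$log2_enrichment
    ids <- k9$element_id
  } else {
    a <- as.numeric(tapply(k9$log2_enrichment, k9$family, median,
                           na.rm = TRUE))
    b <- as.numeric(tapply(k27$log2_enrichment, k27$family, median,
                           na.rm = TRUE))
    ids <- names(tapply(k9$log2_enrichment, k9$family, median))
  }
  cat <- ifelse(a >= tau & b >= tau, "A",
         ifelse(a >= tau, "B", ifelse(b >= tau, "C", "unmarked")))
  cat[is.na(a) | is.na(b)] <- NA_character_
  data.frame(id = ids, category = cat, k9 = a, k27 = b,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Composite coverage metaprofile over full-length intact elements
#'
#' Element bodies are scaled to `n_body_bins` bins and flanked by
#' fixed-width bins over `flank` bp on each side; minus-strand elements are
#' reversed so profiles read 5' to 3' left to right. Only full-length
#' (> 6 kb) and intact (integrity score > 0.8) elements enter the profile;
#' the mean per-bp coverage across elements is reported per bin.
#'
#' @param coverage Coverage table (`chrom`, `start`, `end`, `count`).
#' @param elements Element table (filtered internally).
#' @param mark Label carried to the output.
#' @param n_body_bins Number of body bins (default 100).
#' @param flank Flank width in bp (default 5000).
#' @param flank_bin Width of each flank bin in bp (default 100).
#' @param anchor `"edge"` (body-scaled with flanks from the element edges,
#'   the default) or `"center"` (fixed window around the element midpoint).
#' @return Object of class `metaprofile`: list with `mark`, `profile`
#'   (`data.frame` of `bin`, `region`, `mean_coverage`), `per_element`
#'   matrix and `n_elements`.
#' @export
metaprofile <- function(coverage, elements, mark = "H3K9me3",
                        n_body_bins = 100L, flank = 5000L, flank_bin = 100L,
                        anchor = c("edge", "center")) {
  anchor <- match.arg(anchor)
  keep <- elements$is_full_length & elements$integrity_score > 0.8
  if (!any(keep))
    stop("no elements pass the metaprofile filter ",
         "(full-length > 6 kb and integrity score > 0.8)", call. = FALSE)
  el <- elements[keep, ]
  n_flank_bins <- as.integer(flank / flank_bin)
  profs <- matrix(NA_real_, nrow(el),
                  2L * n_flank_bins + n_body_bins)
  for (i in seq_len(nrow(el))) {
    if (anchor == "edge") {
      up <- seq(el$start[i] - flank, el$start[i], length.out =
                  n_flank_bins + 1L)
      body <- seq(el$start[i], el$end[i], length.out = n_body_bins + 1L)
      down <- seq(el$end[i], el$end[i] + flank, length.out =
                    n_flank_bins + 1L)
      edges <- c(up[-length(up)], body, down[-1])
    } else {
      mid <- (el$start[i] + el$end[i]) / 2
      half <- flank + (flank_bin * n_body_bins) / 2
      edges <- seq(mid - half, mid + half,
                   length.out = 2L * n_flank_bins + n_body_bins + 1L)
    }
    iv <- data.frame(chrom = el$chrom[i], start = pmax(0, head(edges, -1)),
                     end = pmax(1, edges[-1]))
    dens <- .track_counts(coverage, iv) / (iv$end - iv$start)
    if (el$strand[i] == "-") dens <- rev(dens)
    profs[i, ] <- dens
  }
  region <- c(rep("upstream", n_flank_bins), rep("body", n_body_bins),
              rep("downstream", n_flank_bins))
  structure(list(
    mark = mark,
    profile = data.frame(bin = seq_len(ncol(profs)), region = region,
                         mean_coverage = colMeans(profs),
                         stringsAsFactors = FALSE),
    per_element = profs, n_elements = nrow(el)), class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("metaprofile: %s over %d elements, %d bins\n",
              x$mark, x$n_elements, nrow(x$profile)))
  invisible(x)
}

#' Plot a set of metaprofiles
#'
#' @param x A `metaprofile`.
#' @param ... Further `metaprofile` objects to overlay.
#' @param col Line colors.
#' @export
plot.metaprofile <- function(x, ..., col = c("darkgreen", "firebrick",
                                             "steelblue")) {
  profs <- c(list(x), Filter(function(o) inherits(o, "metaprofile"),
                             list(...)))
  ylim <- range(vapply(profs, function(p) range(p$profile$mean_coverage),
                       numeric(2)))
  graphics::plot(NA, xlim = c(1, nrow(x$profile)), ylim = ylim,
                 xlab = "bin (5' flank - body - 3' flank)",
                 ylab = "mean coverage", main = "composite profile")
  for (i in seq_along(profs))
    graphics::lines(profs[[i]]$profile$mean_coverage,
                    col = col[(i - 1L) %% length(col) + 1L], lwd = 2)
  graphics::legend("topright", legend = vapply(profs, `[[`, character(1),
                                               "mark"),
                   col = col[seq_along(profs)], lwd = 2, bty = "n")
  invisible(x)
}

#' Annotate peaks to genomic compartments and repeat classes
#'
#' Each peak is assigned one label by precedence among the annotations it
#' overlaps (default promoter > exon > intron > repeat > intergenic, with
#' the repeat label expanded to the repeat class); ties within a level are
#' broken by largest overlap. Labels partition the peak set, so counts sum
#' to the number of peaks.
#'
#' @param peaks Interval table (`chrom`, `start`, `end`).
#' @param compartments `compartment_set` from [make_compartments()].
#' @param elements Element table supplying repeat classes.
#' @param precedence Order of annotation levels.
#' @return `data.frame` with `annotation`, `n_peaks`.
#' @export
annotate_peaks <- function(peaks, compartments, elements,
                           precedence = c("promoter", "exon", "intron",
                                          "repeat", "intergenic")) {
  n <- nrow(peaks)
  labels <- rep("intergenic", n)
  pk_gr <- .as_granges(peaks)
  assigned <- rep(FALSE, n)
  for (lev in setdiff(precedence, "intergenic")) {
    iv <- if (lev == "repeat") elements[, c("chrom", "start", "end")]
          else compartments[[if (lev == "repeat_") "repeat_" else lev]]
    if (is.null(iv) || !nrow(iv)) next
    ov <- .find_overlaps(pk_gr, .as_granges(iv))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(pk_gr)[qh],
      IRanges::ranges(.as_granges(iv))[sh]))
    for (q in unique(qh)) {
      if (assigned[q]) next
      sel <- qh == q
      best <- sh[sel][which.max(w[sel])]
      labels[q] <- if (lev == "repeat") elements$class[best] else lev
      assigned[q] <- TRUE
    }
  }
  tab <- table(labels)
  data.frame(annotation = names(tab), n_peaks = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
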