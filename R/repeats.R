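# Reconstruction of whole transposon copies from fragmented RepeatMasker
# annotations, integrity scoring and census.

#' Parse a RepeatMasker .out annotation file
#'
#' Reads the standard 15-column RepeatMasker `.out` layout (two header lines
#' followed by one row per alignment fragment) into a fragment table.
#' Coordinates are converted from 1-based inclusive to 0-based half-open and
#' percentage columns (divergence, deletion, insertion) to fractions.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A `data.frame` with one row per fragment and columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`; RepeatMasker's
#'   `C` is mapped to `-`), `repeat_name`, `repeat_class`, `repeat_family`
#'   (the part of the class/family column after `/`, or the class itself),
#'   `pct_divergence`, `pct_deletion`, `pct_insertion` (fractions in
#'   \[0, 1\]) and `linkage_id` (the `.out` ID column, which ties fragments
#'   of one insertion together).
#' @seealso [merge_fragments()], [write_repeatmasker_out()]
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  # skip header: first two banner lines plus any blank line
  body <- lines[-seq_len(min(2L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(.empty_fragments())
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 15L)
      stop(sprintf("malformed RepeatMasker row at line %d of %s",
                   i + 2L, path), call. = FALSE)
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    out[[i]] <- data.frame(
      chrom = f[5],
      start = as.integer(f[6]) - 1L,
      end = as.integer(f[7]),
      strand = if (f[9] %in% c("C", "-")) "-" else "+",
      repeat_name = f[10],
      repeat_class = cf[1],
      repeat_family = if (length(cf) > 1L) cf[2] else cf[1],
      pct_divergence = as.numeric(f[2]) / 100,
      pct_deletion = as.numeric(f[3]) / 100,
      pct_insertion = as.numeric(f[4]) / 100,
      linkage_id = as.integer(f[15]),
      stringsAsFactors = FALSE
    )
    if (is.na(out[[i]]$start) || is.na(out[[i]]$end) ||
        out[[i]]$start >= out[[i]]$end)
      stop(sprintf("malformed coordinates at line %d of %s", i + 2L, path),
           call. = FALSE)
  }
  do.call(rbind, out)
}

.empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), repeat_name = character(),
             repeat_class = character(), repeat_family = character(),
             pct_divergence = numeric(), pct_deletion = numeric(),
             pct_insertion = numeric(), linkage_id = integer(),
             stringsAsFactors = FALSE)
}

# name-based conventions for internal vs LTR fragments of an ERV copy
.is_internal_name <- function(name) grepl("([-_](int|I))$", name)
.is_ltr_name <- function(name) grepl("([-_]LTR[0-9]*)$", name)
.strip_te_suffix <- function(name) sub("([-_](int|I|LTR[0-9]*))$", "", name)

#' Build an LTR-internal dictionary
#'
#' LTR retrotransposons are annotated by RepeatMasker as separate internal
#' and LTR fragments under different repeat names. The dictionary pairs each
#' internal name with the LTR names observed flanking it, so that
#' [merge_fragments()] can reassemble LTR-internal-LTR proviruses. Pairings
#' are inferred from genomic adjacency: an LTR-named fragment within
#' `max_gap` of an internal-named fragment on the same strand counts as a
#' partner. A user-supplied override table always wins over inference.
#'
#' @param fragments Fragment table from [parse_repeatmasker_out()], or `NULL`
#'   when only `override` is given.
#' @param override Optional `data.frame` with columns `internal` and `ltr`.
#' @param max_gap Maximum genomic gap (bp) for the adjacency inference.
#' @return An object of class `ltr_dictionary`: a list with `internal_to_ltr`
#'   and `ltr_to_internal` (named lists of character vectors).
#' @export
build_ltr_dictionary <- function(fragments = NULL, override = NULL,
                                 max_gap = 5000L) {
  pairs <- character(0)
  if (!is.null(fragments) && nrow(fragments)) {
    o <- order(fragments$chrom, fragments$start)
    fr <- fragments[o, ]
    intern <- which(.is_internal_name(fr$repeat_name))
    for (i in intern) {
      for (j in c(i - 1L, i + 1L)) {
        if (j < 1L || j > nrow(fr)) next
        if (fr$chrom[j] != fr$chrom[i] || fr$strand[j] != fr$strand[i]) next
        gap <- max(fr$start[j], fr$start[i]) - min(fr$end[j], fr$end[i])
        if (gap > max_gap) next
        if (.is_internal_name(fr$repeat_name[j])) next
        pairs <- c(pairs, paste(fr$repeat_name[i], fr$repeat_name[j],
                                sep = "\t"))
      }
    }
  }
  pairs <- unique(pairs)
  i2l <- list()
  for (p in pairs) {
    kv <- strsplit(p, "\t", fixed = TRUE)[[1]]
    i2l[[kv[1]]] <- union(i2l[[kv[1]]], kv[2])
  }
  if (!is.null(override)) {
    stopifnot(all(c("internal", "ltr") %in% names(override)))
    for (k in unique(override$internal))
      i2l[[k]] <- unique(override$ltr[override$internal == k])
  }
  l2i <- list()
  for (k in names(i2l)) for (v in i2l[[k]]) l2i[[v]] <- union(l2i[[v]], k)
  structure(list(internal_to_ltr = i2l, ltr_to_internal = l2i),
            class = "ltr_dictionary")
}

.dict_partners <- function(a, b, dict) {
  if (is.null(dict)) return(FALSE)
  (a %in% names(dict$internal_to_ltr) && b %in% dict$internal_to_ltr[[a]]) ||
  (b %in% names(dict$internal_to_ltr) && a %in% dict$internal_to_ltr[[b]])
}

#' Merge annotation fragments into reconstructed transposon copies
#'
#' Fragments are joined into one element when they share the `.out` linkage
#' id on the same chromosome, or when they are same-name pieces or
#' LTR-internal dictionary partners on the same strand with genomic gap at
#' most `max_gap`. The linkage id is trusted whenever present for a group;
#' the dictionary route recovers copies whose fragments carry distinct ids.
#' Merged divergence/deletion/insertion percentages are length-weighted means
#' of the member fragments, so a single-fragment element reproduces its
#' fragment's values exactly.
#'
#' @param fragments Fragment table sorted by `chrom`, `start`
#'   (see [parse_repeatmasker_out()]).
#' @param dict An `ltr_dictionary` from [build_ltr_dictionary()], or `NULL`.
#' @param max_gap Maximum gap in bp for dictionary/same-name joins
#'   (default 5000, the scale of typical nested insertions).
#' @return A `data.frame` of reconstructed elements with columns
#'   `element_id`, `chrom`, `start`, `end`, `strand`, `family`, `class`,
#'   `n_fragments`, `pct_divergence`, `pct_deletion`, `pct_insertion`,
#'   `integrity_score`, `is_full_length` (`end - start > 6000`) and
#'   `is_solo_ltr`, plus a list-column `members` holding the row indices of
#'   member fragments in `fragments`.
#' @export
merge_fragments <- function(fragments, dict = NULL, max_gap = 5000L) {
  n <- nrow(fragments)
  if (!n) stop("no fragments to merge", call. = FALSE)
  if (any(order(fragments$chrom, fragments$start) != seq_len(n)))
    stop("fragments must be sorted by chrom, start", call. = FALSE)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }

  # rule (a): shared linkage id on one chromosome
  key <- paste(fragments$chrom, fragments$linkage_id)
  for (g in split(seq_len(n), key)) {
    if (length(g) > 1L) for (j in g[-1]) union_(g[1], j)
  }
  # rule (b): dictionary partners or same-name pieces within max_gap,
  # scanning forward so fragments of a nested insertion can sit between
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && fragments$chrom[j] == fragments$chrom[i] &&
           fragments$start[j] - fragments$end[i] <= max_gap) {
      if (fragments$strand[j] == fragments$strand[i]) {
        same <- fragments$repeat_name[i] == fragments$repeat_name[j]
        if (same || .dict_partners(fragments$repeat_name[i],
                                   fragments$repeat_name[j], dict))
          union_(i, j)
      }
      j <- j + 1L
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  groups <- unname(split(seq_len(n), match(roots, unique(roots))))
  elems <- lapply(groups, function(idx) {
    fr <- fragments[idx, ]
    w <- fr$end - fr$start
    longest <- idx[which.max(w)]
    has_int <- .is_internal_name(fr$repeat_name)
    fam_src <- if (any(has_int)) fr$repeat_name[which(has_int)[1]]
               else fragments$repeat_name[longest]
    solo <- length(idx) == 1L && .is_ltr_solo(fr$repeat_name[1], dict)
    data.frame(
      chrom = fr$chrom[1], start = min(fr$start), end = max(fr$end),
      strand = fr$strand[which.max(w)],
      family = .strip_te_suffix(fam_src),
      class = fragments$repeat_family[longest],
      n_fragments = length(idx),
      pct_divergence = sum(w * fr$pct_divergence) / sum(w),
      pct_deletion = sum(w * fr$pct_deletion) / sum(w),
      pct_insertion = sum(w * fr$pct_insertion) / sum(w),
      stringsAsFactors = FALSE
    )
  })
  el <- do.call(rbind, elems)
  el$integrity_score <- integrity_score(el$pct_divergence, el$pct_deletion,
                                        el$pct_insertion)
  el$is_full_length <- (el$end - el$start) > 6000L
  el$is_solo_ltr <- vapply(groups, function(idx)
    length(idx) == 1L && .is_ltr_solo(fragments$repeat_name[idx[1]], dict),
    logical(1))
  ord <- order(el$chrom, el$start)
  el <- el[ord, ]
  el$element_id <- sprintf("elem_%05d", seq_len(nrow(el)))
  el$members <- I(groups[ord])
  rownames(el) <- NULL
  el <- el[, c("element_id", "chrom", "start", "end", "strand", "family",
               "class", "n_fragments", "pct_divergence", "pct_deletion",
               "pct_insertion", "integrity_score", "is_full_length",
               "is_solo_ltr", "members")]
  # member-fragment intervals, so read assignment can exclude the gaps of
  # nested insertions inside an element's span
  fi <- do.call(rbind, lapply(seq_len(nrow(el)), function(i) {
    idx <- el$members[[i]]
    data.frame(element_id = el$element_id[i], chrom = fragments$chrom[idx],
               start = fragments$start[idx], end = fragments$end[idx],
               stringsAsFactors = FALSE)
  }))
  attr(el, "fragment_intervals") <- fi
  el
}

.is_ltr_solo <- function(name, dict) {
  ltrish <- .is_ltr_name(name) ||
    (!is.null(dict) && name %in% names(dict$ltr_to_internal))
  ltrish && !.is_internal_name(name)
}

#' Transposon integrity score
#'
#' `1 - mean(divergence, deletion, insertion)` on the fraction scale, clamped
#' to \[0, 1\]. A score above 0.8 is the conventional cutoff for a relatively
#' intact copy.
#'
#' @param pct_divergence,pct_deletion,pct_insertion Fractions in \[0, 1\].
#' @return Numeric score(s) in \[0, 1\].
#' @examples
#' integrity_score(0.10, 0.05, 0.03)  # 0.94
#' @export
integrity_score <- function(pct_divergence, pct_deletion, pct_insertion) {
  for (x in list(pct_divergence, pct_deletion, pct_insertion))
    if (any(x < 0 | x > 1, na.rm = TRUE))
      stop("percentages must be fractions in [0, 1]", call. = FALSE)
  pmin(1, pmax(0, 1 - (pct_divergence + pct_deletion + pct_insertion) / 3))
}

#' Census of reconstructed elements by repeat class
#'
#' Counts, per repeat class, the total number of reconstructed copies and how
#' many are intact (integrity score strictly above `cutoff`), with the intact
#' percentage reported to one decimal.
#'
#' @param elements Element table from [merge_fragments()].
#' @param cutoff Integrity cutoff (default 0.8).
#' @return `data.frame` with columns `class`, `total`, `intact`,
#'   `pct_intact`.
#' @export
census <- function(elements, cutoff = 0.8) {
  cl <- split(seq_len(nrow(elements)), elements$class)
  out <- data.frame(
    class = names(cl),
    total = vapply(cl, length, integer(1)),
    intact = vapply(cl, function(i)
      sum(elements$integrity_score[i] > cutoff), integer(1)),
    stringsAsFactors = FALSE
  )
  out$pct_intact <- census_pct(out$intact, out$total)
  rownames(out) <- NULL
  out
}

#' Intact percentage from census counts
#'
#' @param intact,total Counts of intact and total copies.
#' @return Percentage to one decimal.
#' @export
census_pct <- function(intact, total) round(100 * intact / total, 1)

#' Write reconstructed elements as BED6 plus a TSV sidecar
#'
#' The BED file carries element id (name), integrity score scaled to
#' 0-1000 (score) and strand; the sidecar carries family, class, recomputed
#' percentages, the integrity score and the full-length / solo-LTR flags.
#'
#' @param elements Element table from [merge_fragments()].
#' @param bed_path,tsv_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_elements <- function(elements, bed_path, tsv_path) {
  bed <- data.frame(elements$chrom, elements$start, elements$end,
                    elements$element_id,
                    as.integer(round(1000 * elements$integrity_score)),
                    elements$strand)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  keep <- setdiff(names(elements), "members")
  .write_tsv(elements[, keep], tsv_path)
  invisible(c(bed_path, tsv_path))
}
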