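# Synthetic-data generators with known ground truth: fragmented RepeatMasker
# annotations, alignment hit tables, CpG methylomes, LUMA pyrograms and
# ChIP/input coverage tracks.

#' Describe a transposon family for the synthetic genome
#'
#' @param name Family name (unique within a genome spec).
#' @param class Repeat class, one of `LINE`, `SINE`, `ERV1`, `ERVK`, `ERVL`,
#'   `other`.
#' @param consensus_length Full-element length in bp (for LTR elements this
#'   spans LTR + internal + LTR).
#' @param copy_number Number of genomic copies to place.
#' @param is_ltr_element If `TRUE`, each copy is emitted as three annotation
#'   rows (LTR, internal, LTR) as RepeatMasker does for proviruses.
#' @param ltr_length LTR length in bp (LTR elements only).
#' @param divergence_range,deletion_range,insertion_range Ranges (fractions)
#'   from which per-fragment divergence/deletion/insertion are drawn
#'   uniformly.
#' @param expression Named relative expression multipliers per time point,
#'   `c(D0 = ., D6 = ., D13 = .)`; the default is the biphasic
#'   burst-then-resilencing profile (low at D0, peak at D6, partly
#'   re-silenced at D13).
#' @param category Repressive-chromatin category of the family's copies:
#'   `"A"` (H3K9me3 on the 5' half plus H3K27me3 gained on the 3' half),
#'   `"B"` (H3K9me3 over the full length at all times), `"C"` (full switch
#'   from H3K9me3 to H3K27me3), or `"unmarked"`.
#' @param residual_methylation If `TRUE` the family's copies retain ~26%
#'   CpG methylation after global demethylation (IAP-like behaviour).
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, class = c("LINE", "SINE", "ERV1", "ERVK",
                                        "ERVL", "other"),
                        consensus_length = 6000L, copy_number = 10L,
                        is_ltr_element = FALSE, ltr_length = 350L,
                        divergence_range = c(0.02, 0.25),
                        deletion_range = c(0.01, 0.12),
                        insertion_range = c(0.01, 0.12),
                        expression = c(D0 = 0.2, D6 = 1, D13 = 0.4),
                        category = c("B", "A", "C", "unmarked"),
                        residual_methylation = FALSE) {
  class <- match.arg(class)
  category <- match.arg(category)
  stopifnot(consensus_length > 0, copy_number > 0,
            all(c("D0", "D6", "D13") %in% names(expression)))
  if (is_ltr_element && consensus_length <= 2L * ltr_length)
    stop("consensus_length must exceed twice ltr_length", call. = FALSE)
  structure(list(name = name, class = class,
                 consensus_length = as.integer(consensus_length),
                 copy_number = as.integer(copy_number),
                 is_ltr_element = isTRUE(is_ltr_element),
                 ltr_length = as.integer(ltr_length),
                 divergence_range = divergence_range,
                 deletion_range = deletion_range,
                 insertion_range = insertion_range,
                 expression = expression, category = category,
                 residual_methylation = isTRUE(residual_methylation)),
            class = "family_spec")
}

#' Describe a synthetic genome
#'
#' @param families List of [family_spec()] objects with unique names.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param fragmentation_rate Probability that a non-LTR copy is split into
#'   two annotation rows by a simulated internal insertion.
#' @param nesting_rate Probability that the split of a fragmented copy is
#'   caused by a nested younger element (a copy of the first SINE-class
#'   family in `families`, emitted as an extra true copy).
#' @param seed Random seed; identical seeds give byte-identical outputs.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(families, n_chromosomes = 2L, chrom_length = 2e6,
                        fragmentation_rate = 0.3, nesting_rate = 0.1,
                        seed = 1L) {
  stopifnot(n_chromosomes > 0, chrom_length > 0)
  .stopifnot_prob(fragmentation_rate, "fragmentation_rate")
  .stopifnot_prob(nesting_rate, "nesting_rate")
  nm <- vapply(families, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("family names must be unique", call. = FALSE)
  structure(list(families = families, n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.numeric(chrom_length),
                 fragmentation_rate = fragmentation_rate,
                 nesting_rate = nesting_rate, seed = as.integer(seed)),
            class = "genome_spec")
}

# trajectory of genome background CpG methylation during serum -> 2i+vitC
# conversion; residual (IAP-like) copies plateau instead of dropping
.meth_trajectory <- function(residual) {
  if (residual) c(D0 = 0.85, D6 = 0.40, D13 = 0.26)
  else c(D0 = 0.77, D6 = 0.13, D13 = 0.045)
}

#' Generate a fragmented RepeatMasker annotation with ground truth
#'
#' Places each family's copies on the synthetic genome and emits them the way
#' RepeatMasker fragments real elements: every LTR-element copy becomes
#' LTR/internal/LTR rows (sharing the `.out` linkage id for half the copies,
#' carrying distinct ids otherwise, so both reconstruction routes are
#' exercised), and non-LTR copies are split in two at rate
#' `fragmentation_rate`, optionally by a nested SINE insertion. Per-fragment
#' divergence/deletion/insertion are drawn uniformly within the family's
#' ranges; the ground truth records each copy's length-weighted values so
#' integrity-score recovery is exact.
#'
#' @param spec A [genome_spec()].
#' @param out_path Path for the RepeatMasker `.out` file.
#' @return List with `out_path`, `truth` (one row per true copy: `copy_id`,
#'   coordinates, `family`, `class`, `category`, length-weighted
#'   `true_divergence`/`true_deletion`/`true_insertion`, `true_integrity`,
#'   `n_fragments`, expression multipliers `expr_D0/D6/D13` and methylation
#'   trajectory `meth_D0/D6/D13`), `fragment_copy` (the `copy_id` of every
#'   emitted `.out` row, in file order) and `chrom_lengths`.
#' @export
make_annotation <- function(spec, out_path = tempfile(fileext = ".out")) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  cursor <- setNames(rep(10000, spec$n_chromosomes), chroms)

  nest_fam <- NULL
  for (f in spec$families) if (f$class == "SINE") { nest_fam <- f; break }

  rows <- list(); truth <- list(); frag_copy <- integer(0)
  copy_id <- 0L; next_link <- 1L
  add_copy <- function(fam, chrom, start, pieces, strand, category) {
    # pieces: list of (s, e, name) in genome order; one linkage decision
    copy_id <<- copy_id + 1L
    shared <- runif(1) < 0.5
    ids <- if (shared) rep(next_link, length(pieces))
           else seq(next_link, length.out = length(pieces))
    next_link <<- max(ids) + 1L
    # quantized to the .out file's printed precision (0.1%) so that
    # recomputation from the emitted file recovers the truth exactly
    d <- round(runif(length(pieces), fam$divergence_range[1],
                     fam$divergence_range[2]), 3)
    dl <- round(runif(length(pieces), fam$deletion_range[1],
                      fam$deletion_range[2]), 3)
    ins <- round(runif(length(pieces), fam$insertion_range[1],
                       fam$insertion_range[2]), 3)
    w <- vapply(pieces, function(p) p$e - p$s, numeric(1))
    for (k in seq_along(pieces)) {
      p <- pieces[[k]]
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, start = p$s, end = p$e, strand = strand,
        name = p$name, class = fam$class,
        d = d[k], dl = dl[k], ins = ins[k], id = ids[k],
        stringsAsFactors = FALSE)
      frag_copy <<- c(frag_copy, copy_id)
    }
    tw <- function(x) sum(w * x) / sum(w)
    mt <- .meth_trajectory(fam$residual_methylation)
    truth[[copy_id]] <<- data.frame(
      copy_id = copy_id, chrom = chrom,
      start = min(vapply(pieces, `[[`, numeric(1), "s")),
      end = max(vapply(pieces, `[[`, numeric(1), "e")),
      strand = strand, family = fam$name, class = fam$class,
      category = category,
      true_divergence = tw(d), true_deletion = tw(dl),
      true_insertion = tw(ins),
      true_integrity = integrity_score(tw(d), tw(dl), tw(ins)),
      n_fragments = length(pieces),
      expr_D0 = fam$expression[["D0"]] * runif(1, 0.7, 1.3),
      expr_D6 = fam$expression[["D6"]] * runif(1, 0.7, 1.3),
      expr_D13 = fam$expression[["D13"]] * runif(1, 0.7, 1.3),
      meth_D0 = mt[["D0"]], meth_D6 = mt[["D6"]], meth_D13 = mt[["D13"]],
      stringsAsFactors = FALSE)
  }

  for (fam in spec$families) {
    for (i in seq_len(fam$copy_number)) {
      chrom <- sample(chroms, 1L)
      strand <- sample(c("+", "-"), 1L)
      start <- cursor[[chrom]]
      if (fam$is_ltr_element) {
        L <- fam$ltr_length
        inner <- fam$consensus_length - 2L * L
        pieces <- list(
          list(s = start, e = start + L, name = paste0(fam$name, "-LTR")),
          list(s = start + L, e = start + L + inner,
               name = paste0(fam$name, "-int")),
          list(s = start + L + inner, e = start + fam$consensus_length,
               name = paste0(fam$name, "-LTR")))
        add_copy(fam, chrom, start, pieces, strand, fam$category)
        cend <- start + fam$consensus_length
      } else {
        len <- fam$consensus_length
        if (runif(1) < spec$fragmentation_rate && len >= 400L) {
          cut <- round(runif(1, 0.3, 0.7) * len)
          nest <- !is.null(nest_fam) && fam$name != nest_fam$name &&
            runif(1) < spec$nesting_rate
          gap <- if (nest) nest_fam$consensus_length + 20L
                 else round(runif(1, 100, 1500))
          pieces <- list(
            list(s = start, e = start + cut, name = fam$name),
            list(s = start + cut + gap, e = start + len + gap,
                 name = fam$name))
          add_copy(fam, chrom, start, pieces, strand, fam$category)
          if (nest) {
            npieces <- list(list(s = start + cut + 10L,
                                 e = start + cut + 10L + nest_fam$consensus_length,
                                 name = nest_fam$name))
            add_copy(nest_fam, chrom, start, npieces,
                     sample(c("+", "-"), 1L), nest_fam$category)
          }
          cend <- start + len + gap
        } else {
          pieces <- list(list(s = start, e = start + len, name = fam$name))
          add_copy(fam, chrom, start, pieces, strand, fam$category)
          cend <- start + len
        }
      }
      # inter-copy spacing always exceeds the default merge gap
      cursor[[chrom]] <- cend + round(runif(1, 6000, 15000))
      if (cursor[[chrom]] > spec$chrom_length)
        stop("chrom_length too small for the requested copies", call. = FALSE)
    }
  }

  rowdf <- do.call(rbind, rows)
  # fragments must appear in coordinate order, as in real .out files
  ord <- order(rowdf$chrom, rowdf$start)
  rowdf <- rowdf[ord, ]
  frag_copy <- frag_copy[ord]
  write_repeatmasker_out(rowdf, out_path)
  list(out_path = out_path, truth = do.call(rbind, truth),
       fragment_copy = frag_copy,
       chrom_lengths = setNames(rep(spec$chrom_length, length(chroms)),
                                chroms))
}

#' Write fragment rows in RepeatMasker .out layout
#'
#' Emits the standard 15-column layout with 1-based inclusive coordinates and
#' a two-line header. Used by the generator; exported for round-trip testing.
#'
#' @param rows `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, `class`, `d`, `dl`, `ins` (fractions),
#'   `id`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_repeatmasker_out <- function(rows, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end      (left) repeat    class/family  begin end  (left)  ID")
  cls <- function(class) switch(class,
    LINE = "LINE/LINE", SINE = "SINE/SINE", other = "Other/other",
    paste0("LTR/", class))
  body <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %d %d (%d) %d",
    1000L, 100 * rows$d, 100 * rows$dl, 100 * rows$ins,
    rows$chrom, rows$start + 1L, rows$end, 0L,
    ifelse(rows$strand == "-", "C", "+"),
    rows$name, vapply(rows$class, cls, character(1)),
    1L, rows$end - rows$start, 0L, rows$id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate an alignment hit table for one sample
#'
#' Emits reads from each true copy in proportion to its expression at the
#' requested time point. A fraction of reads are multimappers whose extra
#' hits fall at the same relative offset inside other copies of the same
#' family (mirroring why unique mapping under-counts young, homogeneous
#' families); rRNA decoy reads are added at a stated fraction and flagged.
#'
#' @param truth Ground-truth bundle from [make_annotation()].
#' @param timepoint One of `"D0"`, `"D6"`, `"D13"`.
#' @param depth_per_copy Mean reads per copy at expression multiplier 1.
#' @param multimap_fraction Probability a read is a multimapper.
#' @param rrna_fraction Fraction of decoy rRNA-flagged reads added.
#' @param read_length Read length in bp.
#' @param seed Random seed.
#' @return List with `alignments` (one row per hit: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `n_hits`, `flags`) and `read_truth`
#'   (`read_id`, source `copy_id`, `family`).
#' @export
make_alignments <- function(truth, timepoint = "D6", depth_per_copy = 20,
                            multimap_fraction = 0.3, rrna_fraction = 0.05,
                            read_length = 50L, seed = 1L) {
  if (depth_per_copy <= 0) stop("depth_per_copy must be > 0", call. = FALSE)
  .stopifnot_prob(multimap_fraction, "multimap_fraction")
  set.seed(seed)
  tr <- truth$truth
  expr_col <- paste0("expr_", match.arg(timepoint, c("D0", "D6", "D13")))
  fam_idx <- split(seq_len(nrow(tr)), tr$family)

  aln <- list(); rtruth <- list(); rid <- 0L
  for (i in seq_len(nrow(tr))) {
    n_reads <- rpois(1, depth_per_copy * tr[[expr_col]][i])
    if (n_reads == 0) next
    span <- tr$end[i] - tr$start[i] - read_length
    if (span <= 0) next
    for (r in seq_len(n_reads)) {
      rid <- rid + 1L
      off <- floor(runif(1, 0, span))
      hits <- data.frame(chrom = tr$chrom[i], start = tr$start[i] + off,
                         end = tr$start[i] + off + read_length,
                         strand = tr$strand[i], stringsAsFactors = FALSE)
      sibs <- setdiff(fam_idx[[tr$family[i]]], i)
      if (length(sibs) && runif(1) < multimap_fraction) {
        k <- sample(seq_len(min(3L, length(sibs))), 1L)
        for (s in sample(sibs, k)) {
          span_s <- tr$end[s] - tr$start[s] - read_length
          if (span_s <= 0) next
          off_s <- min(off, span_s)
          hits <- rbind(hits, data.frame(
            chrom = tr$chrom[s], start = tr$start[s] + off_s,
            end = tr$start[s] + off_s + read_length,
            strand = tr$strand[s], stringsAsFactors = FALSE))
        }
      }
      hits$read_id <- sprintf("read_%06d", rid)
      hits$n_hits <- nrow(hits)
      hits$flags <- ""
      aln[[length(aln) + 1L]] <- hits
      rtruth[[length(rtruth) + 1L]] <- data.frame(
        read_id = hits$read_id[1], copy_id = tr$copy_id[i],
        family = tr$family[i], stringsAsFactors = FALSE)
    }
  }
  n_decoy <- round(rrna_fraction * rid)
  if (n_decoy > 0) {
    for (r in seq_len(n_decoy)) {
      rid <- rid + 1L
      pos <- floor(runif(1, 0, 5000))
      aln[[length(aln) + 1L]] <- data.frame(
        read_id = sprintf("read_%06d", rid), chrom = names(truth$chrom_lengths)[1],
        start = pos, end = pos + read_length, strand = "+",
        n_hits = 1L, flags = "rRNA", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, aln)
  out <- out[, c("read_id", "chrom", "start", "end", "strand", "n_hits",
                 "flags")]
  rownames(out) <- NULL
  list(alignments = out, read_truth = do.call(rbind, rtruth))
}

#' Generate a per-CpG methylation call table
#'
#' CpG sites are laid down roughly every `cpg_spacing` bp; each site's
#' methylation probability follows its copy's trajectory (background sites
#' follow the global demethylation trajectory for the time point), coverage
#' is Poisson around `coverage_mean` and the observed fraction is
#' Binomial(coverage, p)/coverage.
#'
#' @param truth Bundle from [make_annotation()].
#' @param timepoint `"D0"`, `"D6"` or `"D13"`.
#' @param coverage_mean Mean read coverage per CpG (must be >= 1).
#' @param cpg_spacing Mean spacing between CpG sites in bp.
#' @param seed Random seed.
#' @return `data.frame` with `chrom`, `pos` (0-based position of the C),
#'   `meth_fraction` and `coverage`; only covered sites are emitted.
#' @export
make_methylome <- function(truth, timepoint = "D0", coverage_mean = 30,
                           cpg_spacing = 100L, seed = 1L) {
  if (coverage_mean < 1) stop("coverage_mean must be >= 1", call. = FALSE)
  tp <- match.arg(timepoint, c("D0", "D6", "D13"))
  set.seed(seed)
  tr <- truth$truth
  meth_col <- paste0("meth_", tp)
  background <- .meth_trajectory(FALSE)[[tp]]
  out <- list()
  for (chrom in names(truth$chrom_lengths)) {
    used <- tr[tr$chrom == chrom, ]
    lim <- if (nrow(used)) max(used$end) + 5000 else 20000
    pos <- seq(50L, lim, by = cpg_spacing) +
      sample(0:20, length(seq(50L, lim, by = cpg_spacing)), replace = TRUE)
    p <- rep(background, length(pos))
    for (i in seq_len(nrow(used))) {
      inside <- pos >= used$start[i] & pos < used$end[i]
      p[inside] <- used[[meth_col]][i]
    }
    cov <- rpois(length(pos), coverage_mean)
    keep <- cov > 0
    meth <- rbinom(sum(keep), cov[keep], p[keep]) / cov[keep]
    out[[chrom]] <- data.frame(chrom = chrom, pos = pos[keep],
                               meth_fraction = meth, coverage = cov[keep],
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a LUMA pyrogram pair encoding a global methylation level
#'
#' Builds methylation-sensitive (HpaII/EcoRI) and -insensitive (MspI/EcoRI)
#' digest runs over the dispensation order `GTGTGTCACACAGTGTGT` whose peak
#' heights at positions 7, 8, 13 and 14 encode `global_meth_fraction` under
#' the LUMA formula, so [luma_global_methylation()] inverts the pair exactly.
#'
#' @param global_meth_fraction Target global CpG methylation in \[0, 1\].
#' @return List with `hpaii` and `mspi`, each a `pyrogram` (run id, digest
#'   label and the 18 peak heights).
#' @export
make_pyrogram <- function(global_meth_fraction) {
  .stopifnot_prob(global_meth_fraction, "global_meth_fraction")
  f <- global_meth_fraction
  base <- rep(0.2, 18)
  hp <- base; ms <- base
  hp[c(7, 13)] <- 1; ms[c(7, 13)] <- 1
  ms[c(8, 14)] <- 1
  hp[c(8, 14)] <- 1 - f
  list(hpaii = pyrogram("hpaii_run", "HpaII_EcoRI", hp),
       mspi = pyrogram("mspi_run", "MspI_EcoRI", ms))
}

#' Construct a pyrogram object
#'
#' @param run_id Run identifier.
#' @param digest `"HpaII_EcoRI"` or `"MspI_EcoRI"`.
#' @param peak_heights Numeric vector of >= 14 nonnegative peak heights
#'   indexed by dispensation position (order `GTGTGTCACACAGTGTGT`).
#' @return A `pyrogram` list with `p7`, `p8`, `p13`, `p14` accessors filled.
#' @export
pyrogram <- function(run_id, digest = c("HpaII_EcoRI", "MspI_EcoRI"),
                     peak_heights) {
  digest <- match.arg(digest)
  if (length(peak_heights) < 14 || any(peak_heights < 0))
    stop("need >= 14 nonnegative peak heights", call. = FALSE)
  structure(list(run_id = run_id, digest = digest,
                 peak_heights = peak_heights,
                 p7 = peak_heights[7], p8 = peak_heights[8],
                 p13 = peak_heights[13], p14 = peak_heights[14]),
            class = "pyrogram")
}

#' Generate ChIP and input coverage tracks for one mark and time point
#'
#' Input is flat Poisson noise; ChIP coverage over each element follows its
#' chromatin category: category A elements carry H3K9me3 on the 5' half
#' (all time points) and gain H3K27me3 on the 3' half at D13; category B
#' elements carry H3K9me3 over the full length throughout; category C
#' elements switch from full-length H3K9me3 at D0 to full-length H3K27me3 at
#' D13. Halves are strand-aware.
#'
#' @param truth Bundle from [make_annotation()].
#' @param mark `"H3K9me3"` or `"H3K27me3"`.
#' @param timepoint `"D0"`, `"D6"` or `"D13"`.
#' @param bin Bin width in bp for the coverage tracks.
#' @param lambda Mean input reads per bin.
#' @param enrich Fold-enrichment of marked regions over background.
#' @param seed Random seed.
#' @return List with `chip` and `input` coverage `data.frame`s
#'   (`chrom`, `start`, `end`, `count`).
#' @export
make_chip <- function(truth, mark = c("H3K9me3", "H3K27me3"),
                      timepoint = c("D0", "D6", "D13"), bin = 50L,
                      lambda = 10, enrich = 6, seed = 1L) {
  mark <- match.arg(mark)
  timepoint <- match.arg(timepoint)
  set.seed(seed)
  tr <- truth$truth
  late <- timepoint == "D13"
  chip <- list(); input <- list()
  for (chrom in names(truth$chrom_lengths)) {
    used <- tr[tr$chrom == chrom, ]
    lim <- if (nrow(used)) max(used$end) + 5000 else 20000
    starts <- seq(0L, lim, by = bin)
    mult <- rep(1, length(starts))
    for (i in seq_len(nrow(used))) {
      s <- used$start[i]; e <- used$end[i]
      mid <- (s + e) / 2
      half5 <- if (used$strand[i] == "+") starts >= s & starts < mid
               else starts >= mid & starts < e
      half3 <- (starts >= s & starts < e) & !half5
      full <- starts >= s & starts < e
      m <- switch(used$category[i],
        A = if (mark == "H3K9me3") half5
            else if (late) half3 else rep(FALSE, length(starts)),
        B = if (mark == "H3K9me3") full else rep(FALSE, length(starts)),
        C = if (mark == "H3K9me3" && !late) full
            else if (mark == "H3K27me3" && late) full
            else rep(FALSE, length(starts)),
        rep(FALSE, length(starts)))
      mult[m] <- enrich
    }
    chip[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                end = starts + bin,
                                count = rpois(length(starts), lambda * mult),
                                stringsAsFactors = FALSE)
    input[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                 end = starts + bin,
                                 count = rpois(length(starts), lambda),
                                 stringsAsFactors = FALSE)
  }
  list(chip = do.call(rbind, chip), input = do.call(rbind, input))
}

#' Generate a stable gene count matrix
#'
#' Negative-binomial counts for genes whose expected expression is constant
#' across samples. Combined with transposon family counts into a single
#' table, these anchor library-size and TMM normalization the way the
#' mostly-stable transcriptome does in real libraries, so that coordinated
#' transposon bursts are not absorbed into the normalization.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (columns).
#' @param mean_log2_range Range of per-gene log2 mean expression.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Random seed.
#' @return Count matrix with rownames `gene_0001`, ...
#' @export
make_gene_counts <- function(n_genes = 500L, n_samples = 6L,
                             mean_log2_range = c(3, 10), dispersion = 20,
                             seed = 1L) {
  set.seed(seed)
  mu <- 2^runif(n_genes, mean_log2_range[1], mean_log2_range[2])
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = rep(mu, n_samples),
                             size = dispersion), n_genes, n_samples)
  rownames(m) <- sprintf("gene_%04d", seq_len(n_genes))
  m
}

#' Generate a small gene annotation downstream of the repeat layout
#'
#' Places multi-exon genes in the repeat-free region of each chromosome, for
#' compartment construction and chimeric-transcript tests.
#'
#' @param truth Bundle from [make_annotation()].
#' @param n_genes Number of genes.
#' @param seed Random seed.
#' @return List with `genes` (`gene_id`, `chrom`, `start`, `end`, `strand`)
#'   and `exons` (`gene_id`, `exon_number`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
make_genes <- function(truth, n_genes = 20L, seed = 1L) {
  set.seed(seed)
  tr <- truth$truth
  genes <- list(); exons <- list()
  chroms <- names(truth$chrom_lengths)
  cursor <- vapply(chroms, function(ch) {
    used <- tr[tr$chrom == ch, ]
    if (nrow(used)) max(used$end) + 20000 else 50000
  }, numeric(1))
  names(cursor) <- chroms
  for (g in seq_len(n_genes)) {
    ch <- chroms[1L + (g - 1L) %% length(chroms)]
    strand <- sample(c("+", "-"), 1L)
    start <- cursor[[ch]]
    ex_starts <- start + c(0, 3000, 7000)
    ex_len <- c(500, 400, 600)
    gid <- sprintf("gene_%03d", g)
    genes[[g]] <- data.frame(gene_id = gid, chrom = ch, start = start,
                             end = max(ex_starts + ex_len), strand = strand,
                             stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, exon_number = 1:3, chrom = ch,
                             start = ex_starts, end = ex_starts + ex_len,
                             strand = strand, stringsAsFactors = FALSE)
    cursor[[ch]] <- max(ex_starts + ex_len) + round(runif(1, 8000, 15000))
    if (cursor[[ch]] > truth$chrom_lengths[[ch]])
      stop("chromosomes too short for the requested genes", call. = FALSE)
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}
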