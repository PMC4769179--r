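hit_row <- function(read_id, chrom, start, end, n_hits = 1L, strand = "+",
                    flags = "") {
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, n_hits = n_hits, flags = flags,
             stringsAsFactors = FALSE)
}

toy_elements <- function() {
  data.frame(element_id = c("e1", "e2"), chrom = "chr1",
             start = c(1000, 2000), end = c(2000, 3000),
             strand = "+", family = c("famA", "famB"),
             stringsAsFactors = FALSE)
}

test_that("rRNA filtering removes exactly the flagged reads", {
  rec <- rbind(hit_row("r1", "chr1", 0, 50),
               hit_row("r2", "chr1", 100, 150, flags = "rRNA"),
               hit_row("r3", "chr1", 200, 250))
  out <- filter_rrna(rec)
  expect_equal(out$read_id, c("r1", "r3"))
  expect_equal(attr(out, "n_removed"), 1)
  clean <- rec[rec$flags == "", ]
  expect_equal(filter_rrna(clean)$read_id, clean$read_id)  # identity
  expect_equal(nrow(filter_rrna(clean[0, ])), 0)           # empty in/out
  ann <- demo_annotation(seed = 31)
  aln <- make_alignments(ann, "D6", rrna_fraction = 0.05, seed = 2)
  kept <- filter_rrna(aln$alignments)
  expect_equal(attr(kept, "n_removed"),
               length(unique(aln$alignments$read_id)) -
                 length(unique(kept$read_id)))
  expect_false(any(grepl("rRNA", kept$flags)))
})

test_that("exon exclusion removes reads touching exons by >= 1 bp", {
  exons <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  inside <- hit_row("r1", "chr1", 1200, 1250)
  onebp <- hit_row("r2", "chr1", 1999, 2049)   # overlaps exon by exactly 1 bp
  outside <- hit_row("r3", "chr1", 2000, 2050) # abuts, zero overlap
  rec <- rbind(inside, onebp, outside)
  out <- exclude_exonic(rec, exons)
  expect_equal(out$read_id, "r3")
})

test_that("exon exclusion can drop whole reads or just exonic hits", {
  exons <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  rec <- rbind(hit_row("r1", "chr1", 1200, 1250, n_hits = 2L),
               hit_row("r1", "chr1", 5000, 5050, n_hits = 2L))
  expect_equal(nrow(exclude_exonic(rec, exons)), 0)
  part <- exclude_exonic(rec, exons, drop_hits_only = TRUE)
  expect_equal(part$start, 5000)
  expect_equal(part$n_hits, 2L)  # weight denominator unchanged
})

test_that("80% overlap assignment is inclusive at the boundary", {
  el <- toy_elements()
  r80 <- hit_row("r1", "chr1", 1920, 2020)  # 80 of 100 bp inside e1
  r79 <- hit_row("r2", "chr1", 1921, 2021)  # 79 bp inside e1, 79 in e2
  split50 <- hit_row("r3", "chr1", 1950, 2050)  # 50/50 across e1/e2
  asg <- assign_to_elements(rbind(r80, r79, split50), el)
  expect_equal(asg$read_id, "r1")
  expect_equal(asg$element_id, "e1")
  expect_error(assign_to_elements(r80, el, min_overlap_frac = 0), "\\(0, 1\\]")
})

test_that("family counts distribute read weight over assigned hits", {
  el <- toy_elements()
  # one read, 4 hits all inside famA's element
  r4 <- do.call(rbind, lapply(1:4, function(i)
    hit_row("r1", "chr1", 1000 + 10 * i, 1100 + 10 * i, n_hits = 4L)))
  expect_equal(family_counts(assign_to_elements(r4, el)),
               c(famA = 1.0))
  # one read, 2 hits, one inside famA and one unassigned
  r2 <- rbind(hit_row("r2", "chr1", 1100, 1200, n_hits = 2L),
              hit_row("r2", "chr1", 50000, 50100, n_hits = 2L))
  expect_equal(family_counts(assign_to_elements(r2, el)),
               c(famA = 0.5))
})

test_that("weighted counts match the exhaustive per-read oracle", {
  ann <- demo_annotation(seed = 37)
  el <- reconstruct(ann)
  aln <- make_alignments(ann, "D6", depth_per_copy = 8,
                         multimap_fraction = 0.4, rrna_fraction = 0, seed = 5)
  rec <- aln$alignments
  expect_lte(length(unique(rec$read_id)), 1000)
  fc <- family_counts(assign_to_elements(rec, el))
  oracle <- brute_family_counts(rec, el)
  expect_equal(fc[sort(names(fc))], oracle[sort(names(oracle))],
               tolerance = 1e-12)
})

test_that("per-read weights are conserved and unique <= weighted", {
  ann <- demo_annotation(seed = 41)
  el <- reconstruct(ann)
  aln <- make_alignments(ann, "D6", depth_per_copy = 10,
                         multimap_fraction = 0.5, rrna_fraction = 0, seed = 6)
  asg <- assign_to_elements(aln$alignments, el)
  per_read <- tapply(asg$weight, asg$read_id, sum)
  expect_true(all(per_read <= 1 + 1e-12))
  wc <- family_counts(asg)
  uc <- family_counts(assign_to_elements(
    aln$alignments[aln$alignments$n_hits == 1L, ], el))
  shared <- intersect(names(wc), names(uc))
  expect_true(all(uc[shared] <= wc[shared] + 1e-9))
})

test_that("counts are invariant under record shuffling", {
  ann <- demo_annotation(seed = 43)
  el <- reconstruct(ann)
  rec <- make_alignments(ann, "D6", seed = 7)$alignments
  set.seed(1)
  shuf <- rec[sample(nrow(rec)), ]
  a <- family_counts(assign_to_elements(rec, el))
  b <- family_counts(assign_to_elements(shuf, el))
  expect_equal(a[sort(names(a))], b[sort(names(b))])
})

test_that("unique-mode element counts apply the 10-read floor", {
  el <- toy_elements()
  mk <- function(n, chrom = "chr1", s = 1100) {
    if (n == 0) return(hit_row("rx", "chr9", 0, 50)[0, ])
    do.call(rbind, lapply(seq_len(n), function(i)
      hit_row(paste0("u", i), chrom, s, s + 100)))
  }
  res <- element_counts(list(s1 = mk(9), s2 = mk(9), s3 = mk(9)), el)
  expect_false("e1" %in% rownames(res$counts))  # (9,9,9) dropped
  res2 <- element_counts(list(s1 = mk(10), s2 = mk(0), s3 = mk(0)), el)
  expect_true("e1" %in% rownames(res2$counts))  # (10,0,0) kept
  expect_equal(res2$counts["e1", "s1"], 10)
})

test_that("CPM and RPKM follow their definitions", {
  expect_equal(cpm(50, 1e6), 50.0)
  expect_equal(rpkm(100, 1000, 1e6), 100.0)
  expect_equal(rpkm(100, 2000, 1e6), 50.0)   # doubling length halves RPKM
  cnts <- matrix(c(10, 20, 30, 40), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lens <- c(500, 2000); libs <- c(1e5, 2e5)
  got <- rpkm(cnts, lens, libs)
  brute <- cnts
  for (i in 1:2) for (j in 1:2)
    brute[i, j] <- cnts[i, j] * 1e9 / (lens[i] * libs[j])
  expect_equal(got, brute)
  expect_error(rpkm(1, 0, 1e6), "lengths")
  expect_error(cpm(1, 0), "library")
})

test_that("GTF exons feed the chimeric caller", {
  skip_if_not_installed("rtracklayer")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1\tcuff\texon\t1201\t1500\t.\t+\t.",
          'gene_id "XLOC_1"; transcript_id "t1";', sep = "\t"),
    paste("chr1\tcuff\texon\t5101\t5300\t.\t+\t.",
          'gene_id "XLOC_1"; transcript_id "t1";', sep = "\t")), gtf)
  tx <- read_transcripts_gtf(gtf)
  expect_equal(tx$start, c(1200, 5100))   # 0-based half-open
  el <- data.frame(element_id = "te1", chrom = "chr1", start = 1000,
                   end = 1600, strand = "+", family = "RLTR9E",
                   stringsAsFactors = FALSE)
  gx <- data.frame(gene_id = "Mep1b", chrom = "chr1", start = 5000,
                   end = 5400)
  expect_equal(detect_chimeric(tx, el, gx)$gene_id, "Mep1b")
})

test_that("chimeric calls need a TE first exon and a gene exon elsewhere", {
  el <- data.frame(element_id = "te1", chrom = "chr1", start = 1000,
                   end = 1600, strand = "+", family = "RLTR9E",
                   stringsAsFactors = FALSE)
  gx <- data.frame(gene_id = "Mep1b", chrom = "chr1",
                   start = c(5000, 8000), end = c(5400, 8300))
  plus_tx <- data.frame(transcript_id = "t1", chrom = "chr1",
                        start = c(1200, 5100), end = c(1500, 5300),
                        strand = "+")
  calls <- detect_chimeric(plus_tx, el, gx)
  expect_equal(calls$transcript_id, "t1")
  expect_equal(calls$element_id, "te1")
  expect_equal(calls$gene_id, "Mep1b")

  mono <- data.frame(transcript_id = "t2", chrom = "chr1", start = 1200,
                     end = 1500, strand = "+")
  expect_equal(nrow(detect_chimeric(mono, el, gx)), 0)

  # minus strand: the 5'-most exon is the highest-coordinate one
  el2 <- data.frame(element_id = "te2", chrom = "chr1", start = 9000,
                    end = 9600, strand = "-", family = "RLTR9E",
                    stringsAsFactors = FALSE)
  minus_tx <- data.frame(transcript_id = "t3", chrom = "chr1",
                         start = c(5100, 9100), end = c(5300, 9500),
                         strand = "-")
  calls2 <- detect_chimeric(minus_tx, el2, gx)
  expect_equal(calls2$element_id, "te2")
  # same exons on + strand: first exon is the gene exon, not chimeric
  plus_same <- transform(minus_tx, strand = "+")
  expect_equal(nrow(detect_chimeric(plus_same, el2, gx)), 0)

  nostrand <- data.frame(transcript_id = "t4", chrom = "chr1",
                         start = c(1200, 5100), end = c(1500, 5300),
                         strand = ".")
  expect_warning(out <- detect_chimeric(nostrand, el, gx), "strand")
  expect_equal(nrow(out), 0)
})
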