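uniform_track <- function(count, lim = 100000, bin = 50, chrom = "chr1") {
  starts <- seq(0, lim - bin, by = bin)
  data.frame(chrom = chrom, start = starts, end = starts + bin,
             count = count, stringsAsFactors = FALSE)
}

one_element <- function(start = 10000, end = 17000, strand = "+",
                        integrity = 0.95) {
  data.frame(element_id = "e1", chrom = "chr1", start = start, end = end,
             strand = strand, family = "fam", class = "ERVK",
             integrity_score = integrity,
             is_full_length = (end - start) > 6000,
             stringsAsFactors = FALSE)
}

test_that("enrichment is 1 for identical tracks and ~2 for doubled signal", {
  el <- one_element()
  tr <- uniform_track(100)
  e <- element_enrichment(tr, tr, el)
  expect_equal(e$enrichment, 1)
  expect_equal(e$log2_enrichment, 0)

  chip <- tr
  inside <- chip$start >= el$start & chip$end <= el$end
  chip$count[inside] <- 200
  # rescale the rest so both libraries stay equal
  deficit <- sum(chip$count) - sum(tr$count)
  chip$count[!inside] <- chip$count[!inside] -
    round(deficit / sum(!inside))
  e2 <- element_enrichment(chip, tr, el)
  expect_equal(e2$enrichment, 2, tolerance = 0.02)
})

test_that("enrichment is invariant under library rescaling", {
  el <- one_element()
  set.seed(4)
  chip <- uniform_track(100); input <- uniform_track(80)
  chip$count <- rpois(nrow(chip), chip$count)
  input$count <- rpois(nrow(input), input$count)
  e1 <- element_enrichment(chip, input, el)
  chip5 <- chip; chip5$count <- chip$count * 5
  input5 <- input; input5$count <- input$count * 5
  e2 <- element_enrichment(chip5, input5, el)
  expect_equal(e2$enrichment, e1$enrichment, tolerance = 0.01)
})

test_that("elements outside covered chromosomes get missing enrichment", {
  el <- one_element()
  el$chrom <- "chrUn"
  e <- element_enrichment(uniform_track(100), uniform_track(100), el)
  expect_true(is.na(e$enrichment))
})

test_that("category calls follow the two-mark decision rules", {
  mk <- function(k9, k27) {
    base <- data.frame(element_id = "e1", family = "fam",
                       stringsAsFactors = FALSE)
    list(k9 = cbind(base, log2_enrichment = k9),
         k27 = cbind(base, log2_enrichment = k27))
  }
  b <- mk(2.0, 0.1)   # IAPEz-like: exclusive H3K9me3
  expect_equal(classify_categories(b$k9, b$k27, level = "family")$category,
               "B")
  cc <- mk(0.1, 2.0)  # MERVL-like: complete switch
  expect_equal(classify_categories(cc$k9, cc$k27, level = "family")$category,
               "C")
  a <- mk(1.0, 1.0)
  expect_equal(classify_categories(a$k9, a$k27)$category, "A")
  u <- mk(0.1, 0.1)
  expect_equal(classify_categories(u$k9, u$k27)$category, "unmarked")
})

test_that("raising tau never moves an element from unmarked to marked", {
  set.seed(5)
  base <- data.frame(element_id = sprintf("e%d", 1:50),
                     family = "fam", stringsAsFactors = FALSE)
  k9 <- cbind(base, log2_enrichment = runif(50, -1, 3))
  k27 <- cbind(base, log2_enrichment = runif(50, -1, 3))
  taus <- c(0.2, 0.5, 1.0, 2.0)
  marked <- sapply(taus, function(tau)
    classify_categories(k9, k27, tau = tau)$category != "unmarked")
  for (j in seq_len(length(taus) - 1))
    expect_true(all(marked[, j] | !marked[, j + 1]))
})

test_that("classification recovers planted categories on generated data", {
  spec <- genome_spec(list(
    family_spec("afam", "ERV1", 7000, 12, is_ltr_element = TRUE,
                category = "A"),
    family_spec("bfam", "ERVK", 7000, 12, is_ltr_element = TRUE,
                category = "B"),
    family_spec("cfam", "ERVL", 7000, 12, is_ltr_element = TRUE,
                category = "C")),
    chrom_length = 4e6, fragmentation_rate = 0, seed = 19)
  ann <- make_annotation(spec)
  el <- reconstruct(ann)
  e <- list()
  for (mk in c("H3K9me3", "H3K27me3")) {
    cov <- make_chip(ann, mk, "D13", seed = 21)
    e[[mk]] <- element_enrichment(cov$chip, cov$input, el, mk, "D13")
  }
  cls <- classify_categories(e$H3K9me3, e$H3K27me3, level = "element")
  m <- truth_match(cbind(el, predicted = cls$category), ann$truth)
  expect_equal(nrow(m), 36)
  expect_gte(mean(m$predicted == m$category), 0.95)
})

test_that("metaprofile is flat on uniform coverage with exact bin layout", {
  el <- one_element()
  mp <- metaprofile(uniform_track(100), el, n_body_bins = 40, flank = 2000,
                    flank_bin = 100)
  expect_equal(nrow(mp$profile), 20 + 40 + 20)
  expect_equal(mp$n_elements, 1)
  expect_equal(table(mp$profile$region)[["body"]], 40)
  expect_lt(diff(range(mp$profile$mean_coverage)), 1e-9)
})

test_that("metaprofile rejects element sets failing the intactness filter", {
  short <- one_element(10000, 12000)            # not full-length
  expect_error(metaprofile(uniform_track(10), short), "full-length")
  degenerate <- one_element(integrity = 0.5)    # full-length but degraded
  expect_error(metaprofile(uniform_track(10), degenerate), "integrity")
})

test_that("reversing element strand flips its metaprofile", {
  el <- one_element(strand = "+")
  tr <- uniform_track(10)
  # asymmetric signal: high over the 5' half only
  mid <- (el$start + el$end) / 2
  tr$count[tr$start >= el$start & tr$end <= mid] <- 100
  fwd <- metaprofile(tr, el, n_body_bins = 20, flank = 1000, flank_bin = 100)
  rev_el <- one_element(strand = "-")
  rev_mp <- metaprofile(tr, rev_el, n_body_bins = 20, flank = 1000,
                        flank_bin = 100)
  expect_equal(rev_mp$profile$mean_coverage,
               rev(fwd$profile$mean_coverage))
})

test_that("category-A profiles show the 5'-K9 / 3'-K27 asymmetry", {
  spec <- genome_spec(list(
    family_spec("afam", "ERV1", 8000, 10, is_ltr_element = TRUE,
                divergence_range = c(0.01, 0.05),
                deletion_range = c(0.01, 0.05),
                insertion_range = c(0.01, 0.05), category = "A")),
    chrom_length = 4e6, fragmentation_rate = 0, seed = 23)
  ann <- make_annotation(spec)
  el <- reconstruct(ann)
  k9 <- make_chip(ann, "H3K9me3", "D13", seed = 25)
  k27 <- make_chip(ann, "H3K27me3", "D13", seed = 25)
  mp9 <- metaprofile(k9$chip, el, "H3K9me3")
  mp27 <- metaprofile(k27$chip, el, "H3K27me3")
  body9 <- mp9$profile$mean_coverage[mp9$profile$region == "body"]
  body27 <- mp27$profile$mean_coverage[mp27$profile$region == "body"]
  half <- length(body9) / 2
  expect_gt(mean(body9[1:half]), 2 * mean(body9[(half + 1):(2 * half)]))
  expect_gt(mean(body27[(half + 1):(2 * half)]), 2 * mean(body27[1:half]))
})

test_that("peak annotation respects precedence and partitions the peaks", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 50000,
                      end = 60000, strand = "+")
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(50000, 55000), end = c(51000, 56000))
  comp <- make_compartments(genes, exons)
  el <- one_element(10000, 17000)   # class ERVK; LINE case below
  el$class <- "LINE"
  peaks <- data.frame(chrom = "chr1",
                      start = c(49200, 16700, 80000),
                      end = c(49800, 17200, 80500))
  # peak 1 fully in promoter; peak 2 60% LINE / 40% outside; peak 3 nothing
  out <- annotate_peaks(peaks, comp, el)
  expect_equal(sum(out$n_peaks), 3)
  expect_equal(out$n_peaks[out$annotation == "promoter"], 1)
  expect_equal(out$n_peaks[out$annotation == "LINE"], 1)
  expect_equal(out$n_peaks[out$annotation == "intergenic"], 1)

  # repeat precedence first: a peak 60% in a LINE and 40% in an intron
  exons2 <- data.frame(gene_id = "g2", chrom = "chr1",
                       start = c(17100, 30000), end = c(17200, 31000))
  genes2 <- data.frame(gene_id = "g2", chrom = "chr1", start = 17100,
                       end = 31000, strand = "+")
  comp2 <- make_compartments(genes2, exons2)
  pk <- data.frame(chrom = "chr1", start = 16400, end = 17400)
  first_repeat <- annotate_peaks(pk, comp2, el,
                                 precedence = c("repeat", "promoter", "exon",
                                                "intron", "intergenic"))
  expect_equal(first_repeat$annotation, "LINE")
})
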