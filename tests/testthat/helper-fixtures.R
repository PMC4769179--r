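# Shared fixture builders; everything is generated in code at test time.

demo_panel <- function() {
  list(
    family_spec("IAP", "ERVK", consensus_length = 7000, copy_number = 12,
                is_ltr_element = TRUE, ltr_length = 350, category = "B",
                residual_methylation = TRUE),
    family_spec("MERVL", "ERVL", consensus_length = 6500, copy_number = 10,
                is_ltr_element = TRUE, ltr_length = 500, category = "C"),
    family_spec("L1", "LINE", consensus_length = 6500, copy_number = 15,
                category = "A"),
    family_spec("B1", "SINE", consensus_length = 200, copy_number = 10,
                category = "unmarked",
                expression = c(D0 = 0.5, D6 = 0.5, D13 = 0.5))
  )
}

demo_annotation <- function(seed = 1, fragmentation_rate = 0.4,
                            nesting_rate = 0.2, chrom_length = 4e6) {
  make_annotation(genome_spec(demo_panel(), n_chromosomes = 2,
                              chrom_length = chrom_length,
                              fragmentation_rate = fragmentation_rate,
                              nesting_rate = nesting_rate, seed = seed))
}

reconstruct <- function(ann, max_gap = 5000) {
  fr <- parse_repeatmasker_out(ann$out_path)
  merge_fragments(fr, build_ltr_dictionary(fr), max_gap = max_gap)
}

# exhaustive per-read oracle for weighted family counts: loops over every
# read, every hit and every element, applying the 80% rule directly; overlap
# is summed over the element's member-fragment intervals when present
brute_family_counts <- function(records, elements, min_overlap = 0.8) {
  fi <- attr(elements, "fragment_intervals")
  if (is.null(fi)) fi <- elements[, c("element_id", "chrom", "start", "end")]
  counts <- list()
  for (rid in unique(records$read_id)) {
    hits <- records[records$read_id == rid, ]
    w <- 1 / hits$n_hits[1]
    for (h in seq_len(nrow(hits))) {
      rl <- hits$end[h] - hits$start[h]
      for (e in seq_len(nrow(elements))) {
        iv <- fi[fi$element_id == elements$element_id[e], ]
        ov <- 0
        for (k in seq_len(nrow(iv))) {
          if (iv$chrom[k] != hits$chrom[h]) next
          ov <- ov + max(0, min(hits$end[h], iv$end[k]) -
                            max(hits$start[h], iv$start[k]))
        }
        if (ov >= min_overlap * rl) {
          fam <- elements$family[e]
          counts[[fam]] <- (counts[[fam]] %||% 0) + w
        }
      }
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match reconstructed elements to ground-truth copies on coordinates
truth_match <- function(elements, truth) {
  merge(elements, truth, by = c("chrom", "start", "end"))
}
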