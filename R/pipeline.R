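# End-to-end orchestration on generated fixtures: annotation reconstruction,
# quantification, differential expression, methylation summaries and
# chromatin classification, with a YAML-round-trippable config and a
# manifest of outputs.

#' Default pipeline configuration
#'
#' All thresholds default to the study's printed values: integrity cutoff
#' 0.8, read-element overlap 0.8, unique-mode minimum 10 reads, CpG minimum
#' coverage 10, DE fold-change 4 (genes) / 2 (transposons) at BH-adjusted
#' p < 0.05, chromatin threshold tau = 0.5 (log2), metaprofile flanks 5 kb.
#'
#' @param seed Seed propagated to every stage.
#' @return Nested configuration list (round-trips through YAML losslessly).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(fixtures = TRUE, reconstruct = TRUE, quant = TRUE,
                  de = TRUE, meth = TRUE, chip = TRUE),
    fixtures = list(n_chromosomes = 2L, chrom_length = 4e6,
                    fragmentation_rate = 0.4, nesting_rate = 0.1,
                    depth_per_copy = 30, multimap_fraction = 0.3,
                    rrna_fraction = 0.05, coverage_mean = 30),
    defaults = list(integrity_cutoff = 0.8, min_overlap_frac = 0.8,
                    min_reads = 10L, min_coverage = 10L, max_gap = 5000L,
                    de = list(gene_fc = 4, te_fc = 2, alpha = 0.05,
                              alpha_genes_variant = 0.01),
                    tau = 0.5, flank = 5000L, n_body_bins = 100L,
                    rmr = list(window = 1000L, min_cpg = 5L,
                               min_meth = 0.1, merge_gap = 1000L))
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config` returns the list; `write_config` the path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# the demo family panel: the three exemplar behaviours plus background
.demo_families <- function() {
  list(
    family_spec("IAPEz", "ERVK", consensus_length = 7000, copy_number = 15,
                is_ltr_element = TRUE, ltr_length = 350, category = "B",
                residual_methylation = TRUE,
                expression = c(D0 = 0.3, D6 = 1.5, D13 = 0.5)),
    family_spec("MERVL", "ERVL", consensus_length = 6500, copy_number = 12,
                is_ltr_element = TRUE, ltr_length = 500, category = "C",
                expression = c(D0 = 0.2, D6 = 1.2, D13 = 0.3)),
    family_spec("L1Md", "LINE", consensus_length = 6500, copy_number = 20,
                category = "A",
                expression = c(D0 = 0.3, D6 = 1.0, D13 = 0.4)),
    family_spec("B1Mur", "SINE", consensus_length = 200, copy_number = 15,
                category = "unmarked",
                expression = c(D0 = 0.5, D6 = 0.5, D13 = 0.5)),
    family_spec("MTA", "ERVL", consensus_length = 2000, copy_number = 10,
                category = "unmarked",
                expression = c(D0 = 0.4, D6 = 0.5, D13 = 0.45))
  )
}

#' Run the pipeline end to end on generated fixtures
#'
#' Executes fixtures, reconstruction, quantification, differential
#' expression, methylation and chromatin stages in order, writing TSV
#' outputs and a JSON manifest (parameters, seed, per-stage paths and MD5
#' checksums) under `outdir`. Reruns with the same config are byte-identical.
#' Disabling a stage whose outputs a later stage needs makes that stage fail
#' fast with the stage name.
#'
#' @param config Configuration list from [default_config()] or a YAML path.
#' @param outdir Output directory (created if needed).
#' @return Invisible list of stage results, including the manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  d <- config$defaults
  res <- list()
  paths <- character(0)

  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stop(sprintf("stage '%s' requires outputs of disabled stage '%s'",
                   stage, dep), call. = FALSE)
  }

  if (isTRUE(st$fixtures)) {
    spec <- genome_spec(.demo_families(),
                        n_chromosomes = config$fixtures$n_chromosomes,
                        chrom_length = config$fixtures$chrom_length,
                        fragmentation_rate = config$fixtures$fragmentation_rate,
                        nesting_rate = config$fixtures$nesting_rate,
                        seed = config$seed)
    out_path <- file.path(outdir, "annotation.out")
    res$fixtures <- make_annotation(spec, out_path)
    paths <- c(paths, out_path)
  }

  if (isTRUE(st$reconstruct)) {
    need("reconstruct", "fixtures")
    frags <- parse_repeatmasker_out(res$fixtures$out_path)
    dict <- build_ltr_dictionary(frags)
    elements <- merge_fragments(frags, dict, max_gap = d$max_gap)
    cen <- census(elements, cutoff = d$integrity_cutoff)
    bed <- file.path(outdir, "elements.bed")
    tsv <- file.path(outdir, "elements.tsv")
    write_elements(elements, bed, tsv)
    .write_tsv(cen, file.path(outdir, "census.tsv"))
    res$reconstruct <- list(elements = elements, census = cen)
    paths <- c(paths, bed, tsv, file.path(outdir, "census.tsv"))
  }

  if (isTRUE(st$quant)) {
    need("quant", "reconstruct")
    elements <- res$reconstruct$elements
    samples <- expand.grid(rep = 1:2, tp = c("D0", "D6", "D13"),
                           stringsAsFactors = FALSE)
    fams <- sort(unique(res$fixtures$truth$truth$family))
    counts <- sapply(seq_len(nrow(samples)), function(i) {
      aln <- make_alignments(res$fixtures, timepoint = samples$tp[i],
                             depth_per_copy = config$fixtures$depth_per_copy,
                             multimap_fraction = config$fixtures$multimap_fraction,
                             rrna_fraction = config$fixtures$rrna_fraction,
                             seed = config$seed + i)
      rec <- filter_rrna(aln$alignments)
      asg <- assign_to_elements(rec, elements, d$min_overlap_frac)
      family_counts(asg, families = fams)
    })
    colnames(counts) <- paste0(samples$tp, "_r", samples$rep)
    .write_tsv(data.frame(family = rownames(counts), round(counts, 4)),
               file.path(outdir, "family_counts.tsv"))
    res$quant <- list(family_counts = counts, samples = samples)
    paths <- c(paths, file.path(outdir, "family_counts.tsv"))
  }

  if (isTRUE(st$de)) {
    need("de", "quant")
    counts <- res$quant$family_counts
    sel <- res$quant$samples$tp %in% c("D0", "D6")
    grp <- factor(res$quant$samples$tp[sel], levels = c("D0", "D6"))
    # genes and transposons in one table: stable genes anchor normalization
    genes <- make_gene_counts(300, sum(sel), seed = config$seed + 19L)
    combined <- rbind(counts[, sel], genes)
    f <- tmm_factors(combined)
    v <- log_cpm_with_weights(combined, f, group = grp)
    de_all <- moderated_test(v$logcpm, v$weights, grp)
    ftype <- c(rep("transposon", nrow(counts)), rep("gene", nrow(genes)))
    de_all$significant <- call_significant(de_all, ftype,
                                           alpha = d$de$alpha,
                                           te_fc = d$de$te_fc,
                                           gene_fc = d$de$gene_fc)
    de <- de_all[seq_len(nrow(counts)), ]
    tp_means <- sapply(unique(res$quant$samples$tp), function(tp)
      rowMeans(counts[, res$quant$samples$tp == tp, drop = FALSE]))
    heat <- log2_relative_to_mean(tp_means)
    de_out <- de
    for (cc in c("logFC", "t", "p", "adj_p"))
      de_out[[cc]] <- signif(de_out[[cc]], 6)
    .write_tsv(de_out, file.path(outdir, "de_results.tsv"))
    .write_tsv(data.frame(family = rownames(heat), round(heat, 4)),
               file.path(outdir, "heatmap_log2_to_mean.tsv"))
    res$de <- list(results = de, heatmap = heat)
    paths <- c(paths, file.path(outdir, "de_results.tsv"),
               file.path(outdir, "heatmap_log2_to_mean.tsv"))
  }

  if (isTRUE(st$meth)) {
    need("meth", "reconstruct")
    elements <- res$reconstruct$elements
    meth <- lapply(c(D0 = "D0", D13 = "D13"), function(tp)
      filter_cpg(make_methylome(res$fixtures, tp,
                                coverage_mean = config$fixtures$coverage_mean,
                                seed = config$seed + 7L),
                 min_cov = d$min_coverage))
    fam_means <- lapply(meth, function(m) element_summary(m, elements)$family)
    rmr <- merge_rmr(detect_rmr(meth$D13, window = d$rmr$window,
                                min_cpg = d$rmr$min_cpg,
                                min_meth = d$rmr$min_meth),
                     max_gap = d$rmr$merge_gap)
    .write_tsv(fam_means$D13, file.path(outdir, "family_methylation_D13.tsv"))
    .write_tsv(rmr, file.path(outdir, "rmr.tsv"))
    res$meth <- list(family_means = fam_means, rmr = rmr)
    paths <- c(paths, file.path(outdir, "family_methylation_D13.tsv"),
               file.path(outdir, "rmr.tsv"))
  }

  if (isTRUE(st$chip)) {
    need("chip", "reconstruct")
    elements <- res$reconstruct$elements
    enr <- list()
    for (mk in c("H3K9me3", "H3K27me3")) {
      cov <- make_chip(res$fixtures, mark = mk, timepoint = "D13",
                       seed = config$seed + 11L)
      enr[[mk]] <- element_enrichment(cov$chip, cov$input, elements,
                                      mark = mk, timepoint = "D13")
    }
    cats <- classify_categories(enr$H3K9me3, enr$H3K27me3, tau = d$tau,
                                level = "family")
    .write_tsv(cats, file.path(outdir, "chromatin_categories.tsv"))
    res$chip <- list(enrichment = enr, categories = cats)
    paths <- c(paths, file.path(outdir, "chromatin_categories.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("retroquant")),
    seed = config$seed,
    parameters = d,
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
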