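#' Pipeline configuration
#'
#' Collects every tunable of the workflow with validated defaults: the
#' 500 bp bin, the 0.75/1.25 ratio thresholds, the >=4-sample CNVR
#' frequency filter, the 0.05 FDR cutoff, and the synthetic-cohort design
#' (2 groups x 10 samples at ~7.5x). The default minimum call span here is
#' 2500 bp (5 bins): at ~37 expected reads per 500 bp bin, shorter
#' threshold runs are noise-dominated and would flood the per-group merge;
#' [segment_calls()] itself keeps the generic >500 bp retention rule as
#' its default for externally supplied data.
#'
#' @param n_per_group Samples per group.
#' @param mean_coverage Mean fold coverage.
#' @param bin_size Depth bin size in bp.
#' @param gc_bias_strength GC bias strength in the simulator.
#' @param dispersion Negative-binomial overdispersion of bin counts.
#' @param del_thresh,dup_thresh Segmentation ratio thresholds.
#' @param max_gap_bins Bridged bins per gap in segmentation.
#' @param min_len_bp Minimum call span (strictly larger than).
#' @param min_abs_z Segment z-score filter (see [segment_calls()]);
#'   default 4.
#' @param min_samples CNVR frequency-filter threshold.
#' @param alpha Enrichment FDR cutoff.
#' @param seed Master seed.
#' @param n_chrom,chrom_length,gc_window Genome design.
#' @param n_genes Genes in the synthetic model.
#' @param n_shared,n_groupA_only,n_intronic,n_intergenic,carriers_per_cnv,size_range
#'   Planted-cohort design (see [plant_cohort_cnvs()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_group = 10, mean_coverage = 7.48,
                            bin_size = 500, gc_bias_strength = 8,
                            dispersion = 0.02, del_thresh = 0.75,
                            dup_thresh = 1.25, max_gap_bins = 1,
                            min_len_bp = 2500, min_abs_z = 4,
                            min_samples = 4, alpha = 0.05,
                            seed = 1, n_chrom = 2, chrom_length = 1e6,
                            gc_window = 500, n_genes = 30, n_shared = 6,
                            n_groupA_only = 4, n_intronic = 0,
                            n_intergenic = 4, carriers_per_cnv = 6,
                            size_range = c(4000, 8000)) {
  cfg <- list(n_per_group = n_per_group, mean_coverage = mean_coverage,
              bin_size = bin_size, gc_bias_strength = gc_bias_strength,
              dispersion = dispersion, del_thresh = del_thresh,
              dup_thresh = dup_thresh, max_gap_bins = max_gap_bins,
              min_len_bp = min_len_bp, min_abs_z = min_abs_z,
              min_samples = min_samples,
              alpha = alpha, seed = seed, n_chrom = n_chrom,
              chrom_length = chrom_length, gc_window = gc_window,
              n_genes = n_genes, n_shared = n_shared,
              n_groupA_only = n_groupA_only, n_intronic = n_intronic,
              n_intergenic = n_intergenic,
              carriers_per_cnv = carriers_per_cnv, size_range = size_range)
  bad <- character()
  if (!(cfg$del_thresh > 0 && cfg$del_thresh < 1)) bad <- c(bad, "del_thresh")
  if (!(cfg$dup_thresh > 1)) bad <- c(bad, "dup_thresh")
  if (cfg$min_len_bp < 0) bad <- c(bad, "min_len_bp")
  if (cfg$min_samples < 1) bad <- c(bad, "min_samples")
  if (!(cfg$alpha >= 0 && cfg$alpha <= 1)) bad <- c(bad, "alpha")
  if (cfg$n_per_group < 4) bad <- c(bad, "n_per_group")
  if (cfg$bin_size < 1) bad <- c(bad, "bin_size")
  if (length(bad)) {
    abort("invalid configuration field(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the whole workflow on a seeded synthetic cohort
#'
#' Generates a genome, gene model, planted two-group cohort and depth
#' profiles, then runs calling, per-group CNVR merging with the frequency
#' filter, gene annotation with intronic removal, the two-group
#' comparison, term enrichment of the differential genes, and
#' delta-delta-Ct validation of a panel of planted loci against the
#' sequencing copy numbers. Fixed seed, identical bundle.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory for the report bundle (summary TSVs,
#'   gene lists, BED/VCF/bedGraph tracks, enrichment and qPCR tables).
#' @return List with every stage's objects: genome, genes, cohort, calls,
#'   summaries, cnvrs (per group), annotated (per group), gene_sets, diff,
#'   enrichment, qpcr, call_eval.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)

  genome <- make_genome(config$n_chrom, config$chrom_length,
                        config$gc_window, seed = seed)
  genes <- make_genes(genome, n_genes = config$n_genes,
                      seed = seed + 1L)
  cohort <- plant_cohort_cnvs(
    genome, genes, n_per_group = config$n_per_group,
    n_shared = config$n_shared, n_groupA_only = config$n_groupA_only,
    n_intronic = config$n_intronic, n_intergenic = config$n_intergenic,
    carriers_per_cnv = config$carriers_per_cnv,
    size_range = config$size_range, seed = seed + 2L
  )
  profiles <- simulate_cohort_depth(
    genome, cohort, mean_coverage = config$mean_coverage,
    bin_size = config$bin_size,
    gc_bias_strength = config$gc_bias_strength,
    dispersion = config$dispersion, seed = seed + 3L
  )

  calls <- call_cohort(profiles, del_thresh = config$del_thresh,
                       dup_thresh = config$dup_thresh,
                       max_gap_bins = config$max_gap_bins,
                       min_len_bp = config$min_len_bp,
                       min_abs_z = config$min_abs_z)
  call_eval <- evaluate_calls(calls, cohort)

  samples <- cohort$samples
  groups <- unique(samples$group)
  group_calls <- lapply(groups, function(g) {
    calls[calls$sample_id %in% samples$sample_id[samples$group == g], ,
          drop = FALSE]
  })
  names(group_calls) <- groups
  summaries <- do.call(rbind, lapply(groups, function(g) {
    summarize_group(group_calls[[g]], sum(samples$group == g), g)
  }))
  summaries <- rbind(summaries, combine_summaries(summaries))

  cnvrs <- merge_by_group(calls, samples, min_samples = config$min_samples)
  annotated <- lapply(cnvrs, overlap_genes, model = genes)
  gene_sets <- lapply(annotated, gene_set)
  diff <- differential_genes(gene_sets$long_hair, gene_sets$normal_hair)

  population <- genes$genes$gene_id
  term_map <- make_term_map(
    population, n_terms = 20, term_size = 5,
    planted = list("TERM:DIFF" = diff$differential),
    seed = seed + 4L
  )
  enr <- if (length(diff$differential)) {
    enrich(diff$differential, term_map, population, alpha = config$alpha)
  } else {
    enrich(character(), term_map, population, alpha = config$alpha)
  }

  ## qPCR panel: planted loci across 6 + 6 individuals, calibrators are
  ## non-carrier samples (diploid at every panel locus)
  panel <- utils::head(cohort$cnvs$cnv_id, 8)
  qp <- NULL
  if (length(panel)) {
    picked <- c(utils::head(samples$sample_id[samples$group == "long_hair"], 6),
                utils::head(samples$sample_id[samples$group == "normal_hair"], 6))
    truth <- expand.grid(sample_id = picked, target_id = panel,
                         stringsAsFactors = FALSE)
    carr_key <- paste(cohort$carriers$sample_id, cohort$carriers$cnv_id)
    idx <- match(paste(truth$sample_id, truth$target_id), carr_key)
    truth$copy_number <- ifelse(is.na(idx), 2,
                                cohort$carriers$copy_number[idx])
    calib <- unique(truth$sample_id[
      !truth$sample_id %in%
        cohort$carriers$sample_id[cohort$carriers$cnv_id %in% panel]])
    if (length(calib) == 0) {
      ## add a synthetic diploid calibrator when every picked sample
      ## carries some panel locus
      truth <- rbind(truth, data.frame(sample_id = "CAL_01",
                                       target_id = panel, copy_number = 2))
      calib <- "CAL_01"
    }
    ct <- simulate_qpcr(truth, ct_noise_sd = 0.15, seed = seed + 5L)
    est <- delta_delta_ct(ct, calibrator_samples = calib)
    conc <- concordance(est, truth)
    qp <- list(truth = truth, ct = ct, estimates = est, calibrators = calib,
               concordance = conc)
  }

  res <- list(config = config, genome = genome, genes = genes,
              cohort = cohort, calls = calls, call_eval = call_eval,
              summaries = summaries, cnvrs = cnvrs, annotated = annotated,
              gene_sets = gene_sets, diff = diff, enrichment = enr,
              qpcr = qp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    w(summaries, "cnv_summary.tsv")
    write_gff3(genes, file.path(out_dir, "genes.gff3"))
    for (g in names(cnvrs)) {
      write_bed(cnvrs[[g]], file.path(out_dir, paste0("cnvrs_", g, ".bed")))
      write_vcf(cnvrs[[g]], file.path(out_dir, paste0("cnvrs_", g, ".vcf")),
                chrom_lengths = genome$chrom_lengths)
      writeLines(gene_sets[[g]], file.path(out_dir,
                                           paste0("genes_", g, ".txt")))
      write_bedgraph(cnvr_density(cnvrs[[g]], window = 1e5,
                                  chrom_lengths = genome$chrom_lengths),
                     file.path(out_dir, paste0("cnvr_density_", g,
                                               ".bedgraph")))
    }
    writeLines(diff$differential, file.path(out_dir,
                                            "differential_genes.txt"))
    w(enr, "enrichment.tsv")
    if (!is.null(qp)) {
      w(qp$estimates, "qpcr_estimates.tsv")
      utils::write.csv(qp$ct, file.path(out_dir, "qpcr_ct.csv"),
                       row.names = FALSE)
    }
  }
  res
}
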