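#!/usr/bin/env Rscript
# Stage 1: build the synthetic study — genome, gene model, planted
# two-group cohort and per-sample depth profiles. Later stages read the
# RDS bundle this writes.

suppressPackageStartupMessages(library(yakcnv))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- pipeline_config(seed = 1)
seed <- as.integer(config$seed)

genome <- make_genome(config$n_chrom, config$chrom_length, config$gc_window,
                      seed = seed)
genes <- make_genes(genome, n_genes = config$n_genes, seed = seed + 1L)
cohort <- plant_cohort_cnvs(
  genome, genes, n_per_group = config$n_per_group,
  n_shared = config$n_shared, n_groupA_only = config$n_groupA_only,
  n_intronic = config$n_intronic, n_intergenic = config$n_intergenic,
  carriers_per_cnv = config$carriers_per_cnv,
  size_range = config$size_range, seed = seed + 2L
)
profiles <- simulate_cohort_depth(
  genome, cohort, mean_coverage = config$mean_coverage,
  bin_size = config$bin_size, gc_bias_strength = config$gc_bias_strength,
  dispersion = config$dispersion, seed = seed + 3L
)

write_gff3(genes, file.path(out_dir, "genes.gff3"))
write.table(cohort$cnvs, file.path(out_dir, "planted_cnvs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$carriers, file.path(out_dir, "planted_carriers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(config = config, genome = genome, genes = genes,
             cohort = cohort, profiles = profiles),
        file.path(out_dir, "stage1_simulation.rds"))

print(genome)
print(genes)
print(cohort)
cat(sprintf("truth: %d group-A genes, %d group-B genes, %d differential\n",
            length(cohort$gene_truth$genes_a),
            length(cohort$gene_truth$genes_b),
            length(cohort$gene_truth$differential)))
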