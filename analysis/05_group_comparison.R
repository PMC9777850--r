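#!/usr/bin/env Rscript
# Stage 5: per-group summary table, CNV size histogram and windowed CNVR
# density tracks.

suppressPackageStartupMessages(library(yakcnv))

out_dir <- "results"
st <- readRDS(file.path(out_dir, "stage1_simulation.rds"))
calls <- readRDS(file.path(out_dir, "stage2_calls.rds"))
cnvrs <- readRDS(file.path(out_dir, "stage3_cnvrs.rds"))

samples <- st$cohort$samples
groups <- unique(samples$group)
summaries <- do.call(rbind, lapply(groups, function(g) {
  gc <- calls[calls$sample_id %in% samples$sample_id[samples$group == g], ]
  summarize_group(gc, sum(samples$group == g), g)
}))
summaries <- rbind(summaries, combine_summaries(summaries))
write.table(summaries, file.path(out_dir, "cnv_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(summaries, digits = 4)

sizes_kb <- (calls$end - calls$start) / 1000
edges <- c(0.5, 1, 2, 5, 10, 20, 50, max(100, ceiling(max(sizes_kb))))
hist_tab <- size_histogram(calls, edges)
write.table(hist_tab, file.path(out_dir, "size_histogram.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (g in names(cnvrs)) {
  track <- cnvr_density(cnvrs[[g]], window = 1e5,
                        chrom_lengths = st$genome$chrom_lengths)
  write_bedgraph(track, file.path(out_dir,
                                  paste0("cnvr_density_", g, ".bedgraph")))
}
cat("wrote summary, size histogram and density tracks to", out_dir, "\n")
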