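#!/usr/bin/env Rscript
# Stage 3: merge calls into CNVRs within each group (single-linkage,
# >= 1 bp overlap) and apply the >= 4-sample frequency filter.

suppressPackageStartupMessages(library(yakcnv))

out_dir <- "results"
st <- readRDS(file.path(out_dir, "stage1_simulation.rds"))
calls <- readRDS(file.path(out_dir, "stage2_calls.rds"))

cnvrs <- merge_by_group(calls, st$cohort$samples,
                        min_samples = st$config$min_samples)
for (g in names(cnvrs)) {
  write_bed(cnvrs[[g]], file.path(out_dir, paste0("cnvrs_", g, ".bed")))
  write_vcf(cnvrs[[g]], file.path(out_dir, paste0("cnvrs_", g, ".vcf")),
            chrom_lengths = st$genome$chrom_lengths)
  cat(g, ":", nrow(cnvrs[[g]]), "CNVRs after the frequency filter\n")
}
saveRDS(cnvrs, file.path(out_dir, "stage3_cnvrs.rds"))
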