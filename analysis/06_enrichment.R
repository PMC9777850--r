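#!/usr/bin/env Rscript
# Stage 6: hypergeometric term enrichment of the differential gene set
# with Benjamini-Hochberg adjustment (alpha = 0.05). The synthetic term
# map plants one term covering the differential genes so the test has a
# true positive to find.

suppressPackageStartupMessages(library(yakcnv))

out_dir <- "results"
st <- readRDS(file.path(out_dir, "stage1_simulation.rds"))
ann <- readRDS(file.path(out_dir, "stage4_annotation.rds"))

population <- st$genes$genes$gene_id
term_map <- make_term_map(population, n_terms = 20, term_size = 5,
                          planted = list("TERM:DIFF" = ann$diff$differential),
                          seed = as.integer(st$config$seed) + 4L)
res <- enrich(ann$diff$differential, term_map, population,
              alpha = st$config$alpha)
write.table(res, file.path(out_dir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(head(res))
cat(sum(res$significant), "term(s) significant at adjusted p <=",
    st$config$alpha, "\n")
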