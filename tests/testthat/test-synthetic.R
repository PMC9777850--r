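test_that("make_genome is seeded, bounded and well shaped", {
  g1 <- make_genome(n_chrom = 2, chrom_length = 1e5, gc_window = 500, seed = 9)
  g2 <- make_genome(n_chrom = 2, chrom_length = 1e5, gc_window = 500, seed = 9)
  g3 <- make_genome(n_chrom = 2, chrom_length = 1e5, gc_window = 500, seed = 10)
  expect_identical(g1, g2)
  expect_false(identical(g1$gc, g3$gc))
  expect_equal(g1$chrom_names, c("chr1", "chr2"))
  expect_true(all(unlist(g1$gc) >= 0.25 & unlist(g1$gc) <= 0.65))
  expect_length(g1$gc$chr1, 200)
  expect_error(make_genome(n_chrom = 1, chrom_length = 100, gc_window = 500),
               "10 GC windows")
})

test_that("make_genes places non-overlapping genes with clear flanks", {
  g <- make_genome(seed = 1)
  gm <- make_genes(g, n_genes = 25, seed = 2)
  expect_s3_class(gm, "gene_model")
  expect_equal(nrow(gm$genes), 25)
  expect_equal(nrow(gm$exons), 75)
  for (chrom in unique(gm$genes$chrom)) {
    gg <- gm$genes[gm$genes$chrom == chrom, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      gaps <- gg$start[-1] - gg$end[-nrow(gg)]
      expect_true(all(gaps >= 11000))
    }
  }
  ## first exon starts at the gene start, last ends at the gene end
  for (i in seq_len(nrow(gm$genes))) {
    ex <- gm$exons[gm$exons$gene_id == gm$genes$gene_id[i], ]
    expect_equal(min(ex$start), gm$genes$start[i])
    expect_equal(max(ex$end), gm$genes$end[i])
  }
  expect_error(make_genes(g, n_genes = 1e5), "infeasible packing")
  empty <- make_genes(g, n_genes = 0)
  expect_equal(nrow(empty$genes), 0)
})

test_that("plant_cohort_cnvs builds a consistent truth table", {
  g <- make_genome(seed = 3)
  gm <- make_genes(g, n_genes = 30, seed = 4)
  co <- plant_cohort_cnvs(g, gm, n_intronic = 2, seed = 5)
  expect_s3_class(co, "planted_cohort")
  expect_equal(nrow(co$samples), 20)
  expect_equal(sum(co$samples$group == "long_hair"), 10)
  ## carrier counts: 6 per group for shared, 6 group-A-only
  tab <- table(co$carriers$cnv_id)
  scope <- co$cnvs$scope[match(names(tab), co$cnvs$cnv_id)]
  expect_true(all(tab[scope == "both"] == 12))
  expect_true(all(tab[scope == "group_a"] == 6))
  ## group-A-only CNVs carried only by long-hair samples
  a_only <- co$cnvs$cnv_id[co$cnvs$scope == "group_a"]
  expect_true(all(co$carriers$group[co$carriers$cnv_id %in% a_only] ==
                    "long_hair"))
  ## nesting: normal-hair truth genes are a subset of long-hair truth genes
  expect_true(all(co$gene_truth$genes_b %in% co$gene_truth$genes_a))
  expect_setequal(co$gene_truth$differential,
                  setdiff(co$gene_truth$genes_a, co$gene_truth$genes_b))
  ## truth invariant: every truth gene's exons intersect some planted
  ## interval of the right scope (brute force)
  brute <- function(rows) {
    hit <- character()
    for (i in seq_len(nrow(rows))) {
      ex <- gm$exons
      ov <- ex$chrom == rows$chrom[i] &
        pmin(ex$end, rows$end[i]) - pmax(ex$start, rows$start[i]) > 0
      hit <- c(hit, ex$gene_id[ov])
    }
    sort(unique(hit))
  }
  expect_identical(co$gene_truth$genes_a, brute(co$cnvs))
  expect_identical(co$gene_truth$genes_b,
                   brute(co$cnvs[co$cnvs$scope == "both", ]))
  ## intronic plants sit strictly inside intron 1 (no exon overlap)
  intr <- co$cnvs[co$cnvs$category == "intronic", ]
  expect_equal(nrow(intr), 2)
  for (i in seq_len(nrow(intr))) {
    ex <- gm$exons[gm$exons$gene_id == intr$gene_id[i], ]
    expect_false(any(pmin(ex$end, intr$end[i]) -
                       pmax(ex$start, intr$start[i]) > 0))
  }
  ## intergenic plants overlap no gene span
  inter <- co$cnvs[co$cnvs$category == "intergenic", ]
  for (i in seq_len(nrow(inter))) {
    gg <- gm$genes[gm$genes$chrom == inter$chrom[i], ]
    expect_false(any(pmin(gg$end, inter$end[i]) -
                       pmax(gg$start, inter$start[i]) > 0))
  }
  expect_error(plant_cohort_cnvs(g, gm, carriers_per_cnv = 3),
               "carriers_per_cnv")
  expect_error(plant_cohort_cnvs(g, gm, cn_pool = c(2, 3)), "cn_pool")
})

test_that("simulate_depth respects copy number, GC bias and determinism", {
  g <- make_genome(n_chrom = 1, chrom_length = 2e5, seed = 6)
  planted <- data.frame(chrom = "chr1", start = 50000L, end = 60000L,
                        copy_number = 0)
  p <- simulate_depth(g, planted, deterministic = TRUE)
  expect_s3_class(p, "depth_profile")
  expect_equal(nrow(p), 400)
  in_del <- p$start >= 50000 & p$end <= 60000
  expect_true(all(p$count[in_del] == 0))
  ## deterministic diploid expectation without GC bias
  expect_equal(unique(p$count[!in_del]), 7.48 * 500 / 100)
  ## CN 4 doubles the expectation
  p4 <- simulate_depth(g, transform(planted, copy_number = 4),
                       deterministic = TRUE)
  expect_equal(unique(p4$count[in_del]), 2 * 7.48 * 500 / 100)
  ## GC bias multiplies by exp(-s (gc - 0.45)^2)
  pb <- simulate_depth(g, NULL, gc_bias_strength = 10, deterministic = TRUE)
  expect_equal(pb$count, 37.4 * exp(-10 * (pb$gc - 0.45)^2))
  ## stochastic draws are seeded
  s1 <- simulate_depth(g, NULL, seed = 11)
  s2 <- simulate_depth(g, NULL, seed = 11)
  expect_identical(s1, s2)
  ## Poisson mode at dispersion 0 has roughly the right mean
  sp <- simulate_depth(g, NULL, dispersion = 0, seed = 12)
  expect_lt(abs(mean(sp$count) - 37.4), 1)
})

test_that("simulate_cohort_depth yields one seeded profile per sample", {
  g <- make_genome(n_chrom = 1, chrom_length = 1e5, seed = 7)
  gm <- make_genes(g, n_genes = 2, seed = 8)
  co <- plant_cohort_cnvs(g, gm, n_shared = 1, n_groupA_only = 1,
                          n_intergenic = 0, seed = 9)
  profs <- simulate_cohort_depth(g, co, seed = 10)
  expect_named(profs, co$samples$sample_id)
  expect_identical(profs, simulate_cohort_depth(g, co, seed = 10))
  ## carriers of the planted deletion/duplication differ from non-carriers
  cnv <- co$cnvs[1, ]
  carr <- co$carriers$sample_id[co$carriers$cnv_id == cnv$cnv_id][1]
  non <- setdiff(co$samples$sample_id,
                 co$carriers$sample_id[co$carriers$cnv_id == cnv$cnv_id])[1]
  sel <- function(p) mean(p$count[p$start >= cnv$start & p$end <= cnv$end])
  if (cnv$copy_number < 2) {
    expect_lt(sel(profs[[carr]]), sel(profs[[non]]))
  } else {
    expect_gt(sel(profs[[carr]]), sel(profs[[non]]))
  }
})

test_that("simulate_qpcr encodes copy number in Ct and make_term_map plants terms", {
  truth <- data.frame(sample_id = c("s1", "s2"), target_id = "t1",
                      copy_number = c(4, 0))
  ct <- simulate_qpcr(truth, ct_noise_sd = 0, seed = 1)
  expect_equal(nrow(ct), 6)
  expect_equal(ct$target_ct[ct$sample_id == "s1"], rep(20 + 2 - 1, 3))
  expect_equal(ct$target_ct[ct$sample_id == "s2"], rep(38, 3))
  expect_error(simulate_qpcr(data.frame(sample_id = "s")), "columns")
  tm <- make_term_map(letters, n_terms = 5, term_size = 3,
                      planted = list(MY = c("a", "b")), seed = 2)
  expect_length(tm, 6)
  expect_equal(tm$MY, c("a", "b"))
})
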