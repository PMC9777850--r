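mk_calls <- function(n_dup, n_del, size_bp = 2000L) {
  n <- n_dup + n_del
  data.frame(sample_id = rep("S1", n), chrom = rep("chr1", n),
             start = seq(0L, by = size_bp * 2L, length.out = n),
             end = seq(0L, by = size_bp * 2L, length.out = n) + size_bp,
             svtype = rep(c("DUP", "DEL"), c(n_dup, n_del)),
             stringsAsFactors = FALSE)
}

test_that("summarize_group computes counts, rounded means and kb sizes", {
  calls <- mk_calls(3, 2)
  s <- summarize_group(calls, n_samples = 2, group_name = "g")
  expect_equal(s$n_cnvs, 5)
  expect_equal(s$n_dup, 3)
  expect_equal(s$n_del, 2)
  expect_equal(s$mean_cnvs_per_individual, 3)  # 2.5 rounds half away
  expect_equal(s$size_mean_kb, 2)
  expect_equal(s$size_min_kb, 2)
  empty <- summarize_group(mk_calls(0, 0), 4, "empty")
  expect_equal(empty$n_cnvs, 0)
  expect_equal(empty$mean_cnvs_per_individual, 0)
})

test_that("combine_summaries recomputes the mean from totals, not from means", {
  a <- summarize_group(mk_calls(9, 0), n_samples = 2, group_name = "a")
  b <- summarize_group(mk_calls(0, 2, size_bp = 4000L), 2, "b")
  tot <- combine_summaries(rbind(a, b))
  expect_equal(tot$n_cnvs, 11)
  expect_equal(tot$n_samples, 4)
  ## 11/4 = 2.75 -> 3; the mean of the rounded group means would be 4
  expect_equal(tot$mean_cnvs_per_individual, 3)
  expect_equal(tot$n_dup, 9)
  expect_equal(tot$n_del, 2)
  expect_equal(tot$size_mean_kb, (9 * 2 + 2 * 4) / 11)
  expect_true(is.na(tot$size_median_kb))
  expect_equal(tot$size_max_kb, 4)
  expect_error(combine_summaries(a[0, ]), "at least one")
})

test_that("differential_genes does set algebra and flags nesting", {
  d <- differential_genes(c("g1", "g2", "g3"), c("g2"))
  expect_equal(d$shared, "g2")
  expect_equal(d$only_a, c("g1", "g3"))
  expect_equal(d$only_b, character())
  expect_equal(d$differential, c("g1", "g3"))
  expect_true(d$nested_b_in_a)
  d2 <- differential_genes(c("g1", "g2"), c("g2", "g9"))
  expect_false(d2$nested_b_in_a)
  expect_setequal(d2$differential, c("g1", "g9"))
  ## duplicates and ordering do not matter
  d3 <- differential_genes(c("g2", "g1", "g1"), c("g2"))
  expect_equal(d3$genes_a, c("g1", "g2"))
})

test_that("cnvr_density counts regions by midpoint window", {
  cnvrs <- rbind(toy_cnvr("chr1", 0L, 1000L),       # mid 500  -> window 1
                 toy_cnvr("chr1", 900L, 1200L),     # mid 1050 -> window 2
                 toy_cnvr("chr1", 1900L, 2100L))    # mid 2000 -> window 3
  d <- cnvr_density(cnvrs, window = 1000, chrom_lengths = c(chr1 = 3000))
  expect_equal(d$count, c(1L, 1L, 1L))
  expect_equal(d$end, c(1000L, 2000L, 3000L))
  ## a midpoint on the last base clamps into the final window
  edge <- cnvr_density(toy_cnvr("chr1", 2900L, 3100L), window = 1000,
                       chrom_lengths = c(chr1 = 3000))
  expect_equal(edge$count, c(0L, 0L, 1L))
  none <- cnvr_density(cnvrs[0, ], window = 1000)
  expect_equal(nrow(none), 0)
})

test_that("size_histogram uses right-closed kb bins and validates the range", {
  calls <- data.frame(sample_id = "S", chrom = "chr1",
                      start = c(0L, 0L, 0L), end = c(1000L, 2000L, 2500L),
                      svtype = "DUP", stringsAsFactors = FALSE)
  h <- size_histogram(calls, bin_edges_kb = c(0.5, 1, 2, 3))
  expect_equal(h$count, c(1L, 1L, 1L))  # 1 kb lands in (0.5,1]
  expect_equal(sum(h$count), nrow(calls))
  expect_error(size_histogram(calls, c(1, 2, 3)), "outside")
  expect_error(size_histogram(calls, c(2, 1)), "strictly increasing")
})
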