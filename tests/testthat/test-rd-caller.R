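mk_profile <- function(counts, gc = rep(0.5, length(counts)), bin = 100L,
                       sample_id = "S01") {
  n <- length(counts)
  depth_profile(
    data.frame(chrom = "chr1", start = seq(0L, by = bin, length.out = n),
               end = seq(bin, by = bin, length.out = n), gc = gc,
               count = counts),
    sample_id = sample_id, bin_size = bin
  )
}

test_that("gc_correct inverts a multiplicative GC bias exactly", {
  g <- make_genome(n_chrom = 1, chrom_length = 2e5, seed = 21)
  p <- simulate_depth(g, NULL, gc_bias_strength = 12, deterministic = TRUE)
  corrected <- gc_correct(p)
  expect_true(attr(corrected, "gc_corrected"))
  ## within each GC stratum the bias is a constant, so after median-ratio
  ## correction every well-populated stratum sits exactly on the global
  ## median; overall spread collapses to stratum-rounding error
  expect_lt(stats::mad(corrected$count) / stats::median(corrected$count),
            0.02)
  expect_lt(stats::mad(p$count) / stats::median(p$count) * 0.5,
            stats::mad(corrected$count) / stats::median(corrected$count) + 0.2)
})

test_that("gc_correct borrows factors for sparse strata and warns on degenerate input", {
  ## 200 bins at gc 0.50 with depth 40, 2 bins at gc 0.30 with depth 10:
  ## the sparse stratum borrows the 0.50 factor (=1), leaving the low bins
  ## low (they are signal, not stratum artifacts)
  p <- mk_profile(c(rep(40, 200), 10, 10), gc = c(rep(0.5, 200), 0.3, 0.3))
  corrected <- gc_correct(p)
  expect_equal(corrected$count[201:202], c(10, 10))
  expect_warning(gc_correct(mk_profile(rep(0, 120))), "all-zero")
  expect_warning(gc_correct(mk_profile(rep(40, 50))), "fewer than 100")
})

test_that("normalize_depth sets a median-robust diploid baseline", {
  p <- mk_profile(c(rep(40, 90), rep(80, 10)))
  n <- normalize_depth(p)
  expect_equal(attr(n, "diploid_depth"), 40)
  expect_equal(n$ratio[1], 1)
  expect_equal(n$ratio[95], 2)
  expect_error(normalize_depth(mk_profile(rep(0, 10))), "median depth is 0")
})

test_that("segment_calls finds threshold runs with the strict >min_len rule", {
  ## deletion and duplication runs of 6 bins (600 bp) each
  counts <- rep(40, 60)
  counts[11:16] <- 10     # ratio 0.25 -> DEL
  counts[31:36] <- 80     # ratio 2    -> DUP
  calls <- segment_calls(normalize_depth(mk_profile(counts)))
  expect_equal(nrow(calls), 2)
  del <- calls[calls$svtype == "DEL", ]
  dup <- calls[calls$svtype == "DUP", ]
  expect_equal(c(del$start, del$end), c(1000, 1600))
  expect_equal(c(dup$start, dup$end), c(3000, 3600))
  expect_equal(del$copy_number, 1)  # 2 * 0.25 = 0.5 rounds half away to 1
  expect_equal(dup$copy_number, 4)
  ## exactly-500 bp candidates are dropped: retention is strictly > 500
  counts5 <- rep(40, 60); counts5[11:15] <- 10
  expect_equal(nrow(segment_calls(normalize_depth(mk_profile(counts5)))), 0)
  counts5b <- rep(40, 60); counts5b[11:15] <- 10
  expect_equal(nrow(segment_calls(normalize_depth(mk_profile(counts5b)),
                                  min_len_bp = 499)), 1)
})

test_that("gap bridging joins runs but never across opposite-type bins", {
  counts <- rep(40, 40)
  counts[11:13] <- 10
  counts[14] <- 40          # single non-qualifying gap bin
  counts[15:17] <- 10
  calls <- segment_calls(normalize_depth(mk_profile(counts)),
                         max_gap_bins = 1, min_len_bp = 200)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(1000, 1700))
  ## same geometry, but the gap bin qualifies as DUP: no bridge
  counts[14] <- 80
  calls2 <- segment_calls(normalize_depth(mk_profile(counts)),
                          max_gap_bins = 1, min_len_bp = 200)
  expect_equal(sum(calls2$svtype == "DEL"), 2)
  ## max_gap_bins = 0 also keeps them apart
  counts[14] <- 40
  calls3 <- segment_calls(normalize_depth(mk_profile(counts)),
                          max_gap_bins = 0, min_len_bp = 200)
  expect_equal(nrow(calls3), 2)
  ## calls never overlap within a sample
  ir <- IRanges::IRanges(calls2$start + 1L, calls2$end)
  expect_equal(length(IRanges::reduce(ir)), length(ir))
})

test_that("the segment z-score filter drops marginal runs and keeps real ones", {
  set.seed(31)
  counts <- rpois(400, 40)
  counts[101:110] <- rpois(10, 20)   # true heterozygous deletion, ratio ~0.5
  p <- normalize_depth(mk_profile(counts))
  loose <- segment_calls(p, min_abs_z = 0, min_len_bp = 300)
  strict <- segment_calls(p, min_abs_z = 4, min_len_bp = 300)
  ## the real deletion survives the filter...
  expect_true(any(loose$start <= 10000 & loose$end >= 11000))
  expect_true(any(strict$start <= 10000 & strict$end >= 11000))
  ## ...and the strict set is exactly the loose calls whose segment
  ## z-score clears the bar
  cv <- stats::mad(p$ratio)
  z <- abs(loose$rd_ratio - 1) *
    sqrt((loose$end - loose$start) / 100) / cv
  key <- function(d) paste(d$start, d$end, d$svtype)
  expect_setequal(key(strict), key(loose)[z > 4])
  ## the bar is meaningful: a 4-bin run at ratio 0.72 would fail it while
  ## the real 10-bin half-depth deletion passes comfortably
  expect_lt(abs(0.72 - 1) * sqrt(4) / cv, 4)
  expect_gt(abs(0.5 - 1) * sqrt(10) / cv, 4)
})

test_that("call_sample and call_cohort wire the stages together", {
  g <- make_genome(n_chrom = 1, chrom_length = 3e5, seed = 41)
  planted <- data.frame(chrom = "chr1", start = 100000L, end = 110000L,
                        copy_number = 0)
  p <- simulate_depth(g, planted, gc_bias_strength = 5, seed = 42,
                      sample_id = "S01")
  calls <- call_sample(p, min_len_bp = 2500, min_abs_z = 4)
  hit <- calls[calls$svtype == "DEL" & calls$start < 110000 &
                 calls$end > 100000, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$start - 100000), 1500)
  expect_lt(abs(hit$end - 110000), 1500)
  expect_equal(hit$copy_number, 0)
  p2 <- p
  attr(p2, "sample_id") <- "S02"
  cohort_calls <- call_cohort(list(S01 = p, S02 = p2), min_len_bp = 2500,
                              min_abs_z = 4)
  expect_setequal(unique(cohort_calls$sample_id), c("S01", "S02"))
})

test_that("evaluate_calls applies reciprocal overlap per sample and type", {
  g <- make_genome(n_chrom = 1, chrom_length = 1e5, seed = 51)
  gm <- make_genes(g, n_genes = 1, seed = 52)
  co <- plant_cohort_cnvs(g, gm, n_shared = 1, n_groupA_only = 0,
                          n_intergenic = 0, cn_pool = 0, seed = 53)
  cnv <- co$cnvs[1, ]
  carr <- co$carriers$sample_id[1]
  perfect <- data.frame(sample_id = carr, chrom = cnv$chrom,
                        start = cnv$start, end = cnv$end, svtype = "DEL",
                        stringsAsFactors = FALSE)
  ev <- evaluate_calls(perfect, co)
  expect_equal(ev$recall, 1 / nrow(co$carriers))
  expect_equal(ev$precision, 1)
  ## wrong direction never matches
  ev2 <- evaluate_calls(transform(perfect, svtype = "DUP"), co)
  expect_equal(ev2$precision, 0)
  ## sliver overlap fails the reciprocal-overlap bar
  sliver <- transform(perfect, start = cnv$end - 100L, end = cnv$end + 5000L)
  expect_equal(evaluate_calls(sliver, co)$precision, 0)
})
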