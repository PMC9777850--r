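test_that("merge_cnvrs unions overlapping calls with boundary extension", {
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    chrom = "chr1",
    start = c(100L, 150L, 400L, 390L),
    end = c(200L, 260L, 500L, 480L),
    svtype = c("DUP", "DUP", "DEL", "DUP"),
    stringsAsFactors = FALSE
  )
  r <- merge_cnvrs(calls)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(100L, 390L))
  expect_equal(r$end, c(260L, 500L))
  expect_equal(r$frequency, c(2L, 2L))
  expect_equal(r$cnvr_class, c("gain", "mixed"))
  expect_equal(r$cnvr_id, c("chr1:100-260", "chr1:390-500"))
})

test_that("abutting half-open intervals are not merged; 1 bp overlap is", {
  ab <- data.frame(sample_id = c("S1", "S2"), chrom = "chr1",
                   start = c(0L, 100L), end = c(100L, 200L),
                   svtype = "DEL", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_cnvrs(ab)), 2)
  one <- transform(ab, start = c(0L, 99L))
  expect_equal(nrow(merge_cnvrs(one)), 1)
})

test_that("a sample with several member calls counts once; DUP+DEL is 'both'", {
  calls <- data.frame(
    sample_id = c("S1", "S1", "S2"),
    chrom = "chr1", start = c(0L, 50L, 80L), end = c(60L, 100L, 150L),
    svtype = c("DUP", "DEL", "DEL"), stringsAsFactors = FALSE
  )
  r <- merge_cnvrs(calls)
  expect_equal(nrow(r), 1)
  expect_equal(r$frequency, 2L)
  expect_equal(r$svtypes, "both,DEL")
  expect_equal(r$cnvr_class, "mixed")
})

test_that("merge_cnvrs matches the brute-force per-base oracle on random instances", {
  set.seed(2024)
  for (rep in seq_len(300)) {
    calls <- random_calls(sample.int(12, 1))
    r <- merge_cnvrs(calls)
    for (chrom in unique(calls$chrom)) {
      cc <- calls[calls$chrom == chrom, ]
      want <- oracle_union(cc$start, cc$end)
      got <- r[r$chrom == chrom, c("start", "end")]
      rownames(got) <- NULL
      expect_identical(got, want)
      ## frequency = distinct samples among members of each region
      for (i in seq_len(nrow(want))) {
        inside <- cc$start < want$end[i] & cc$end > want$start[i]
        expect_identical(
          r$frequency[r$chrom == chrom][i],
          length(unique(cc$sample_id[inside]))
        )
      }
    }
  }
})

test_that("frequency_filter keeps 4 and drops 3 (boundary)", {
  calls <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(sample_id = sprintf("S%d", i), chrom = "chr1",
               start = 100L, end = 200L, svtype = "DUP",
               stringsAsFactors = FALSE)
  }))
  calls3 <- calls[1:3, ]
  calls3$start <- 1000L; calls3$end <- 1100L
  r <- merge_cnvrs(rbind(calls, calls3))
  expect_equal(r$frequency, c(4L, 3L))
  kept <- frequency_filter(r, min_samples = 4)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$frequency, 4L)
})

test_that("classify_cnvr and empty inputs behave", {
  expect_equal(classify_cnvr(c("DUP", "DUP")), "gain")
  expect_equal(classify_cnvr(c("DEL", "DEL")), "loss")
  expect_equal(classify_cnvr(c("DEL", "both")), "mixed")
  expect_error(classify_cnvr(character()), "at least one")
  expect_equal(nrow(merge_cnvrs(NULL)), 0)
  expect_equal(nrow(merge_cnvrs(random_calls(0))), 0)
})

test_that("merge_by_group merges within groups and honours min_samples = NULL", {
  samples <- data.frame(sample_id = sprintf("S%d", 1:8),
                        group = rep(c("a", "b"), each = 4),
                        stringsAsFactors = FALSE)
  calls <- data.frame(sample_id = sprintf("S%d", 1:8), chrom = "chr1",
                      start = 100L, end = 200L, svtype = "DUP",
                      stringsAsFactors = FALSE)
  by_g <- merge_by_group(calls, samples, min_samples = 4)
  expect_named(by_g, c("a", "b"))
  expect_equal(by_g$a$frequency, 4L)
  ## group b only has 4 members too; raising the bar empties both
  expect_equal(nrow(merge_by_group(calls, samples, min_samples = 5)$a), 0)
  expect_equal(nrow(merge_by_group(calls, samples, min_samples = NULL)$b), 1)
  all_in <- merge_by_group(calls, samples, min_samples = 8, per_group = FALSE)
  expect_equal(all_in$all$frequency, 8L)
})
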