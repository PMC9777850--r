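#' GC-correct a depth profile
#'
#' Median-ratio correction against GC strata: bins are stratified by
#' rounded GC percent and each bin's count is rescaled by
#' `global_median / stratum_median`. Strata with fewer than 5 bins (whose
#' own median would be noise) borrow the factor of the nearest
#' well-populated stratum — GC bias is smooth in GC, so the neighbour's
#' factor is the best available estimate, and leaving sparse extreme-GC
#' strata uncorrected would plant recurrent artifact calls at the same
#' loci in every sample. When no stratum has 5 bins the factor is 1.
#' This inverts a multiplicative GC-dependent coverage bias exactly when
#' the bias is constant within a stratum and noise-free, and
#' approximately otherwise.
#'
#' @param profile A `depth_profile`.
#' @return The profile with `count` replaced by real-valued corrected
#'   counts (attribute `gc_corrected = TRUE`).
#' @export
gc_correct <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) == 0) return(profile)
  if (all(profile$count == 0)) {
    warning("all-zero depth profile; GC correction skipped")
    return(profile)
  }
  if (nrow(profile) < 100) {
    warning("fewer than 100 bins; per-GC medians may be unstable")
  }
  stratum <- round(profile$gc * 100)
  global_med <- stats::median(profile$count)
  med <- tapply(profile$count, stratum, stats::median)
  n <- tapply(profile$count, stratum, length)
  gc_pct <- as.numeric(names(med))
  solid <- n >= 5 & med > 0
  factor <- rep(1, length(med))
  if (any(solid)) {
    factor[solid] <- global_med / med[solid]
    if (any(!solid)) {
      nearest <- vapply(gc_pct[!solid], function(g) {
        which(solid)[which.min(abs(gc_pct[solid] - g))]
      }, integer(1))
      factor[!solid] <- factor[nearest]
    }
  }
  names(factor) <- names(med)
  profile$count <- profile$count * factor[as.character(stratum)]
  attr(profile, "gc_corrected") <- TRUE
  profile
}

#' Normalise a depth profile to read-depth ratios
#'
#' The diploid baseline is the \emph{median} corrected bin depth — robust
#' to even large CNVs, unlike the mean — and each bin's ratio is
#' `count / baseline`, so a diploid bin sits near 1, a homozygous deletion
#' at 0, and a CN-4 duplication near 2.
#'
#' @param profile A `depth_profile` (ideally GC-corrected).
#' @return The profile with an added `ratio` column and attribute
#'   `diploid_depth` (the baseline).
#' @export
normalize_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile) == 0) abort("empty profile cannot be normalised")
  baseline <- stats::median(profile$count)
  if (baseline == 0) {
    abort("degenerate profile: median depth is 0, no diploid baseline")
  }
  profile$ratio <- profile$count / baseline
  attr(profile, "diploid_depth") <- baseline
  profile
}

## group qualifying bin indices into runs, bridging <= max_gap interior
## bins provided none of the bridged bins is blocked (i.e. qualifies for
## the opposite call type)
run_groups <- function(qual, blocked, max_gap) {
  idx <- which(qual)
  if (length(idx) == 0) return(list())
  grp <- integer(length(idx))
  grp[1] <- 1L
  for (j in seq_along(idx)[-1]) {
    gap <- idx[j] - idx[j - 1L] - 1L
    bridge <- gap <= max_gap &&
      (gap == 0 || !any(blocked[(idx[j - 1L] + 1L):(idx[j] - 1L)]))
    grp[j] <- if (bridge) grp[j - 1L] else grp[j - 1L] + 1L
  }
  split(idx, grp)
}

#' Segment read-depth ratios into CNV calls
#'
#' Threshold-run segmentation: maximal runs of bins with ratio below
#' `del_thresh` (deletions) or above `dup_thresh` (duplications), allowing
#' up to `max_gap_bins` interior non-qualifying bins per gap as long as the
#' bridged bins do not qualify for the opposite type (which also guarantees
#' calls never overlap within a sample). A candidate's `rd_ratio` is the
#' mean bin ratio over its span; candidates whose span is `<= min_len_bp`
#' are discarded — the retention rule is strictly \emph{larger than}
#' 0.5 kb at the defaults.
#'
#' When `min_abs_z > 0`, candidates must also pass a segment-level
#' significance test: `|mean ratio - 1| * sqrt(n_bins) / cv > min_abs_z`,
#' where `cv` is the robust (MAD) spread of bin ratios genome wide. This
#' plays the role a segment significance test plays in production
#' read-depth callers — marginal runs whose mean barely crosses a
#' threshold are noise, while even a heterozygous change (ratio 0.5 or
#' 1.5) clears the bar after a handful of bins. When the profile is
#' noise-free (`cv = 0`) the test passes everything.
#'
#' @param profile A normalised `depth_profile` (with a `ratio` column).
#' @param del_thresh Deletion threshold (0 < del_thresh < 1).
#' @param dup_thresh Duplication threshold (> 1).
#' @param max_gap_bins Interior non-qualifying bins bridged per gap.
#' @param min_len_bp Minimum span; candidates with span <= this are dropped.
#' @param min_abs_z Minimum segment z-score (0 disables the test).
#' @return Data frame of calls: sample_id, chrom, start, end (0-based
#'   half-open), svtype ("DEL"/"DUP"), rd_ratio, copy_number
#'   (`round(2 * rd_ratio)` half away from zero, floored at 0), sorted by
#'   (chrom, start).
#' @export
segment_calls <- function(profile, del_thresh = 0.75, dup_thresh = 1.25,
                          max_gap_bins = 1, min_len_bp = 500,
                          min_abs_z = 0) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!(del_thresh > 0 && del_thresh < 1 && dup_thresh > 1)) {
    abort("thresholds must satisfy 0 < del_thresh < 1 < dup_thresh")
  }
  if (nrow(profile) == 0 || is.null(profile$ratio)) {
    if (nrow(profile) == 0) return(empty_calls())
    abort("profile has no ratio column; run normalize_depth() first")
  }
  cv <- stats::mad(profile$ratio)
  sid <- attr(profile, "sample_id")
  out <- list()
  for (chrom in unique(profile$chrom)) {
    p <- profile[profile$chrom == chrom, ]
    qual_del <- p$ratio < del_thresh
    qual_dup <- p$ratio > dup_thresh
    emit <- function(groups, svtype) {
      for (idx in groups) {
        lo <- min(idx); hi <- max(idx)
        start <- p$start[lo]; end <- p$end[hi]
        if (end - start <= min_len_bp) next
        rd <- mean(p$ratio[lo:hi])
        if (min_abs_z > 0 && cv > 0 &&
            abs(rd - 1) * sqrt(hi - lo + 1) / cv <= min_abs_z) next
        out[[length(out) + 1L]] <<- data.frame(
          sample_id = sid, chrom = chrom, start = start, end = end,
          svtype = svtype, rd_ratio = rd,
          copy_number = max(0, round_half_away(2 * rd)),
          stringsAsFactors = FALSE
        )
      }
    }
    emit(run_groups(qual_del, qual_dup, max_gap_bins), "DEL")
    emit(run_groups(qual_dup, qual_del, max_gap_bins), "DUP")
  }
  if (!length(out)) return(empty_calls())
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$chrom, calls$start), ]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), svtype = character(), rd_ratio = numeric(),
             copy_number = numeric(), stringsAsFactors = FALSE)
}

#' Call CNVs for one sample
#'
#' The per-sample read-depth pipeline: GC correction, median
#' normalisation, threshold-run segmentation. Deterministic for a fixed
#' input profile.
#'
#' @param profile A raw `depth_profile`.
#' @param del_thresh,dup_thresh,max_gap_bins,min_len_bp,min_abs_z Passed to
#'   [segment_calls()].
#' @return A calls data frame (see [segment_calls()]).
#' @export
call_sample <- function(profile, del_thresh = 0.75, dup_thresh = 1.25,
                        max_gap_bins = 1, min_len_bp = 500, min_abs_z = 0) {
  corrected <- gc_correct(profile)
  normed <- normalize_depth(corrected)
  segment_calls(normed, del_thresh = del_thresh, dup_thresh = dup_thresh,
                max_gap_bins = max_gap_bins, min_len_bp = min_len_bp,
                min_abs_z = min_abs_z)
}

#' Call CNVs for a cohort of profiles
#'
#' @param profiles Named list of `depth_profile`s.
#' @inheritParams call_sample
#' @return One calls data frame over all samples.
#' @export
call_cohort <- function(profiles, del_thresh = 0.75, dup_thresh = 1.25,
                        max_gap_bins = 1, min_len_bp = 500, min_abs_z = 0) {
  calls <- lapply(profiles, call_sample, del_thresh = del_thresh,
                  dup_thresh = dup_thresh, max_gap_bins = max_gap_bins,
                  min_len_bp = min_len_bp, min_abs_z = min_abs_z)
  out <- do.call(rbind, calls)
  if (is.null(out)) out <- empty_calls()
  rownames(out) <- NULL
  out
}

#' Compare calls with a planted truth table
#'
#' A truth carrier interval counts as recovered when some call from the
#' same sample, of the matching direction (DEL for copy number < 2, DUP
#' for > 2), overlaps it with reciprocal overlap at least
#' `min_reciprocal_overlap`; a call is a true positive when it recovers
#' some truth interval. Recall and precision follow.
#'
#' @param calls Calls data frame from [call_cohort()].
#' @param cohort A `planted_cohort`.
#' @param min_reciprocal_overlap Reciprocal-overlap fraction in (0, 1].
#' @return List with `recall`, `precision`, `n_truth`, `n_calls`,
#'   `n_truth_recovered`, `n_calls_matched`.
#' @export
evaluate_calls <- function(calls, cohort, min_reciprocal_overlap = 0.5) {
  stopifnot(inherits(cohort, "planted_cohort"))
  truth <- merge(cohort$carriers, cohort$cnvs[, c("cnv_id", "chrom",
                                                 "start", "end")],
                 by = "cnv_id")
  truth$svtype <- ifelse(truth$copy_number < 2, "DEL", "DUP")
  truth_hit <- logical(nrow(truth))
  call_hit <- logical(nrow(calls))
  if (nrow(calls) && nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      cand <- which(calls$sample_id == truth$sample_id[i] &
                      calls$chrom == truth$chrom[i] &
                      calls$svtype == truth$svtype[i])
      for (j in cand) {
        ov <- min(calls$end[j], truth$end[i]) -
          max(calls$start[j], truth$start[i])
        if (ov <= 0) next
        ro <- min(ov / (calls$end[j] - calls$start[j]),
                  ov / (truth$end[i] - truth$start[i]))
        if (ro >= min_reciprocal_overlap) {
          truth_hit[i] <- TRUE
          call_hit[j] <- TRUE
        }
      }
    }
  }
  list(
    recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
    precision = if (nrow(calls)) mean(call_hit) else NA_real_,
    n_truth = nrow(truth), n_calls = nrow(calls),
    n_truth_recovered = sum(truth_hit), n_calls_matched = sum(call_hit)
  )
}
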