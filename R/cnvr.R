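#' Merge per-sample CNV calls into CNV regions
#'
#' Single-linkage union: calls on the same chromosome that overlap by at
#' least 1 bp — directly or through a chain of overlaps — form one CNVR
#' spanning the minimum start to the maximum end of its members
#' ("boundary extension"). Half-open abutting intervals share no base and
#' are \emph{not} merged. A sample contributes once to a region's
#' frequency however many of its calls fall inside; a sample carrying both
#' a DUP and a DEL member is recorded with svtype `"both"`.
#'
#' @param calls Calls data frame (sample_id, chrom, start, end, svtype).
#' @return Data frame of CNVRs sorted by (chrom, start): cnvr_id, chrom,
#'   start, end, frequency (distinct supporting samples), cnvr_class
#'   ("gain" iff every sample's svtype is DUP, "loss" iff all DEL,
#'   "mixed" otherwise), samples and svtypes (comma-separated, aligned).
#' @export
merge_cnvrs <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) return(empty_cnvrs())
  out <- list()
  for (chrom in sort(unique(calls$chrom))) {
    cc <- calls[calls$chrom == chrom, ]
    ir <- to_iranges(cc$start, cc$end)
    ## min.gapwidth = 0: only ranges sharing >= 1 base merge; abutting
    ## half-open intervals (gap 0 in 1-based terms... adjacent) stay apart
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, red)
    region_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (r in seq_along(red)) {
      members <- cc[region_of == r, ]
      per_sample <- tapply(members$svtype, members$sample_id, function(tt) {
        u <- unique(tt)
        if (length(u) == 1) u else "both"
      })
      sids <- sort(names(per_sample))
      types <- as.character(per_sample[sids])
      coords <- from_iranges(red[r])
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = coords$start, end = coords$end,
        frequency = length(sids),
        cnvr_class = classify_svtypes(types),
        samples = paste(sids, collapse = ","),
        svtypes = paste(types, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  cnvrs <- do.call(rbind, out)
  cnvrs <- cnvrs[order(cnvrs$chrom, cnvrs$start), ]
  cnvrs <- cbind(cnvr_id = sprintf("%s:%d-%d", cnvrs$chrom, cnvrs$start,
                                   cnvrs$end),
                 cnvrs, stringsAsFactors = FALSE)
  rownames(cnvrs) <- NULL
  cnvrs
}

classify_svtypes <- function(types) {
  if (all(types == "DUP")) "gain"
  else if (all(types == "DEL")) "loss"
  else "mixed"
}

empty_cnvrs <- function() {
  data.frame(cnvr_id = character(), chrom = character(), start = integer(),
             end = integer(), frequency = integer(), cnvr_class = character(),
             samples = character(), svtypes = character(),
             stringsAsFactors = FALSE)
}

#' Classify one CNVR from its per-sample svtypes
#'
#' @param svtypes Character vector of per-sample svtypes
#'   ("DUP"/"DEL"/"both").
#' @return "gain", "loss" or "mixed".
#' @export
classify_cnvr <- function(svtypes) {
  if (length(svtypes) == 0) abort("a CNVR needs at least one member")
  classify_svtypes(svtypes)
}

#' Frequency-filter CNVRs
#'
#' Retains regions supported by at least `min_samples` distinct samples —
#' the "present in four or more samples" false-positive guard.
#'
#' @param cnvrs CNVR data frame from [merge_cnvrs()].
#' @param min_samples Minimum supporting samples (default 4).
#' @return The retained subset.
#' @export
frequency_filter <- function(cnvrs, min_samples = 4) {
  check_scalar_number(min_samples, "min_samples", min = 1)
  out <- cnvrs[cnvrs$frequency >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge calls per group, then frequency-filter
#'
#' CNVRs are built within each phenotype group separately (the two-group
#' design merges each group's 10 samples into its own region set), then
#' filtered at `min_samples`.
#'
#' @param calls Cohort calls data frame.
#' @param samples Data frame (sample_id, group).
#' @param min_samples Frequency-filter threshold (default 4); `NULL` skips
#'   filtering.
#' @param per_group If FALSE, merge all samples together instead.
#' @return Named list of CNVR data frames, one per group (or `$all`).
#' @export
merge_by_group <- function(calls, samples, min_samples = 4,
                           per_group = TRUE) {
  if (!per_group) {
    m <- merge_cnvrs(calls)
    if (!is.null(min_samples)) m <- frequency_filter(m, min_samples)
    return(list(all = m))
  }
  groups <- unique(samples$group)
  out <- lapply(groups, function(g) {
    gs <- samples$sample_id[samples$group == g]
    m <- merge_cnvrs(calls[calls$sample_id %in% gs, , drop = FALSE])
    if (!is.null(min_samples)) m <- frequency_filter(m, min_samples)
    m
  })
  names(out) <- groups
  out
}
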