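#' Summarise one group's CNV calls
#'
#' The per-group row of the cohort summary table: call counts split into
#' duplications and deletions, the per-individual mean rounded half away
#' from zero to a whole number, and size statistics in kb (1 kb =
#' 1000 bp).
#'
#' @param calls Calls data frame for one group.
#' @param n_samples Number of individuals in the group (> 0).
#' @param group_name Row label.
#' @return One-row data frame: group, n_samples, n_cnvs, n_dup, n_del,
#'   mean_cnvs_per_individual, size_mean_kb, size_median_kb, size_min_kb,
#'   size_max_kb.
#' @export
summarize_group <- function(calls, n_samples, group_name = "group") {
  check_scalar_number(n_samples, "n_samples", min = 1)
  n <- nrow(calls)
  sizes_kb <- if (n) (calls$end - calls$start) / 1000 else numeric()
  data.frame(
    group = group_name,
    n_samples = as.integer(n_samples),
    n_cnvs = n,
    n_dup = if (n) sum(calls$svtype == "DUP") else 0L,
    n_del = if (n) sum(calls$svtype == "DEL") else 0L,
    mean_cnvs_per_individual = round_half_away(n / n_samples),
    size_mean_kb = if (n) mean(sizes_kb) else 0,
    size_median_kb = if (n) stats::median(sizes_kb) else 0,
    size_min_kb = if (n) min(sizes_kb) else 0,
    size_max_kb = if (n) max(sizes_kb) else 0,
    stringsAsFactors = FALSE
  )
}

#' Combine group summaries into an overall row
#'
#' Sums samples and counts and recomputes the rounded per-individual mean
#' from the totals (110,268 calls over 20 individuals rounds to 5513, not
#' to the mean of the group means). The combined size mean is
#' count-weighted; a combined median is not recoverable from summaries and
#' is reported as NA.
#'
#' @param summaries A data frame of rows from [summarize_group()] (or a
#'   list of them).
#' @param group_name Label for the combined row (default "total").
#' @return One-row data frame in the same shape.
#' @export
combine_summaries <- function(summaries, group_name = "total") {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, summaries)
  }
  if (nrow(summaries) == 0) abort("need at least one summary")
  n_cnvs <- sum(summaries$n_cnvs)
  n_samples <- sum(summaries$n_samples)
  data.frame(
    group = group_name,
    n_samples = as.integer(n_samples),
    n_cnvs = n_cnvs,
    n_dup = sum(summaries$n_dup),
    n_del = sum(summaries$n_del),
    mean_cnvs_per_individual = round_half_away(n_cnvs / n_samples),
    size_mean_kb = if (n_cnvs) {
      sum(summaries$size_mean_kb * summaries$n_cnvs) / n_cnvs
    } else 0,
    size_median_kb = NA_real_,
    size_min_kb = if (n_cnvs) min(summaries$size_min_kb[summaries$n_cnvs > 0]) else 0,
    size_max_kb = if (n_cnvs) max(summaries$size_max_kb[summaries$n_cnvs > 0]) else 0,
    stringsAsFactors = FALSE
  )
}

#' Differential gene sets between two groups
#'
#' Set algebra over the two annotated gene sets; the differential set is
#' the symmetric difference. When one set nests inside the other (as with
#' two closely related populations), the differential reduces to the
#' larger set minus the shared genes, and `nested_b_in_a` flags it.
#'
#' @param genes_a,genes_b Character vectors of gene ids.
#' @return List: genes_a, genes_b, shared, only_a, only_b, differential
#'   (only_a U only_b), nested_b_in_a (TRUE iff genes_b is a subset of
#'   genes_a).
#' @export
differential_genes <- function(genes_a, genes_b) {
  a <- sort(unique(as.character(genes_a)))
  b <- sort(unique(as.character(genes_b)))
  shared <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  list(genes_a = a, genes_b = b, shared = shared,
       only_a = only_a, only_b = only_b,
       differential = sort(union(only_a, only_b)),
       nested_b_in_a = length(only_b) == 0)
}

#' Windowed CNVR density per chromosome
#'
#' Counts CNVRs by the window containing their midpoint; the exported
#' track plots the (non-uniform) distribution of regions along each
#' chromosome.
#'
#' @param cnvrs CNVR data frame.
#' @param window Window size in bp (> 0).
#' @param chrom_lengths Named lengths; defaults to each chromosome's
#'   maximum CNVR end.
#' @return bedGraph-style data frame (chrom, start, end, count) covering
#'   every window of every chromosome.
#' @export
cnvr_density <- function(cnvrs, window, chrom_lengths = NULL) {
  check_scalar_number(window, "window", min = 1)
  if (is.null(chrom_lengths)) {
    if (nrow(cnvrs) == 0) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), count = integer()))
    }
    chrom_lengths <- tapply(cnvrs$end, cnvrs$chrom, max)
  }
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    start <- seq(0L, len - 1L, by = window)
    end <- pmin(start + window, len)
    cc <- cnvrs[cnvrs$chrom == chrom, , drop = FALSE]
    mids <- floor((cc$start + cc$end) / 2)
    idx <- pmin(floor(mids / window) + 1L, length(start))
    count <- tabulate(idx, nbins = length(start))
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(end), count = count,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' CNV size histogram
#'
#' Counts calls per size interval (kb), right-closed bins, the classic
#' size-distribution figure as a table.
#'
#' @param calls Calls data frame.
#' @param bin_edges_kb Strictly increasing edges in kb; every call size
#'   must fall in (first, last].
#' @return Data frame (bin, lower_kb, upper_kb, count); counts sum to the
#'   number of calls.
#' @export
size_histogram <- function(calls, bin_edges_kb) {
  if (is.unsorted(bin_edges_kb, strictly = TRUE)) {
    abort("bin_edges_kb must be strictly increasing")
  }
  nb <- length(bin_edges_kb) - 1L
  out <- data.frame(
    bin = sprintf("(%g,%g]", bin_edges_kb[-length(bin_edges_kb)],
                  bin_edges_kb[-1]),
    lower_kb = bin_edges_kb[-length(bin_edges_kb)],
    upper_kb = bin_edges_kb[-1],
    count = integer(nb),
    stringsAsFactors = FALSE
  )
  if (nrow(calls)) {
    sizes <- (calls$end - calls$start) / 1000
    if (any(sizes <= bin_edges_kb[1] | sizes > bin_edges_kb[length(bin_edges_kb)])) {
      abort("call sizes outside the histogram range")
    }
    idx <- findInterval(sizes, bin_edges_kb, left.open = TRUE,
                        rightmost.closed = TRUE)
    out$count <- tabulate(idx, nbins = nb)
  }
  out
}
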