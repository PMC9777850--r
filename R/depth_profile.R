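#' Construct a depth profile
#'
#' A binned read-depth signal for one sample: per-bin counts plus per-bin
#' GC fraction, bins tiling each chromosome left to right in 0-based
#' half-open coordinates.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end`, `gc`,
#'   `count`.
#' @param sample_id Sample label.
#' @param bin_size Nominal bin width in bp.
#' @return A `depth_profile` (a data frame with attributes).
#' @export
depth_profile <- function(bins, sample_id, bin_size) {
  need <- c("chrom", "start", "end", "gc", "count")
  if (!all(need %in% names(bins))) {
    abort("bins must have columns: ", paste(need, collapse = ", "))
  }
  if (any(bins$count < 0)) abort("counts must be >= 0")
  if (any(bins$gc < 0 | bins$gc > 1)) abort("gc must be in [0, 1]")
  if (any(bins$end <= bins$start)) abort("bins must have end > start")
  ## bins must tile each chromosome left to right
  by_chr <- split(bins, bins$chrom)
  for (b in by_chr) {
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)])) {
      abort("bins must tile the chromosome without gaps or overlaps")
    }
  }
  structure(as.data.frame(bins), sample_id = sample_id,
            bin_size = as.integer(bin_size),
            class = c("depth_profile", "data.frame"))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile", attr(x, "sample_id"), ":", nrow(x), "bins of",
      attr(x, "bin_size"), "bp, mean depth",
      signif(mean(x$count), 4), "\n")
  invisible(x)
}

#' Write a depth profile as a 4-column bedGraph-style TSV
#'
#' Columns chrom, start, end, count (0-based half-open), no header.
#' GC fractions travel in a sidecar column when `with_gc = TRUE` (the
#' default: the caller's GC correction needs them).
#'
#' @param profile A `depth_profile`.
#' @param path Output path.
#' @param with_gc Include the gc column (5-column variant).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path, with_gc = TRUE) {
  stopifnot(inherits(profile, "depth_profile"))
  cols <- if (with_gc) c("chrom", "start", "end", "count", "gc")
          else c("chrom", "start", "end", "count")
  utils::write.table(profile[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a depth profile written by [write_depth_tsv()]
#'
#' @param path TSV path (4 or 5 columns).
#' @param sample_id Sample label for the profile.
#' @return A `depth_profile`. A 4-column file gets `gc = 0.5` everywhere
#'   (GC correction then degenerates to a no-op single stratum).
#' @export
read_depth_tsv <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) abort("no such file: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (!ncol(d) %in% c(4L, 5L)) {
    abort("depth TSV must have 4 or 5 columns, found ", ncol(d))
  }
  names(d) <- c("chrom", "start", "end", "count", "gc")[seq_len(ncol(d))]
  if (ncol(d) == 4L) d$gc <- 0.5
  bin_size <- if (nrow(d)) max(d$end - d$start) else 0L
  depth_profile(d[, c("chrom", "start", "end", "gc", "count")],
                sample_id = sample_id, bin_size = bin_size)
}
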