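#' Write intervals as BED
#'
#' BED is 0-based half-open — the internal convention — so coordinates are
#' written verbatim. Calls are written as chrom/start/end/name/score with
#' name = svtype and score = copy number; CNVRs carry frequency, class and
#' the supporting sample list as extra columns.
#'
#' @param x Calls or CNVR data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  ## [[ indexing: $ would partial-match the CNVR "svtypes" column
  if (!is.null(x[["svtype"]])) {
    bed <- data.frame(x$chrom, x$start, x$end, x$svtype, x$copy_number,
                      x$sample_id)
  } else if (!is.null(x$cnvr_class)) {
    bed <- data.frame(x$chrom, x$start, x$end, x$cnvr_id, x$frequency,
                      x$cnvr_class, x$samples)
  } else {
    bed <- data.frame(x$chrom, x$start, x$end)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Validates coordinates and reports offending line numbers.
#'
#' @param path BED path.
#' @return Data frame with chrom, start, end and any extra columns
#'   (name, score, ...).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort("malformed BED line(s) with < 3 fields: line ",
          paste(which(nf < 3), collapse = ", "))
  }
  d <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                         header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  if (ncol(d) >= 5) names(d)[5] <- "score"
  bad <- which(!is.finite(d$start) | !is.finite(d$end) | d$end <= d$start)
  if (length(bad)) {
    abort("invalid coordinates (end <= start) at line ",
          paste(bad, collapse = ", "))
  }
  d
}

#' Write CNV calls or CNVRs as a VCF 4.2 symbolic-SV file
#'
#' Symbolic alleles `<DEL>`/`<DUP>` with INFO `END` (1-based inclusive)
#' and `SVLEN`: an internal 0-based half-open interval `[100, 200)`
#' becomes POS 101, END 200. CNVRs additionally carry `NSAMP` (supporting
#' samples) and mixed regions are emitted as `<CNV>`.
#'
#' @param x Calls (svtype column) or CNVR (cnvr_class column) data frame.
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, chrom_lengths = NULL) {
  ## [[ indexing: $ would partial-match the CNVR "svtypes" column
  is_call <- !is.null(x[["svtype"]])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=yakcnv",
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=CNV,Description="Copy number variable region">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length, negative for deletions">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">'
  )
  if (!is_call) {
    header <- c(header,
      '##INFO=<ID=NSAMP,Number=1,Type=Integer,Description="Supporting samples">')
  }
  if (!is.null(chrom_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(chrom_lengths),
                                as.integer(chrom_lengths)))
  }
  header <- c(header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO"), collapse = "\t"))
  if (nrow(x) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (is_call) {
    svtype <- x$svtype
    id <- sprintf("%s_%s_%d", x$sample_id, x$chrom, x$start)
    extra <- ""
  } else {
    svtype <- c(gain = "DUP", loss = "DEL", mixed = "CNV")[x$cnvr_class]
    id <- x$cnvr_id
    extra <- sprintf(";NSAMP=%d", x$frequency)
  }
  svlen <- ifelse(svtype == "DEL", -(x$end - x$start), x$end - x$start)
  rec <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d%s",
                 x$chrom, x$start + 1L, id, svtype, svtype, x$end,
                 as.integer(svlen), extra)
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read a symbolic-SV VCF back into an interval data frame
#'
#' Parses with `VariantAnnotation::readVcf` and converts POS/END (1-based
#' inclusive) back to the internal 0-based half-open convention; records
#' with END before POS are rejected.
#'
#' @param path VCF path.
#' @return Data frame: chrom, start, end, id, svtype, svlen (+ nsamp when
#'   present).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  v <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  if (length(rr) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(), svtype = character(),
                      svlen = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(info$END)) abort("VCF records lack the required INFO END field")
  pos <- BiocGenerics::start(rr)
  end1 <- as.integer(unlist(info$END))
  if (any(is.na(end1))) abort("VCF records lack the required INFO END field")
  if (any(end1 < pos)) {
    abort("invalid record(s): END before POS at ",
          paste(which(end1 < pos), collapse = ", "))
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = pos - 1L,
    end = end1,
    id = names(rr),
    svtype = as.character(unlist(info$SVTYPE)),
    svlen = as.integer(unlist(info$SVLEN)),
    stringsAsFactors = FALSE
  )
  if (!is.null(info$NSAMP)) out$nsamp <- as.integer(unlist(info$NSAMP))
  rownames(out) <- NULL
  out
}

#' Write a bedGraph track
#'
#' @param track Data frame (chrom, start, end, count/value).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, 1:4], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
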