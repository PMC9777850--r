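#' Construct a gene model
#'
#' Container for gene spans and their exons, everything in 0-based
#' half-open coordinates (the GFF3 readers/writers convert at the file
#' boundary). Exons must lie inside their gene's span and reference an
#' existing gene.
#'
#' @param genes Data frame with columns `gene_id`, `name`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param exons Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(genes, exons) {
  need_g <- c("gene_id", "name", "chrom", "start", "end", "strand")
  need_e <- c("gene_id", "chrom", "start", "end")
  if (!all(need_g %in% names(genes))) {
    abort("genes must have columns: ", paste(need_g, collapse = ", "))
  }
  if (!all(need_e %in% names(exons))) {
    abort("exons must have columns: ", paste(need_e, collapse = ", "))
  }
  if (any(genes$end <= genes$start)) abort("gene intervals must have end > start")
  if (nrow(exons)) {
    if (any(exons$end <= exons$start)) abort("exon intervals must have end > start")
    orphan <- setdiff(exons$gene_id, genes$gene_id)
    if (length(orphan)) {
      abort("orphan exons reference unknown genes: ",
            paste(orphan, collapse = ", "))
    }
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(exons$start < span$start | exons$end > span$end)) {
      abort("exons must lie within their gene span")
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "gene(s),", nrow(x$exons), "exon(s)\n")
  invisible(x)
}

#' Write a gene model to GFF3
#'
#' Emits `gene` and `exon` features with ID/Parent linkage; internal
#' 0-based half-open coordinates become the format's 1-based inclusive
#' ones.
#'
#' @param model A `gene_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  g <- model$genes
  e <- model$exons
  gr_g <- GenomicRanges::GRanges(
    seqnames = g$chrom, ranges = to_iranges(g$start, g$end),
    strand = g$strand, type = "gene", ID = g$gene_id, Name = g$name
  )
  if (nrow(e)) {
    strand_e <- g$strand[match(e$gene_id, g$gene_id)]
    gr_e <- GenomicRanges::GRanges(
      seqnames = e$chrom, ranges = to_iranges(e$start, e$end),
      strand = strand_e, type = "exon",
      ID = sprintf("%s.exon%d", e$gene_id,
                   stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along)),
      Name = NA_character_
    )
    S4Vectors::mcols(gr_e)$Parent <- e$gene_id
    S4Vectors::mcols(gr_g)$Parent <- NA_character_
    gr <- c(gr_g, gr_e)
  } else {
    gr <- gr_g
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Keeps `gene` and `exon` features; exons are linked to genes through
#' their `Parent` attribute and orphan exons are rejected. File
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention, so a gene written as `1..100` comes back as
#' `[0, 100)`.
#'
#' @param path GFF3 file path.
#' @return A `gene_model`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort("malformed GFF3 (", path, "): ",
                              conditionMessage(e))
  )
  typ <- as.character(S4Vectors::mcols(gr)$type)
  gg <- gr[typ == "gene"]
  ge <- gr[typ == "exon"]
  if (length(gg) == 0 && length(ge) > 0) {
    abort("orphan exons: exon features but no gene features in ", path)
  }
  if (length(gg) == 0) {
    return(gene_model(
      genes = data.frame(gene_id = character(), name = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character()),
      exons = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer())
    ))
  }
  ids <- as.character(S4Vectors::mcols(gg)$ID)
  nm <- S4Vectors::mcols(gg)$Name
  nm <- if (is.null(nm)) ids else ifelse(is.na(as.character(nm)), ids,
                                         as.character(nm))
  genes <- data.frame(
    gene_id = ids, name = nm,
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = BiocGenerics::start(gg) - 1L,
    end = BiocGenerics::end(gg),
    strand = as.character(BiocGenerics::strand(gg)),
    stringsAsFactors = FALSE
  )
  genes$strand[genes$strand == "*"] <- "+"
  if (length(ge)) {
    parent <- S4Vectors::mcols(ge)$Parent
    parent <- vapply(as.list(parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    if (anyNA(parent) || !all(parent %in% ids)) {
      abort("orphan exons: exon features whose Parent is not a gene ID: ",
            paste(utils::head(setdiff(parent, ids)), collapse = ", "))
    }
    exons <- data.frame(
      gene_id = parent,
      chrom = as.character(GenomicRanges::seqnames(ge)),
      start = BiocGenerics::start(ge) - 1L,
      end = BiocGenerics::end(ge),
      stringsAsFactors = FALSE
    )
  } else {
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer())
  }
  gene_model(genes = genes, exons = exons)
}
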