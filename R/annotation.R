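#' Annotate CNVRs with overlapping genes
#'
#' A CNVR hits a gene when their spans share at least 1 bp. Each hit is
#' classified: `spanning` when the CNVR fully contains the gene,
#' otherwise `exonic` when it overlaps at least one exon, otherwise
#' `intronic`. Intronic-only hits are flagged `retained = FALSE` — the
#' workflow keeps only variants touching coding-relevant sequence — and a
#' CNVR with hits on several genes keeps only its exonic/spanning hits.
#'
#' @param cnvrs CNVR data frame (needs cnvr_id, chrom, start, end).
#' @param model A `gene_model`.
#' @return List with `hits` (one row per CNVR x gene: cnvr_id, gene_id,
#'   region_class, retained) and `cnvrs` (the input plus `n_genes` and
#'   `retained` — TRUE when at least one hit is retained).
#' @export
overlap_genes <- function(cnvrs, model) {
  stopifnot(inherits(model, "gene_model"))
  g <- model$genes
  if (nrow(cnvrs) && nrow(g) &&
      !any(cnvrs$chrom %in% g$chrom)) {
    warning("no shared chromosome names between CNVRs (",
            paste(utils::head(unique(cnvrs$chrom)), collapse = ","),
            ") and gene model (",
            paste(utils::head(unique(g$chrom)), collapse = ","), ")")
  }
  hits <- data.frame(cnvr_id = character(), gene_id = character(),
                     region_class = character(), retained = logical(),
                     stringsAsFactors = FALSE)
  if (nrow(cnvrs) && nrow(g)) {
    gr_c <- GenomicRanges::GRanges(cnvrs$chrom,
                                   to_iranges(cnvrs$start, cnvrs$end))
    gr_g <- GenomicRanges::GRanges(g$chrom, to_iranges(g$start, g$end))
    ov <- GenomicRanges::findOverlaps(gr_c, gr_g)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      cls <- character(length(ov))
      for (h in seq_along(qi)) {
        ci <- qi[h]; gi <- si[h]
        if (cnvrs$start[ci] <= g$start[gi] && cnvrs$end[ci] >= g$end[gi]) {
          cls[h] <- "spanning"
        } else {
          ex <- model$exons[model$exons$gene_id == g$gene_id[gi], ]
          exonic <- nrow(ex) > 0 &&
            any(pmin(cnvrs$end[ci], ex$end) -
                  pmax(cnvrs$start[ci], ex$start) > 0)
          cls[h] <- if (exonic) "exonic" else "intronic"
        }
      }
      hits <- data.frame(
        cnvr_id = cnvrs$cnvr_id[qi], gene_id = g$gene_id[si],
        region_class = cls, retained = cls != "intronic",
        stringsAsFactors = FALSE
      )
      hits <- hits[order(hits$cnvr_id, hits$gene_id), ]
      rownames(hits) <- NULL
    }
  }
  ann <- cnvrs
  ann$n_genes <- vapply(ann$cnvr_id, function(id) {
    sum(hits$cnvr_id == id)
  }, integer(1))
  ann$retained <- vapply(ann$cnvr_id, function(id) {
    any(hits$retained[hits$cnvr_id == id])
  }, logical(1))
  list(hits = hits, cnvrs = ann)
}

#' Distinct genes hit by annotated CNVRs
#'
#' @param annotated Result of [overlap_genes()].
#' @param retained_only Keep only retained (exonic/spanning) hits — the
#'   default, matching the intronic-removal rule.
#' @return Sorted character vector of gene ids.
#' @export
gene_set <- function(annotated, retained_only = TRUE) {
  h <- annotated$hits
  if (retained_only) h <- h[h$retained, , drop = FALSE]
  sort(unique(h$gene_id))
}
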