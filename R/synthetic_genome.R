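#' Build a synthetic genome model with a smooth GC landscape
#'
#' The genome model stands in for a mammalian reference assembly at desk
#' scale: a handful of chromosomes, each carrying a GC fraction per
#' fixed-width window. The GC landscape is a smoothed (AR(1)) process
#' squashed into \[0.25, 0.65\], so GC-dependent depth bias and its
#' correction are exercisable.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length(s) in bp; recycled to `n_chrom`.
#' @param gc_window Width in bp of the GC windows (last window truncated).
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   model.
#' @return An object of class `cnv_genome`: a list with `chrom_names`,
#'   `chrom_lengths` (named), `gc_window`, and `gc` (a named list of
#'   per-window GC fractions).
#' @examples
#' g <- make_genome(n_chrom = 2, chrom_length = 1e6, gc_window = 500, seed = 1)
#' range(unlist(g$gc))
#' @export
make_genome <- function(n_chrom = 2, chrom_length = 1e6, gc_window = 500,
                        seed = NULL) {
  check_scalar_number(n_chrom, "n_chrom", min = 1)
  if (!is.numeric(chrom_length) || any(chrom_length <= 0)) {
    abort("chrom_length must be positive")
  }
  check_scalar_number(gc_window, "gc_window", min = 1)
  lens <- rep_len(as.numeric(chrom_length), n_chrom)
  if (any(lens < 10 * gc_window)) {
    abort("each chromosome must span at least 10 GC windows")
  }
  seed_if(seed)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  gc <- lapply(lens, function(len) {
    n_win <- ceiling(len / gc_window)
    innov <- stats::rnorm(n_win)
    x <- as.numeric(stats::filter(innov, 0.9, method = "recursive"))
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    ## tanh keeps the landscape strictly inside [0.25, 0.65]
    0.45 + 0.2 * tanh(x / (2 * s))
  })
  names(gc) <- chrom_names
  names(lens) <- chrom_names
  structure(
    list(chrom_names = chrom_names, chrom_lengths = lens,
         gc_window = as.integer(gc_window), gc = gc),
    class = "cnv_genome"
  )
}

#' @export
print.cnv_genome <- function(x, ...) {
  cat("cnv_genome:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total, GC window",
      x$gc_window, "bp\n")
  invisible(x)
}

#' GC fraction of arbitrary bins
#'
#' Looks up the genome GC landscape for bin midpoints; used by the depth
#' simulator when the analysis bin size differs from the GC window.
#' @keywords internal
genome_gc_at <- function(genome, chrom, mid) {
  idx <- pmin(floor(mid / genome$gc_window) + 1L, length(genome$gc[[chrom]]))
  genome$gc[[chrom]][idx]
}

#' Generate a non-overlapping synthetic gene model
#'
#' Genes are placed on a slot grid (one gene per slot, slots separated by
#' `min_spacing`) so genes never overlap and every gene keeps clear flanks;
#' each gene carries `exons_per_gene` exons with the first starting at the
#' gene start and the last ending at the gene end.
#'
#' @param genome A `cnv_genome`.
#' @param n_genes Number of genes (0 allowed).
#' @param exons_per_gene Exons per gene (>= 1).
#' @param gene_length Gene span in bp.
#' @param exon_length Exon length in bp.
#' @param min_spacing Minimum bp between neighbouring gene spans.
#' @param seed Optional seed.
#' @return A `gene_model` (see [gene_model()]): `genes` and `exons` data
#'   frames in 0-based half-open coordinates.
#' @export
make_genes <- function(genome, n_genes = 30, exons_per_gene = 3,
                       gene_length = 20000, exon_length = 400,
                       min_spacing = 12000, seed = NULL) {
  stopifnot(inherits(genome, "cnv_genome"))
  check_scalar_number(n_genes, "n_genes", min = 0)
  check_scalar_number(exons_per_gene, "exons_per_gene", min = 1)
  if (exons_per_gene * exon_length >= gene_length) {
    abort("exons do not fit inside gene_length")
  }
  seed_if(seed)
  slot <- gene_length + min_spacing
  n_slots <- floor((genome$chrom_lengths - min_spacing) / slot)
  if (sum(n_slots) < n_genes) {
    abort("infeasible packing: ", n_genes, " genes need more than the ",
          sum(n_slots), " available slots; shrink genes or grow the genome")
  }
  if (n_genes == 0) {
    return(gene_model(
      genes = data.frame(gene_id = character(), name = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character()),
      exons = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer())
    ))
  }
  slots <- do.call(rbind, lapply(seq_along(n_slots), function(i) {
    if (n_slots[i] == 0) return(NULL)
    data.frame(chrom = genome$chrom_names[i], slot = seq_len(n_slots[i]))
  }))
  pick <- slots[sort(sample.int(nrow(slots), n_genes)), , drop = FALSE]
  ## jitter kept small so the inter-gene gap stays close to min_spacing
  start <- min_spacing + (pick$slot - 1L) * slot +
    sample.int(1000L, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    name = sprintf("G%03d", seq_len(n_genes)),
    chrom = pick$chrom,
    start = as.integer(start),
    end = as.integer(start + gene_length),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    offs <- if (exons_per_gene == 1) 0 else
      round(seq(0, gene_length - exon_length, length.out = exons_per_gene))
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = genes$start[i] + as.integer(offs),
               end = genes$start[i] + as.integer(offs) + exon_length,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- rownames(exons) <- NULL
  gene_model(genes = genes, exons = exons)
}
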