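# Brute-force oracles used by the property-based suites. Deliberately
# naive implementations: correctness by obviousness, not speed.

# Brute-force single-linkage union of 0-based half-open intervals on one
# chromosome: two intervals are linked iff they share at least one base
# (checked per pair), components are grown to a fixed point, and each
# component spans min(start)..max(end). Abutting half-open intervals share
# no base and therefore stay in separate components.
oracle_union <- function(start, end) {
  n <- length(start)
  if (n == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        shares_base <- min(end[i], end[j]) - max(start[i], start[j]) > 0
        if (shares_base && comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cpt) {
    data.frame(start = min(start[comp == cpt]),
               end = max(end[comp == cpt]))
  }))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive hypergeometric upper tail: enumerate every subset size-n
# draw outcome via the pmf written out with choose().
oracle_hyper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg from its definition: q_(i) = min over j >= i of
# p_(j) * m / j, capped at 1, mapped back to the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# Random calls table for merge fuzzing: a handful of samples, short
# integer intervals on one or two chromosomes.
random_calls <- function(n, max_pos = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(8, n, replace = TRUE)
  data.frame(
    sample_id = sample(sprintf("S%02d", 1:6), n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = start + len,
    svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# A tiny handcrafted gene model: two genes on chr1, one on chr2, three
# exons each with the first exon at the gene start.
toy_gene_model <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    name = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 10000L, 2000L),
    end = c(4000L, 13000L, 5000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               start = s + c(0L, 1300L, 2800L),
               end = s + c(200L, 1500L, 3000L),
               stringsAsFactors = FALSE)
  }))
  gene_model(genes = genes, exons = exons)
}

# One-row CNVR data frame in merge_cnvrs() shape.
toy_cnvr <- function(chrom, start, end, id = sprintf("%s:%d-%d", chrom, start, end),
                     frequency = 5L, cnvr_class = "gain") {
  data.frame(cnvr_id = id, chrom = chrom, start = start, end = end,
             frequency = frequency, cnvr_class = cnvr_class,
             samples = "S01", svtypes = "DUP", stringsAsFactors = FALSE)
}
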