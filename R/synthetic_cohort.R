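#' Plant CNV genotypes across a two-group cohort
#'
#' Emulates the study design the downstream comparison assumes: two closely
#' related groups (long-haired vs normal-haired), with
#' \itemize{
#'   \item shared exonic CNVs carried by at least `carriers_per_cnv` samples
#'     of \emph{both} groups (so both gene sets contain the hit genes and the
#'     normal-hair set nests inside the long-hair set),
#'   \item group-A-only exonic CNVs carried only by long-hair samples (the
#'     differential genes),
#'   \item optional intronic-only CNVs (exercise the intronic-removal rule)
#'     and intergenic CNVs (hit no gene).
#' }
#' Every planted locus is placed on the gene-model slot grid so loci are
#' pairwise well separated and exonic CNVs fully contain the first exon of
#' their target gene with a margin.
#'
#' @param genome A `cnv_genome`.
#' @param genes A `gene_model` from [make_genes()] (slot-grid placement is
#'   assumed for the clearance guarantees).
#' @param n_per_group Samples per group (>= 4, default 10).
#' @param n_shared Shared exonic CNVs (both groups).
#' @param n_groupA_only Exonic CNVs private to the long-hair group.
#' @param n_intronic Intronic-only CNVs (shared; retained=FALSE downstream).
#' @param n_intergenic Intergenic CNVs (shared; hit no gene).
#' @param carriers_per_cnv Carriers per group per CNV (>= 4 so the
#'   frequency filter is exercisable; <= n_per_group).
#' @param size_range Planted CNV length range in bp (min >= 600).
#' @param intronic_size CNV length used for intronic plants (must fit in an
#'   intron with margins).
#' @param cn_pool Copy numbers drawn for exonic/intergenic plants
#'   (diploid = 2 excluded; 0/1 deletions, 3/4 duplications).
#' @param exon_margin Minimum bp by which an exonic CNV extends past the
#'   targeted exon on each side.
#' @param seed Optional seed.
#' @return A `planted_cohort`: list with `samples` (sample_id, group),
#'   `cnvs` (one row per planted locus: cnv_id, chrom, start, end,
#'   copy_number, category, gene_id, scope), `carriers` (cnv_id, sample_id,
#'   group, copy_number), and `gene_truth` (`genes_a`, `genes_b`,
#'   `differential` — exon-hit genes only).
#' @export
plant_cohort_cnvs <- function(genome, genes, n_per_group = 10,
                              n_shared = 6, n_groupA_only = 4,
                              n_intronic = 0, n_intergenic = 4,
                              carriers_per_cnv = 6,
                              size_range = c(4000, 8000),
                              intronic_size = 3500,
                              cn_pool = c(0, 1, 3, 4),
                              exon_margin = 800, seed = NULL) {
  stopifnot(inherits(genome, "cnv_genome"), inherits(genes, "gene_model"))
  check_scalar_number(n_per_group, "n_per_group", min = 4)
  if (carriers_per_cnv < 4 || carriers_per_cnv > n_per_group) {
    abort("carriers_per_cnv must be in [4, n_per_group]")
  }
  if (length(size_range) != 2 || size_range[1] > size_range[2]) {
    abort("size_range must be an increasing pair")
  }
  if (size_range[1] < 600) {
    abort("size_range minimum is 600 bp (smallest CNV the workflow models)")
  }
  if (any(cn_pool < 0) || any(cn_pool == 2)) {
    abort("cn_pool must be non-negative and exclude the diploid state 2")
  }
  seed_if(seed)

  samples <- data.frame(
    sample_id = c(sprintf("LH_%02d", seq_len(n_per_group)),
                  sprintf("NH_%02d", seq_len(n_per_group))),
    group = rep(c("long_hair", "normal_hair"), each = n_per_group),
    stringsAsFactors = FALSE
  )
  group_a <- samples$sample_id[samples$group == "long_hair"]
  group_b <- samples$sample_id[samples$group == "normal_hair"]

  n_exonic <- n_shared + n_groupA_only
  if (n_exonic + n_intronic > nrow(genes$genes)) {
    abort("not enough genes to host the requested exonic/intronic CNVs")
  }
  gene_pick <- sample(genes$genes$gene_id, n_exonic + n_intronic)

  cnvs <- list()
  carriers <- list()
  add_cnv <- function(id, chrom, start, end, cn, category, gene_id, scope) {
    cnvs[[length(cnvs) + 1L]] <<- data.frame(
      cnv_id = id, chrom = chrom, start = as.integer(start),
      end = as.integer(end), copy_number = cn, category = category,
      gene_id = gene_id, scope = scope, stringsAsFactors = FALSE
    )
    carr <- switch(scope,
      both = c(sample(group_a, carriers_per_cnv),
               sample(group_b, carriers_per_cnv)),
      group_a = sample(group_a, carriers_per_cnv)
    )
    carriers[[length(carriers) + 1L]] <<- data.frame(
      cnv_id = id, sample_id = carr,
      group = samples$group[match(carr, samples$sample_id)],
      copy_number = cn, stringsAsFactors = FALSE
    )
  }

  ## single-copy gains (CN 3) shift read depth by only 50% and are the
  ## hardest state for a depth caller, so they are planted 1.5x larger —
  ## mirroring that real heterozygous duplications are only reliably
  ## detectable when long
  draw_len <- function(cn) {
    mult <- if (cn == 3) 1.5 else 1
    round(stats::runif(1, size_range[1] * mult, size_range[2] * mult))
  }

  ## exonic plants: roughly centred on exon 1 of the target gene (so even a
  ## call truncated to either half still overlaps the exon), extending
  ## leftwards into the guaranteed-clear upstream flank
  place_exonic <- function(gene_id, len) {
    ex <- genes$exons[genes$exons$gene_id == gene_id, ][1, ]
    exon_len <- ex$end - ex$start
    need <- exon_len + 2 * exon_margin
    if (len < need) len <- need
    mid <- (ex$start + ex$end) / 2
    jitter <- round(stats::runif(1, -exon_margin / 2, exon_margin / 2))
    start <- max(0, round(mid - len / 2) + jitter)
    c(start = start, end = start + len)
  }

  k <- 0L
  for (i in seq_len(n_shared)) {
    k <- k + 1L
    gid <- gene_pick[k]
    g <- genes$genes[genes$genes$gene_id == gid, ]
    cn <- sample(cn_pool, 1)
    pos <- place_exonic(gid, draw_len(cn))
    add_cnv(sprintf("cnv%03d", k), g$chrom, pos["start"], pos["end"],
            cn, "shared_exonic", gid, "both")
  }
  for (i in seq_len(n_groupA_only)) {
    k <- k + 1L
    gid <- gene_pick[k]
    g <- genes$genes[genes$genes$gene_id == gid, ]
    cn <- sample(cn_pool, 1)
    pos <- place_exonic(gid, draw_len(cn))
    add_cnv(sprintf("cnv%03d", k), g$chrom, pos["start"], pos["end"],
            cn, "groupA_exonic", gid, "group_a")
  }
  for (i in seq_len(n_intronic)) {
    k <- k + 1L
    gid <- gene_pick[k]
    ex <- genes$exons[genes$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) abort("intronic plants need genes with >= 2 exons")
    intr_start <- ex$end[1]
    intr_end <- ex$start[2]
    margin <- (intr_end - intr_start - intronic_size) / 2
    if (margin < 500) {
      abort("intron too small for intronic_size with a safety margin")
    }
    start <- intr_start + floor(margin)
    add_cnv(sprintf("cnv%03d", k), ex$chrom[1], start, start + intronic_size,
            sample(cn_pool, 1), "intronic", gid, "both")
  }

  ## intergenic plants: rejection-sample positions clear of genes and of
  ## already-planted loci
  if (n_intergenic > 0) {
    clearance <- 6000
    gr_busy <- function() {
      busy <- do.call(rbind, c(
        list(genes$genes[, c("chrom", "start", "end")]),
        lapply(cnvs, function(d) d[, c("chrom", "start", "end")])
      ))
      GenomicRanges::GRanges(busy$chrom,
                             to_iranges(pmax(0, busy$start - clearance),
                                        busy$end + clearance))
    }
    for (i in seq_len(n_intergenic)) {
      busy <- gr_busy()
      placed <- FALSE
      cn <- sample(cn_pool, 1)
      for (try in seq_len(200)) {
        chrom <- sample(genome$chrom_names, 1)
        len <- draw_len(cn)
        start <- floor(stats::runif(1, clearance,
                                    genome$chrom_lengths[[chrom]] - len - clearance))
        cand <- GenomicRanges::GRanges(chrom, to_iranges(start, start + len))
        if (length(GenomicRanges::findOverlaps(cand, busy)) == 0) {
          k <- k + 1L
          add_cnv(sprintf("cnv%03d", k), chrom, start, start + len,
                  cn, "intergenic", NA_character_, "both")
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place intergenic CNV ", i,
                         "; genome too crowded")
    }
  }

  cnvs <- if (length(cnvs)) do.call(rbind, cnvs) else data.frame(
    cnv_id = character(), chrom = character(), start = integer(),
    end = integer(), copy_number = numeric(), category = character(),
    gene_id = character(), scope = character(), stringsAsFactors = FALSE
  )
  carriers <- if (length(carriers)) do.call(rbind, carriers) else data.frame(
    cnv_id = character(), sample_id = character(), group = character(),
    copy_number = numeric(), stringsAsFactors = FALSE
  )
  rownames(cnvs) <- rownames(carriers) <- NULL

  ## truth gene sets by brute-force interval intersection against the exon
  ## table — a plant's interval can reach beyond its target gene, and the
  ## truth must reflect what the intervals actually overlap
  exon_hits <- function(rows) {
    if (nrow(rows) == 0 || nrow(genes$exons) == 0) return(character())
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(rows$chrom, to_iranges(rows$start, rows$end)),
      GenomicRanges::GRanges(genes$exons$chrom,
                             to_iranges(genes$exons$start, genes$exons$end))
    )
    sort(unique(genes$exons$gene_id[S4Vectors::subjectHits(hits)]))
  }
  genes_a <- exon_hits(cnvs)
  genes_b <- exon_hits(cnvs[cnvs$scope == "both", , drop = FALSE])
  structure(
    list(samples = samples, cnvs = cnvs, carriers = carriers,
         gene_truth = list(genes_a = genes_a, genes_b = genes_b,
                           differential = setdiff(genes_a, genes_b))),
    class = "planted_cohort"
  )
}

#' @export
print.planted_cohort <- function(x, ...) {
  cat("planted_cohort:", nrow(x$samples), "samples,", nrow(x$cnvs),
      "planted loci,", nrow(x$carriers), "carrier genotypes\n")
  invisible(x)
}

#' Planted intervals for one sample
#'
#' @param cohort A `planted_cohort`.
#' @param sample_id One sample.
#' @return Data frame (chrom, start, end, copy_number), possibly empty.
#' @export
sample_planted <- function(cohort, sample_id) {
  stopifnot(inherits(cohort, "planted_cohort"))
  ids <- cohort$carriers$cnv_id[cohort$carriers$sample_id == sample_id]
  out <- cohort$cnvs[cohort$cnvs$cnv_id %in% ids,
                     c("chrom", "start", "end", "copy_number")]
  rownames(out) <- NULL
  out
}

## unimodal multiplicative GC factor, peak at GC = 0.45; strength 0 disables
gc_factor <- function(gc, strength) {
  exp(-strength * (gc - 0.45)^2)
}

#' Simulate a binned read-depth profile for one sample
#'
#' Bin counts are drawn from a negative-binomial (Poisson when
#' `dispersion = 0`) with expectation
#' `(copy_number / 2) * mean_coverage * bin_size / read_length *
#' gc_factor(GC)`, i.e. expected read starts per bin for a diploid genome
#' scaled by local copy number and a unimodal GC bias peaking at GC 0.45.
#' A copy-number-0 region therefore has expectation 0 and, counts being
#' non-negative, depth exactly 0.
#'
#' @param genome A `cnv_genome`.
#' @param planted Data frame (chrom, start, end, copy_number) of this
#'   sample's CNVs; may be empty. A bin takes the copy number of the
#'   planted interval containing its midpoint (diploid 2 elsewhere).
#' @param mean_coverage Mean fold coverage of the diploid genome
#'   (default 7.48, a low-coverage resequencing design).
#' @param bin_size Bin width in bp (default 500).
#' @param read_length Read length equivalent in bp used to convert fold
#'   coverage into expected reads per bin (default 100).
#' @param gc_bias_strength Strength of the multiplicative GC bias
#'   (0 = none).
#' @param dispersion Negative-binomial overdispersion: variance =
#'   mu + dispersion * mu^2; 0 gives Poisson.
#' @param deterministic If TRUE, return the exact (real-valued)
#'   expectations instead of sampling — useful for exactness contracts.
#' @param sample_id Label stored on the profile.
#' @param seed Optional seed.
#' @return A `depth_profile`: data frame (chrom, start, end, gc, count)
#'   with attributes `sample_id` and `bin_size`.
#' @export
simulate_depth <- function(genome, planted = NULL, mean_coverage = 7.48,
                           bin_size = 500, read_length = 100,
                           gc_bias_strength = 0, dispersion = 0.02,
                           deterministic = FALSE, sample_id = "sample",
                           seed = NULL) {
  stopifnot(inherits(genome, "cnv_genome"))
  check_scalar_number(mean_coverage, "mean_coverage", min = 0, strict_min = TRUE)
  check_scalar_number(bin_size, "bin_size", min = 1)
  check_scalar_number(dispersion, "dispersion", min = 0)
  seed_if(seed)
  bins <- do.call(rbind, lapply(genome$chrom_names, function(chrom) {
    len <- genome$chrom_lengths[[chrom]]
    start <- seq(0L, len - 1L, by = bin_size)
    end <- pmin(start + bin_size, len)
    mid <- (start + end) / 2
    data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
               gc = genome_gc_at(genome, chrom, mid),
               stringsAsFactors = FALSE)
  }))
  cn <- rep(2, nrow(bins))
  if (!is.null(planted) && nrow(planted)) {
    mid <- (bins$start + bins$end) / 2
    for (i in seq_len(nrow(planted))) {
      hit <- bins$chrom == planted$chrom[i] &
        mid >= planted$start[i] & mid < planted$end[i]
      cn[hit] <- planted$copy_number[i]
    }
  }
  width <- bins$end - bins$start
  mu <- (cn / 2) * mean_coverage * width / read_length *
    gc_factor(bins$gc, gc_bias_strength)
  count <- if (deterministic) {
    mu
  } else if (dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  bins$count <- count
  depth_profile(bins, sample_id = sample_id, bin_size = bin_size)
}

#' Simulate a whole cohort's depth profiles
#'
#' One [simulate_depth()] call per sample, each with a sub-seed derived
#' from `seed`, so a fixed seed gives a bit-identical cohort.
#'
#' @inheritParams simulate_depth
#' @param cohort A `planted_cohort`.
#' @return Named list of `depth_profile`s, one per sample.
#' @export
simulate_cohort_depth <- function(genome, cohort, mean_coverage = 7.48,
                                  bin_size = 500, read_length = 100,
                                  gc_bias_strength = 0, dispersion = 0.02,
                                  seed = 1) {
  stopifnot(inherits(cohort, "planted_cohort"))
  profs <- lapply(seq_len(nrow(cohort$samples)), function(i) {
    sid <- cohort$samples$sample_id[i]
    simulate_depth(genome, sample_planted(cohort, sid),
                   mean_coverage = mean_coverage, bin_size = bin_size,
                   read_length = read_length,
                   gc_bias_strength = gc_bias_strength,
                   dispersion = dispersion, sample_id = sid,
                   seed = (seed * 1000L + i) %% .Machine$integer.max)
  })
  names(profs) <- cohort$samples$sample_id
  profs
}

#' Simulate a qPCR Ct table from true copy numbers
#'
#' Inverse model of the delta-delta-Ct quantification: for each
#' sample x target, `target_ct = reference_ct + offset(target) -
#' log2(CN / 2) + noise`, with the reference assay at a fixed baseline
#' (plus noise) and three technical replicates. CN = 0 cannot amplify and
#' is encoded by a Ct ceiling.
#'
#' @param truth Data frame (sample_id, target_id, copy_number), one row per
#'   sample x target.
#' @param ct_noise_sd Replicate noise SD in cycles (>= 0).
#' @param reference_ct Reference-assay baseline Ct.
#' @param target_offset Per-target offset added to the diploid target Ct;
#'   scalar or named by target_id.
#' @param ct_ceiling Ct reported for non-amplifying (CN 0) targets.
#' @param n_replicates Technical replicates per sample x target (default 3).
#' @param seed Optional seed.
#' @return Data frame (sample_id, target_id, replicate, target_ct,
#'   reference_ct).
#' @export
simulate_qpcr <- function(truth, ct_noise_sd = 0.15, reference_ct = 20,
                          target_offset = 2, ct_ceiling = 38,
                          n_replicates = 3, seed = NULL) {
  need <- c("sample_id", "target_id", "copy_number")
  if (!all(need %in% names(truth))) {
    abort("truth must have columns: ", paste(need, collapse = ", "))
  }
  if (any(truth$copy_number < 0)) abort("copy numbers must be >= 0")
  check_scalar_number(ct_noise_sd, "ct_noise_sd", min = 0)
  seed_if(seed)
  targets <- unique(truth$target_id)
  offs <- if (length(target_offset) == 1) {
    stats::setNames(rep(target_offset, length(targets)), targets)
  } else {
    target_offset[targets]
  }
  rows <- truth[rep(seq_len(nrow(truth)), each = n_replicates), ]
  rows$replicate <- rep(seq_len(n_replicates), nrow(truth))
  noise <- function(n) stats::rnorm(n, 0, ct_noise_sd)
  ref_ct <- reference_ct + noise(nrow(rows))
  tgt_ct <- ifelse(
    rows$copy_number == 0,
    ct_ceiling,
    reference_ct + offs[rows$target_id] - log2(rows$copy_number / 2) +
      noise(nrow(rows))
  )
  out <- data.frame(
    sample_id = rows$sample_id, target_id = rows$target_id,
    replicate = rows$replicate, target_ct = tgt_ct, reference_ct = ref_ct,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build a synthetic term map for enrichment tests
#'
#' Random gene-set terms over a population, plus optional planted terms
#' that cover a given study set (and little else), so enrichment detection
#' is falsifiable.
#'
#' @param population Character vector of population gene ids.
#' @param n_terms Number of random background terms.
#' @param term_size Genes per random term.
#' @param planted Optional named list of term_id -> gene vector to include
#'   verbatim.
#' @param seed Optional seed.
#' @return Named list term_id -> character vector of gene ids.
#' @export
make_term_map <- function(population, n_terms = 20, term_size = 5,
                          planted = NULL, seed = NULL) {
  seed_if(seed)
  tm <- lapply(seq_len(n_terms), function(i) {
    sample(population, min(term_size, length(population)))
  })
  names(tm) <- sprintf("TERM:%04d", seq_len(n_terms))
  c(planted, tm)
}
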