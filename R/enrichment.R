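#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance that a random study set of size `n` drawn from a population of
#' `N` genes, `K` of which carry the term, contains `k` or more term
#' genes.
#'
#' @param k Study genes carrying the term.
#' @param K Population genes carrying the term.
#' @param n Study-set size.
#' @param N Population size.
#' @return The p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  ok <- k >= 0 & K >= k & N >= K & n >= k & N >= n
  if (!all(ok)) abort("inconsistent counts: need k <= K <= N and k <= n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q_i = p_(i) * m / i, monotone from the top,
#' capped at 1), returned in the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Term enrichment of a study gene set
#'
#' One hypergeometric upper-tail test per term that intersects the study
#' set, BH-adjusted across the tested terms, significance called at
#' `adjusted_p <= alpha`.
#'
#' @param study_set Character vector of study gene ids (must all be in
#'   `population`).
#' @param term_map Named list: term_id -> character vector of population
#'   gene ids (genes outside the population are dropped).
#' @param population Character vector of population gene ids.
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @param term_meta Optional data frame (term_id, name, category) merged
#'   into the output.
#' @return Data frame sorted by adjusted_p: term_id, k, K, n, N, p_value,
#'   adjusted_p, significant, genes (comma-separated study hits), plus any
#'   metadata columns.
#' @export
enrich <- function(study_set, term_map, population, alpha = 0.05,
                   term_meta = NULL) {
  population <- unique(as.character(population))
  study_set <- unique(as.character(study_set))
  outside <- setdiff(study_set, population)
  if (length(outside)) {
    abort("study genes not in population: ", paste(outside, collapse = ", "))
  }
  N <- length(population)
  n <- length(study_set)
  rows <- lapply(names(term_map), function(tid) {
    tg <- intersect(unique(term_map[[tid]]), population)
    hit <- intersect(study_set, tg)
    if (length(hit) == 0) return(NULL)
    data.frame(term_id = tid, k = length(hit), K = length(tg), n = n, N = N,
               p_value = hypergeom_test(length(hit), length(tg), n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$adjusted_p <- bh_adjust(res$p_value)
  res$significant <- res$adjusted_p <= alpha
  if (!is.null(term_meta)) {
    res <- merge(res, term_meta, by = "term_id", all.x = TRUE, sort = FALSE)
  }
  res <- res[order(res$adjusted_p, res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}
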