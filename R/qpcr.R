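#' Copy number from qPCR Ct values (delta-delta-Ct)
#'
#' For each sample x target: replicate Ct values are averaged,
#' `dCt = mean(target Ct) - mean(reference Ct)`, `ddCt = dCt -
#' mean(dCt over calibrator samples)` for that target, relative quantity
#' `RQ = 2^(-ddCt)`, and — the calibrators being assumed diploid —
#' `copy_number = 2 * RQ`. Adding a constant to every Ct leaves the
#' estimates unchanged.
#'
#' @param table qPCR table: sample_id, target_id, replicate, target_ct,
#'   reference_ct.
#' @param calibrator_samples Sample ids assumed diploid at every target
#'   (>= 1 must carry data for each target).
#' @param expected_replicates Replicates expected per sample x target
#'   (default 3); fewer triggers a warning and the available ones are
#'   used.
#' @return Data frame: sample_id, target_id, mean_delta_ct,
#'   delta_delta_ct, relative_quantity, copy_number, rounded_cn (half away
#'   from zero, floored at 0).
#' @export
delta_delta_ct <- function(table, calibrator_samples,
                           expected_replicates = 3) {
  need <- c("sample_id", "target_id", "replicate", "target_ct",
            "reference_ct")
  if (!all(need %in% names(table))) {
    abort("table must have columns: ", paste(need, collapse = ", "))
  }
  if (length(calibrator_samples) == 0) {
    abort("at least one calibrator sample is required")
  }
  key <- interaction(table$sample_id, table$target_id, drop = TRUE)
  nrep <- tapply(table$replicate, key, length)
  if (any(nrep < expected_replicates)) {
    warning(sum(nrep < expected_replicates),
            " sample x target pair(s) have fewer than ",
            expected_replicates, " replicates; using available ones")
  }
  agg <- do.call(rbind, lapply(split(table, key), function(d) {
    data.frame(sample_id = d$sample_id[1], target_id = d$target_id[1],
               mean_target_ct = mean(d$target_ct),
               mean_reference_ct = mean(d$reference_ct),
               stringsAsFactors = FALSE)
  }))
  agg$mean_delta_ct <- agg$mean_target_ct - agg$mean_reference_ct
  est <- do.call(rbind, lapply(split(agg, agg$target_id), function(d) {
    cal <- d$mean_delta_ct[d$sample_id %in% calibrator_samples]
    if (length(cal) == 0) {
      abort("no calibrator measurements for target ", d$target_id[1])
    }
    d$delta_delta_ct <- d$mean_delta_ct - mean(cal)
    d
  }))
  est$relative_quantity <- 2^(-est$delta_delta_ct)
  est$copy_number <- 2 * est$relative_quantity
  est$rounded_cn <- pmax(0, round_half_away(est$copy_number))
  est <- est[order(est$sample_id, est$target_id),
             c("sample_id", "target_id", "mean_delta_ct", "delta_delta_ct",
               "relative_quantity", "copy_number", "rounded_cn")]
  rownames(est) <- NULL
  est
}

#' Concordance between qPCR and sequencing copy numbers
#'
#' Pairs estimates with sequencing-derived copy numbers on
#' (sample, target). Direction concordance calls a pair concordant when
#' both sides agree on gain / loss / neutral relative to diploid; exact
#' concordance additionally requires the rounded integers to match. Both
#' fractions are reported.
#'
#' @param estimates Output of [delta_delta_ct()].
#' @param sequencing_cns Data frame (sample_id, target_id, copy_number)
#'   from the sequencing side.
#' @return List: direction_concordance, exact_concordance, n_pairs,
#'   n_direction_concordant, n_exact_concordant, unmatched (keys present
#'   on only one side).
#' @export
concordance <- function(estimates, sequencing_cns) {
  key_e <- paste(estimates$sample_id, estimates$target_id, sep = "|")
  key_s <- paste(sequencing_cns$sample_id, sequencing_cns$target_id,
                 sep = "|")
  unmatched <- c(setdiff(key_e, key_s), setdiff(key_s, key_e))
  m <- merge(estimates, sequencing_cns, by = c("sample_id", "target_id"),
             suffixes = c("_qpcr", "_seq"))
  if (nrow(m) == 0) abort("no matched (sample, target) pairs to validate")
  dir_of <- function(cn) sign(round_half_away(cn) - 2)
  dir_ok <- dir_of(m$copy_number_qpcr) == dir_of(m$copy_number_seq)
  exact_ok <- m$rounded_cn == round_half_away(m$copy_number_seq)
  list(
    direction_concordance = mean(dir_ok),
    exact_concordance = mean(exact_ok),
    n_pairs = nrow(m),
    n_direction_concordant = sum(dir_ok),
    n_exact_concordant = sum(exact_ok),
    unmatched = unmatched
  )
}
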