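#' Candidate miRNA-target pairs from DE results and predicted targets
#'
#' Applies the first two dysregulation criteria: the miRNA is on the
#' disease-associated list, the pair is on the predicted-target list, both
#' members are differentially expressed, and their directions are reversed
#' (miRNA up with target down, or vice versa).
#'
#' @param disease_mirnas Character vector of disease-associated miRNA IDs.
#' @param predicted_pairs Data frame with columns `mirna`, `target`.
#' @param de_mirna,de_gene DE result data frames from
#'   [differential_expression()].
#' @return Data frame `mirna`, `target`, `mirna_dir`, `target_dir`.
#' @export
candidate_pairs <- function(disease_mirnas, predicted_pairs,
                            de_mirna, de_gene) {
  if (is.null(predicted_pairs) || nrow(predicted_pairs) == 0)
    stop("empty predicted-pair list")
  dm <- stats::setNames(de_mirna$direction, de_mirna$feature)
  dg <- stats::setNames(de_gene$direction, de_gene$feature)
  p <- predicted_pairs[predicted_pairs$mirna %in% disease_mirnas, , drop = FALSE]
  p$mirna_dir <- unname(dm[p$mirna])
  p$target_dir <- unname(dg[p$target])
  keep <- !is.na(p$mirna_dir) & !is.na(p$target_dir) &
    p$mirna_dir != "ns" & p$target_dir != "ns" &
    p$mirna_dir != p$target_dir
  out <- p[keep, c("mirna", "target", "mirna_dir", "target_dir"), drop = FALSE]
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of tumors showing the reversed high/low pattern
#'
#' For an up-regulated miRNA the pattern is miRNA `"high"` with target
#' `"low"` in the same tumor; for a down-regulated miRNA it is miRNA
#' `"low"` with target `"high"`. The returned value is the fraction of
#' tumor samples exhibiting the pattern.
#'
#' @param mirna,target Feature IDs.
#' @param states High/low state matrix from [dichotomize_by_median()]
#'   covering both features.
#' @param mirna_dir Direction of the miRNA's differential expression
#'   (`"up"` or `"down"`).
#' @return A fraction in \[0, 1\].
#' @export
pattern_fraction <- function(mirna, target, states, mirna_dir) {
  for (f in c(mirna, target))
    if (!f %in% rownames(states))
      stop("feature absent from the state matrix: ", f)
  if (!mirna_dir %in% c("up", "down")) stop("'mirna_dir' must be up or down")
  ms <- states[mirna, ]
  ts <- states[target, ]
  if (mirna_dir == "up") mean(ms == "high" & ts == "low")
  else mean(ms == "low" & ts == "high")
}

#' Screen candidate pairs for dysregulated interactions
#'
#' Retains candidate pairs whose reversed high/low pattern is present in
#' strictly more than `cfg$pattern_min_fraction` of tumor samples, and
#' annotates each with its pattern fraction. Output order is deterministic
#' (sorted by miRNA, then target).
#'
#' @param candidates Data frame from [candidate_pairs()].
#' @param states State matrix from [dichotomize_by_median()] covering both
#'   miRNAs and genes (e.g. `rbind` of the two state matrices).
#' @param cfg An [mtk_config()].
#' @return Data frame `mirna`, `target`, `mirna_dir`, `target_dir`,
#'   `pattern_fraction`.
#' @export
screen_dysregulated <- function(candidates, states, cfg = mtk_config()) {
  if (nrow(candidates) == 0) {
    out <- candidates
    out$pattern_fraction <- numeric(0)
    return(out)
  }
  frac <- vapply(seq_len(nrow(candidates)), function(i) {
    pattern_fraction(candidates$mirna[i], candidates$target[i], states,
                     candidates$mirna_dir[i])
  }, numeric(1))
  out <- candidates
  out$pattern_fraction <- frac
  out <- out[frac > cfg$pattern_min_fraction, , drop = FALSE]
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
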