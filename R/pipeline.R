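#' Run the full key-interaction discovery pipeline
#'
#' Chains every stage on a cohort: read-support filtering (2 reads for
#' miRNAs, 10 for genes, each in more than half the samples), log2 RPM/RPKM
#' normalization, Welch differential expression with BH correction,
#' median dichotomization of tumors, the three-criteria dysregulation
#' screen, and the resampled-Cox plus pattern-split log-rank selection of
#' key interactions.
#'
#' @param inputs List with `mirna_counts`, `mrna_counts` ([expr_matrix()]
#'   of raw counts), `gene_lengths` (named kb vector), `clinical`
#'   (`clinical_table`), `disease_mirnas`, `predicted_pairs` — the shape
#'   returned by [simulate_cohort()].
#' @param cfg An [mtk_config()].
#' @param mirna_min_reads,gene_min_reads Read-filter operating points.
#' @return List with all intermediates: `de_mirna`, `de_gene`, `states`,
#'   `candidates`, `dysregulated`, `key_interactions`, `mirna_log`,
#'   `gene_log` (tumor-only log matrices), `outcome_groups`.
#' @export
run_pipeline <- function(inputs, cfg = mtk_config(),
                         mirna_min_reads = 2, gene_min_reads = 10) {
  mir <- filter_low_expression(inputs$mirna_counts, mirna_min_reads)
  gen <- filter_low_expression(inputs$mrna_counts, gene_min_reads)
  mir_log <- normalize_counts(mir)
  gen_log <- normalize_counts(gen, gene_lengths_kb = inputs$gene_lengths)
  de_mirna <- differential_expression(mir_log, cfg = cfg)
  de_gene <- differential_expression(gen_log, cfg = cfg)
  states <- rbind(dichotomize_by_median(mir_log),
                  dichotomize_by_median(gen_log))
  cand <- candidate_pairs(inputs$disease_mirnas, inputs$predicted_pairs,
                          de_mirna, de_gene)
  dys <- screen_dysregulated(cand, states, cfg)
  mir_tum <- subset_condition(mir_log, "tumor")
  gen_tum <- subset_condition(gen_log, "tumor")
  key <- if (nrow(dys) > 0) {
    ratios <- ratio_matrix(dys, mir_tum, gen_tum)
    select_key_interactions(dys, ratios, states, inputs$clinical, cfg)
  } else {
    empty <- dys
    for (col in c("median_beta", "beta_sign", "sig_freq", "logrank_chisq",
                  "logrank_p"))
      empty[[col]] <- numeric(0)
    empty$risk_group <- character(0)
    empty
  }
  list(de_mirna = de_mirna, de_gene = de_gene, states = states,
       candidates = cand, dysregulated = dys, key_interactions = key,
       mirna_log = mir_tum, gene_log = gen_tum,
       outcome_groups = attr(key, "outcome_groups"))
}

#' Recovery metrics against planted truth
#'
#' Sensitivity is the fraction of planted prognostic pairs recovered among
#' the selected key interactions; the false-discovery proportion is the
#' fraction of selected pairs that are not planted prognostic pairs (0 when
#' nothing is selected).
#'
#' @param key_interactions Selected pairs (columns `mirna`, `target`).
#' @param truth Planted-truth data frame from [simulate_expression()].
#' @return List with `sensitivity`, `fdp`, `n_selected`, `n_true`.
#' @export
recovery_metrics <- function(key_interactions, truth) {
  prog <- truth[truth$is_prognostic, ]
  true_keys <- paste(prog$mirna, prog$target, sep = "|")
  sel_keys <- if (nrow(key_interactions) > 0)
    paste(key_interactions$mirna, key_interactions$target, sep = "|")
  else character(0)
  tp <- length(intersect(sel_keys, true_keys))
  list(sensitivity = if (length(true_keys) > 0) tp / length(true_keys) else NA,
       fdp = if (length(sel_keys) > 0)
         (length(sel_keys) - tp) / length(sel_keys) else 0,
       n_selected = length(sel_keys), n_true = length(true_keys))
}

#' Reference per-cancer key-interaction counts
#'
#' Published counts of prognosis-related key miRNA-target interactions,
#' miRNAs and targets across 16 TCGA cancer types, bundled as reference
#' input for summary arithmetic (e.g. the mean and maximum interaction
#' count per cancer type).
#'
#' @return Data frame `cancer_type`, `n_interactions`, `n_mirnas`,
#'   `n_targets`.
#' @export
tcga_interaction_counts <- function() {
  path <- system.file("extdata", "tcga_key_interaction_counts.tsv",
                      package = "mirtarkey", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
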