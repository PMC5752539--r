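#' Pipeline run configuration
#'
#' Collects every global threshold of the key-interaction pipeline in one
#' validated list. The defaults are the published operating point of the
#' method: differential expression at FDR < 0.05 with fold change > 1.2,
#' joint high/low pattern in more than 20% of tumors, 1,000 resamples of 80%
#' of each outcome-extreme group with a significance frequency above 0.6,
#' log-rank confirmation at 0.05, random-walk restart probability 0.7 with
#' 1,000 degree-preserving network permutations, and hub miRNAs defined as
#' the top 10% of nodes by degree regulating at least 10 targets.
#'
#' @param de_fdr BH-adjusted FDR cutoff for differential expression.
#' @param de_fc Linear fold-change cutoff (larger/smaller ratio, so the rule
#'   is symmetric in direction).
#' @param pattern_min_fraction Minimum fraction of tumor samples showing the
#'   reversed high/low pattern; the comparison is strict (`>`).
#' @param n_resamples Number of resampled Cox fits per pair.
#' @param resample_fraction Fraction of each outcome group drawn (without
#'   replacement) per resample.
#' @param sig_freq_threshold Minimum fraction of resamples with Cox Wald
#'   p < 0.05; strict (`>`).
#' @param logrank_alpha Significance level of the pattern-split log-rank test.
#' @param restart_prob Restart probability of the random walk with restart.
#' @param n_permutations Number of degree-preserving network rewirings for
#'   the hallmark permutation test.
#' @param hub_top_fraction Fraction of top-degree nodes defining hub
#'   candidates.
#' @param hub_min_targets Minimum number of targets a hub miRNA must regulate.
#' @param sign_rule How coefficient-sign consistency is judged across
#'   resamples: `"all"` requires one sign in every converged resample,
#'   `"significant"` only in the resamples with p < 0.05.
#' @param seed Master random seed; every stochastic stage derives its stream
#'   from it.
#' @return A list of class `mtk_config`.
#' @export
mtk_config <- function(de_fdr = 0.05,
                       de_fc = 1.2,
                       pattern_min_fraction = 0.20,
                       n_resamples = 1000L,
                       resample_fraction = 0.80,
                       sig_freq_threshold = 0.60,
                       logrank_alpha = 0.05,
                       restart_prob = 0.70,
                       n_permutations = 1000L,
                       hub_top_fraction = 0.10,
                       hub_min_targets = 10L,
                       sign_rule = c("all", "significant"),
                       seed = 1L) {
  cfg <- list(
    de_fdr = de_fdr, de_fc = de_fc,
    pattern_min_fraction = pattern_min_fraction,
    n_resamples = as.integer(n_resamples),
    resample_fraction = resample_fraction,
    sig_freq_threshold = sig_freq_threshold,
    logrank_alpha = logrank_alpha,
    restart_prob = restart_prob,
    n_permutations = as.integer(n_permutations),
    hub_top_fraction = hub_top_fraction,
    hub_min_targets = as.integer(hub_min_targets),
    sign_rule = match.arg(sign_rule),
    seed = as.integer(seed)
  )
  probs <- c("de_fdr", "pattern_min_fraction", "resample_fraction",
             "sig_freq_threshold", "logrank_alpha", "restart_prob",
             "hub_top_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single number in [0, 1]", p))
  }
  for (p in c("n_resamples", "n_permutations", "hub_min_targets")) {
    v <- cfg[[p]]
    if (is.na(v) || v < 1L)
      stop(sprintf("'%s' must be a positive integer", p))
  }
  if (!is.numeric(cfg$de_fc) || cfg$de_fc < 1)
    stop("'de_fc' must be a fold change >= 1")
  if (is.na(cfg$seed)) stop("'seed' must be an integer")
  class(cfg) <- "mtk_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file holds any subset of [mtk_config()] fields; unspecified fields
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `mtk_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a YAML mapping")
  unknown <- setdiff(names(vals), names(formals(mtk_config)))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(mtk_config, vals)
}

#' @export
print.mtk_config <- function(x, ...) {
  cat("mirtarkey run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a per-stage RNG seed from the master seed; keeps independent stages
# on reproducible, distinct streams while staying below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(expression = 11L, survival = 23L, network = 37L,
               pathways = 41L, candidates = 53L, resample = 67L,
               permutation = 79L, clustering = 97L)
  off <- offsets[[stage]]
  (abs(as.integer(seed)) %% 2000000L) * 1000L + off
}
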