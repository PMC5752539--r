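#' Kaplan-Meier median survival with confidence interval
#'
#' The median is the first time the Kaplan-Meier curve falls to 0.5 or
#' below; its confidence interval inverts the log-log-transformed
#' Greenwood confidence band (the Brookmeyer-Crowley construction, as
#' implemented by `survival::survfit` with `conf.type = "log-log"`).
#'
#' @param time Follow-up times (>= 10 subjects required).
#' @param event Event indicators (0/1); at least one event required.
#' @param conf_level Confidence level of the interval.
#' @return List with `median`, `lower`, `upper` (days).
#' @export
km_median_ci <- function(time, event, conf_level = 0.95) {
  if (length(time) < 10)
    stop("need at least 10 subjects to estimate the median CI")
  if (sum(event) < 1)
    stop("all subjects censored; median survival undefined")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level, conf.type = "log-log")
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  lo <- unname(q$lower)
  up <- unname(q$upper)
  if (is.na(med))
    stop("survival curve never reaches 50%; a larger or longer-followed ",
         "cohort is needed")
  if (is.na(lo) || is.na(up))
    stop("median CI bound undefined; a larger cohort is needed")
  list(median = med, lower = lo, upper = up)
}

#' Assign outcome-extreme patient groups
#'
#' Good-outcome patients have follow-up time strictly above the upper bound
#' of the Kaplan-Meier median's confidence interval (alive or dead, they
#' provably outlived the bound). Poor-outcome patients died strictly before
#' the lower bound; patients censored below the lower bound are
#' uninformative and stay unassigned, as do all patients inside the
#' interval.
#'
#' @param clinical A `clinical_table`.
#' @param conf_level Confidence level of the median CI.
#' @param min_group Minimum size of each group.
#' @return List with `good` and `poor` sample-ID vectors plus `median`,
#'   `lower`, `upper`.
#' @export
assign_outcome_groups <- function(clinical, conf_level = 0.95,
                                  min_group = 5L) {
  ci <- km_median_ci(clinical$time, clinical$event, conf_level)
  good <- clinical$sample[clinical$time > ci$upper]
  poor <- clinical$sample[clinical$event == 1 & clinical$time < ci$lower]
  if (length(good) < min_group || length(poor) < min_group)
    stop(sprintf(
      "outcome groups too small (good = %d, poor = %d; need >= %d each)",
      length(good), length(poor), min_group))
  list(good = good, poor = poor,
       median = ci$median, lower = ci$lower, upper = ci$upper)
}

#' Per-patient miRNA:target expression ratio
#'
#' On the log2 scale the ratio of a miRNA to its target is the difference
#' of their log expressions, which keeps the Cox covariate linear and
#' numerically stable.
#'
#' @param mirna_log,target_log Named log2 expression vectors over the same
#'   samples.
#' @return Named numeric vector of per-patient log ratios.
#' @export
expression_ratio <- function(mirna_log, target_log) {
  if (length(mirna_log) != length(target_log))
    stop("sample mismatch between miRNA and target vectors")
  if (!is.null(names(mirna_log)) && !is.null(names(target_log))) {
    if (!setequal(names(mirna_log), names(target_log)))
      stop("sample mismatch between miRNA and target vectors")
    target_log <- target_log[names(mirna_log)]
  }
  mirna_log - target_log
}

#' Resampled univariate Cox screen of one expression ratio
#'
#' Draws `cfg$n_resamples` subsamples, each taking `cfg$resample_fraction`
#' of the good-outcome and of the poor-outcome group without replacement,
#' and fits a univariate Cox model of survival on the ratio in each.
#' The pair passes when the coefficient sign is consistent and the fraction
#' of resamples with Wald p < 0.05 strictly exceeds
#' `cfg$sig_freq_threshold`. Resamples with fewer than 2 events, a constant
#' covariate, or a non-converged fit are skipped but stay in the frequency
#' denominator. Under `cfg$sign_rule = "all"` (default) the sign must agree
#' across every converged resample; `"significant"` restricts the check to
#' the significant ones.
#'
#' @param ratio Named ratio vector covering at least the grouped samples.
#' @param groups Outcome groups from [assign_outcome_groups()].
#' @param clinical A `clinical_table`.
#' @param cfg An [mtk_config()].
#' @return List with `sig_freq`, `sign_consistent`, `median_beta`,
#'   `beta_sign`, `n_used`, `pass`.
#' @export
resampled_cox_screen <- function(ratio, groups, clinical, cfg = mtk_config()) {
  rownames(clinical) <- clinical$sample
  all_s <- c(groups$good, groups$poor)
  missing <- setdiff(all_s, names(ratio))
  if (length(missing) > 0)
    stop("ratio vector lacks grouped sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  ng <- floor(cfg$resample_fraction * length(groups$good))
  np <- floor(cfg$resample_fraction * length(groups$poor))
  betas <- rep(NA_real_, cfg$n_resamples)
  sig <- rep(FALSE, cfg$n_resamples)
  for (b in seq_len(cfg$n_resamples)) {
    s <- c(sample(groups$good, ng), sample(groups$poor, np))
    ti <- clinical[s, "time"]; ev <- clinical[s, "event"]
    xv <- ratio[s]
    if (sum(ev) < 2 || stats::sd(xv) == 0) next
    fit <- cox_univariate(xv, ti, ev)
    if (!fit$converged || !is.finite(fit$se)) next
    betas[b] <- fit$beta
    sig[b] <- fit$p < 0.05
  }
  used <- !is.na(betas)
  sig_freq <- sum(sig) / cfg$n_resamples
  signs <- sign(betas[used])
  relevant <- if (cfg$sign_rule == "significant") signs[sig[used]] else signs
  sign_consistent <- length(relevant) > 0 && length(unique(relevant)) == 1
  median_beta <- if (any(used)) stats::median(betas[used]) else NA_real_
  list(sig_freq = sig_freq, sign_consistent = sign_consistent,
       median_beta = median_beta,
       beta_sign = if (is.na(median_beta)) NA_integer_
                   else as.integer(sign(median_beta)),
       n_used = sum(used),
       pass = sign_consistent && sig_freq > cfg$sig_freq_threshold)
}

#' Split patients by the reversed miRNA/target expression pattern
#'
#' Group A holds tumors with the miRNA high and the target low, group B
#' those with the miRNA low and the target high; tumors matching neither
#' pattern are excluded.
#'
#' @param mirna,target Feature IDs.
#' @param states State matrix from [dichotomize_by_median()].
#' @return List with sample-ID vectors `A` and `B`.
#' @export
pattern_split <- function(mirna, target, states) {
  for (f in c(mirna, target))
    if (!f %in% rownames(states))
      stop("feature absent from the state matrix: ", f)
  ms <- states[mirna, ]; ts <- states[target, ]
  list(A = colnames(states)[ms == "high" & ts == "low"],
       B = colnames(states)[ms == "low" & ts == "high"])
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom, symmetric in the
#' group labels.
#'
#' @param groupA,groupB Sample-ID vectors.
#' @param clinical A `clinical_table` covering both groups.
#' @return List with `chisq`, `p`, `n`.
#' @export
logrank_test <- function(groupA, groupB, clinical) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("both groups must be non-empty")
  rownames(clinical) <- clinical$sample
  s <- c(groupA, groupB)
  missing <- setdiff(s, clinical$sample)
  if (length(missing) > 0)
    stop("clinical data missing for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  ti <- clinical[s, "time"]; ev <- clinical[s, "event"]
  if (sum(ev) == 0) stop("no events in either group")
  grp <- rep(c("A", "B"), c(length(groupA), length(groupB)))
  sd <- survival::survdiff(survival::Surv(ti, ev) ~ grp)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = length(s))
}

#' Select prognosis-related key miRNA-target interactions
#'
#' The optimization core: each dysregulated pair's log ratio is screened by
#' resampled univariate Cox regression on the outcome-extreme groups; pairs
#' with a consistent coefficient sign and significance frequency above the
#' threshold are then confirmed by a log-rank test between the two reversed
#' expression-pattern groups over the full cohort. Survivors with log-rank
#' p below `cfg$logrank_alpha` are the key interactions, labelled high-risk
#' (positive coefficient) or low-risk (negative).
#'
#' @param screened Data frame from [screen_dysregulated()].
#' @param ratios Matrix of log ratios (rows named `"<mirna>|<target>"`,
#'   columns tumor samples); build with [ratio_matrix()].
#' @param states State matrix from [dichotomize_by_median()] covering both
#'   feature kinds.
#' @param clinical A `clinical_table`.
#' @param cfg An [mtk_config()]; `cfg$seed` fixes the resampling streams.
#' @return Data frame of key interactions (one row per selected pair):
#'   `mirna`, `target`, `mirna_dir`, `target_dir`, `pattern_fraction`,
#'   `median_beta`, `beta_sign`, `sig_freq`, `logrank_chisq`, `logrank_p`,
#'   `risk_group`, sorted by (miRNA, target). The full per-pair diagnostics
#'   (including non-selected pairs) are attached as attribute
#'   `"diagnostics"`.
#' @export
select_key_interactions <- function(screened, ratios, states, clinical,
                                    cfg = mtk_config()) {
  groups <- assign_outcome_groups(clinical)
  n <- nrow(screened)
  diag <- screened
  diag$median_beta <- NA_real_; diag$beta_sign <- NA_integer_
  diag$sig_freq <- NA_real_; diag$sign_consistent <- NA
  diag$cox_pass <- FALSE
  diag$logrank_chisq <- NA_real_; diag$logrank_p <- NA_real_
  set.seed(stage_seed(cfg$seed, "resample"))
  for (i in seq_len(n)) {
    key <- paste(screened$mirna[i], screened$target[i], sep = "|")
    if (!key %in% rownames(ratios))
      stop("no ratio row for pair ", key)
    scr <- resampled_cox_screen(ratios[key, ], groups, clinical, cfg)
    diag$median_beta[i] <- scr$median_beta
    diag$beta_sign[i] <- scr$beta_sign
    diag$sig_freq[i] <- scr$sig_freq
    diag$sign_consistent[i] <- scr$sign_consistent
    diag$cox_pass[i] <- scr$pass
    if (!scr$pass) next
    grp <- pattern_split(screened$mirna[i], screened$target[i], states)
    grp$A <- intersect(grp$A, clinical$sample)
    grp$B <- intersect(grp$B, clinical$sample)
    if (length(grp$A) == 0 || length(grp$B) == 0) {
      message("pair ", key, ": an expression-pattern group is empty; dropped")
      next
    }
    lr <- logrank_test(grp$A, grp$B, clinical)
    diag$logrank_chisq[i] <- lr$chisq
    diag$logrank_p[i] <- lr$p
  }
  sel <- diag[diag$cox_pass & !is.na(diag$logrank_p) &
                diag$logrank_p < cfg$logrank_alpha, , drop = FALSE]
  sel$risk_group <- ifelse(sel$beta_sign > 0, "high-risk", "low-risk")
  sel <- sel[order(sel$mirna, sel$target),
             c("mirna", "target", "mirna_dir", "target_dir",
               "pattern_fraction", "median_beta", "beta_sign", "sig_freq",
               "logrank_chisq", "logrank_p", "risk_group"), drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "diagnostics") <- diag
  attr(sel, "outcome_groups") <- groups
  sel
}
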