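#' Ratio matrix of interactions by patients
#'
#' Row `i` holds the per-patient log2 miRNA:target ratio of interaction `i`
#' (see [expression_ratio()]); rows are named `"<mirna>|<target>"`.
#' Interactions whose miRNA or target is absent from the cohort's matrices
#' are dropped with a warning (the cross-cohort case); if none remain the
#' call errors.
#'
#' @param interactions Data frame with columns `mirna`, `target`.
#' @param mirna_log,gene_log Log2-scale [expr_matrix()] objects (tumor
#'   samples).
#' @return Numeric matrix, interactions x patients.
#' @export
ratio_matrix <- function(interactions, mirna_log, gene_log) {
  if (!setequal(colnames(mirna_log), colnames(gene_log)))
    stop("miRNA and gene matrices cover different samples")
  ml <- unclass(mirna_log)
  gl <- unclass(gene_log)[, colnames(ml), drop = FALSE]
  present <- interactions$mirna %in% rownames(ml) &
    interactions$target %in% rownames(gl)
  if (!any(present)) stop("no interaction has both features in this cohort")
  if (any(!present))
    warning(sprintf("%d of %d interaction(s) missing a feature; dropped",
                    sum(!present), length(present)))
  ia <- interactions[present, , drop = FALSE]
  out <- ml[ia$mirna, , drop = FALSE] - gl[ia$target, , drop = FALSE]
  rownames(out) <- paste(ia$mirna, ia$target, sep = "|")
  out
}

#' Cluster patients on interaction ratios
#'
#' k-means (k = 2 by default) on patient vectors of interaction ratios,
#' Euclidean distance, `n_restarts` seeded initializations keeping the best
#' inertia. Rows (interactions) are standardized beforehand so
#' high-variance interactions do not dominate; disable with
#' `standardize = FALSE`.
#'
#' @param rmat Ratio matrix from [ratio_matrix()] (interactions x patients).
#' @param k Number of clusters.
#' @param n_restarts Random restarts of k-means.
#' @param standardize Z-score each interaction row first?
#' @param seed Seed for the restarts (stage-derived when a full
#'   [mtk_config()] drives the run).
#' @return List of class `patient_clustering`: `cluster` (named labels),
#'   `inertia`, `k`, `n_restarts`, `seed`.
#' @export
cluster_patients <- function(rmat, k = 2L, n_restarts = 25L,
                             standardize = TRUE, seed = 1L) {
  if (ncol(rmat) < k) stop("fewer patients than clusters")
  if (nrow(rmat) < 1) stop("need at least one interaction row")
  x <- rmat
  if (standardize) {
    sds <- apply(x, 1, stats::sd)
    x <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  }
  pts <- t(x)
  if (nrow(unique(pts)) < k)
    stop("degenerate input: fewer than k distinct patient profiles")
  set.seed(seed)
  km <- stats::kmeans(pts, centers = k, nstart = n_restarts, iter.max = 100)
  structure(list(cluster = stats::setNames(km$cluster, colnames(rmat)),
                 inertia = km$tot.withinss, k = k,
                 n_restarts = n_restarts, seed = seed),
            class = "patient_clustering")
}

#' Evaluate a patient clustering against survival
#'
#' Log-rank test between the two clusters, then a multivariable Cox model
#' of survival on cluster membership adjusted for age (continuous) and
#' gender. The poor-prognosis cluster (the one with the worse survival
#' curve) is taken as the risk group, so the reported hazard ratio is for
#' poor vs good and is >= 1 in the unadjusted orientation. Patients with
#' missing age or gender are excluded from the Cox model only.
#'
#' @param clustering A `patient_clustering`.
#' @param clinical A `clinical_table` covering the clustered patients.
#' @return List with `logrank_chisq`, `logrank_p`, `poor_cluster`, `hr`,
#'   `hr_lower`, `hr_upper`, `cox_p`, `n`, `n_cox`.
#' @export
evaluate_signature <- function(clustering, clinical) {
  stopifnot(inherits(clustering, "patient_clustering"))
  rownames(clinical) <- clinical$sample
  s <- intersect(names(clustering$cluster), clinical$sample)
  if (length(s) < 4) stop("too few patients with both cluster and clinical data")
  cl <- clustering$cluster[s]
  if (length(unique(cl)) < 2) stop("only one cluster represented")
  ti <- clinical[s, "time"]; ev <- clinical[s, "event"]
  sdiff <- survival::survdiff(survival::Surv(ti, ev) ~ cl)
  chisq <- unname(sdiff$chisq)
  logrank_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  # Worse-curve cluster: the one with more observed than expected events.
  labs <- sort(unique(cl))
  excess <- sdiff$obs - sdiff$exp
  poor <- labs[which.max(excess)]
  dat <- data.frame(time = ti, event = ev,
                    poor = as.integer(cl == poor),
                    age = clinical[s, "age"],
                    gender = clinical[s, "gender"])
  dat_cox <- dat[stats::complete.cases(dat), ]
  hr <- hr_lo <- hr_up <- cox_p <- NA_real_
  if (sum(dat_cox$event) >= 2 && length(unique(dat_cox$poor)) == 2) {
    fit <- survival::coxph(
      survival::Surv(time, event) ~ poor + age + gender, data = dat_cox)
    sm <- summary(fit)
    hr <- unname(sm$conf.int["poor", "exp(coef)"])
    hr_lo <- unname(sm$conf.int["poor", "lower .95"])
    hr_up <- unname(sm$conf.int["poor", "upper .95"])
    cox_p <- unname(sm$coefficients["poor", "Pr(>|z|)"])
  } else {
    warning("Cox model not fitted (too few events or degenerate cluster)")
  }
  list(logrank_chisq = chisq, logrank_p = logrank_p, poor_cluster = poor,
       hr = hr, hr_lower = hr_lo, hr_upper = hr_up, cox_p = cox_p,
       n = length(s), n_cox = nrow(dat_cox))
}

#' Transfer a signature to another cohort
#'
#' Applies key interactions discovered in cohort A to cohort B: the ratio
#' matrix is restricted to interactions whose features exist in B, patients
#' are clustered, and the clustering is evaluated against B's survival.
#'
#' @param interactions Key-interaction data frame from cohort A.
#' @param mirna_log,gene_log Cohort B log2 expression ([expr_matrix()]),
#'   tumor samples, normalized on the same scale as cohort A.
#' @param clinical Cohort B `clinical_table`.
#' @param seed Clustering seed.
#' @return The [evaluate_signature()] list, plus `n_transferable` and
#'   `fraction_transferable`, and the `clustering` used.
#' @export
cross_cohort_evaluation <- function(interactions, mirna_log, gene_log,
                                    clinical, seed = 1L) {
  rmat <- suppressWarnings(ratio_matrix(interactions, mirna_log, gene_log))
  if (nrow(rmat) < 3)
    stop("fewer than 3 transferable interactions; signature cannot be applied")
  clus <- cluster_patients(rmat, seed = seed)
  out <- evaluate_signature(clus, clinical)
  out$n_transferable <- nrow(rmat)
  out$fraction_transferable <- nrow(rmat) / nrow(interactions)
  out$clustering <- clus
  out
}

#' Compare the key-interaction signature with simpler baselines
#'
#' Clusters patients three ways - (a) ratios of the key interactions,
#' (b) ratios of all dysregulated interactions, (c) expression of the key
#' miRNAs alone - and reports the between-cluster log-rank p of each.
#'
#' @param key_interactions,all_interactions Interaction data frames.
#' @param key_mirnas Character vector of key miRNA IDs.
#' @param mirna_log,gene_log Log2 [expr_matrix()] objects (tumor samples).
#' @param clinical A `clinical_table`.
#' @param seed Clustering seed.
#' @return Data frame `baseline`, `logrank_p`, `neglog10_p`.
#' @export
baseline_comparison <- function(key_interactions, all_interactions,
                                key_mirnas, mirna_log, gene_log, clinical,
                                seed = 1L) {
  mats <- list(
    key_interactions = ratio_matrix(key_interactions, mirna_log, gene_log),
    all_interactions = ratio_matrix(all_interactions, mirna_log, gene_log),
    key_mirnas = unclass(mirna_log)[intersect(key_mirnas,
                                              rownames(mirna_log)), ,
                                    drop = FALSE])
  ps <- vapply(mats, function(m) {
    clus <- cluster_patients(m, seed = seed)
    evaluate_signature(clus, clinical)$logrank_p
  }, numeric(1))
  data.frame(baseline = names(ps), logrank_p = unname(ps),
             neglog10_p = -log10(unname(ps)),
             stringsAsFactors = FALSE, row.names = NULL)
}

check_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != c(2, 2)))
    stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (sum(table) == 0) stop("empty table")
  invisible(table)
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square on one degree of freedom with Yates continuity
#' correction by default (the correction reproduces the published
#' literature-survey p-values of 0.004 and 0.005; without it both are
#' smaller).
#'
#' @param table 2x2 integer matrix.
#' @param continuity Apply the Yates correction?
#' @return List with `statistic`, `p`.
#' @export
chi_square_2x2 <- function(table, continuity = TRUE) {
  check_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total; use fisher_exact_2x2() instead")
  ct <- stats::chisq.test(table, correct = continuity)
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Fisher's exact test of a 2x2 contingency table
#'
#' Two-sided exact p: the sum of hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' one.
#'
#' @param table 2x2 integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  check_2x2(table)
  stats::fisher.test(table)$p.value
}

#' Secondary clinical-outcome tests of a patient clustering
#'
#' Crosses the cluster labels with progression-free survival (log-rank),
#' poor functional status (Karnofsky performance score strictly below 60;
#' Fisher's exact test) and distant metastasis (M0 vs M1; Fisher's exact
#' test). Absent clinical columns are skipped and reported as unavailable.
#'
#' @param clustering A `patient_clustering`.
#' @param clinical A `clinical_table`, optionally with `pfs_time`,
#'   `pfs_event`, `kps`, `m_stage`.
#' @return Data frame `test`, `available`, `p`.
#' @export
secondary_outcome_tests <- function(clustering, clinical) {
  rownames(clinical) <- clinical$sample
  s <- intersect(names(clustering$cluster), clinical$sample)
  cl <- clustering$cluster[s]
  res <- data.frame(test = c("pfs_logrank", "kps_fisher", "m_stage_fisher"),
                    available = FALSE, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (all(c("pfs_time", "pfs_event") %in% names(clinical))) {
    ok <- s[!is.na(clinical[s, "pfs_time"]) & !is.na(clinical[s, "pfs_event"])]
    if (length(unique(cl[ok])) == 2 && sum(clinical[ok, "pfs_event"]) > 0) {
      sd <- survival::survdiff(
        survival::Surv(clinical[ok, "pfs_time"],
                       clinical[ok, "pfs_event"]) ~ cl[ok])
      res$available[1] <- TRUE
      res$p[1] <- stats::pchisq(unname(sd$chisq), 1, lower.tail = FALSE)
    }
  }
  if ("kps" %in% names(clinical)) {
    ok <- s[!is.na(clinical[s, "kps"])]
    low <- factor(clinical[ok, "kps"] < 60, levels = c(FALSE, TRUE))
    tab <- table(factor(cl[ok]), low)
    if (all(dim(tab) == c(2, 2))) {
      res$available[2] <- TRUE
      res$p[2] <- fisher_exact_2x2(matrix(tab, 2, 2))
    }
  }
  if ("m_stage" %in% names(clinical)) {
    ok <- s[clinical[s, "m_stage"] %in% c("M0", "M1")]
    tab <- table(factor(cl[ok]),
                 factor(clinical[ok, "m_stage"], levels = c("M0", "M1")))
    if (all(dim(tab) == c(2, 2))) {
      res$available[3] <- TRUE
      res$p[3] <- fisher_exact_2x2(matrix(tab, 2, 2))
    }
  }
  res
}
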