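#' Filter features by minimum read support
#'
#' Retains features with at least `min_reads` counts in strictly more than
#' `min_fraction` of all samples (tumor and normal pooled). Standard
#' operating points: 10 reads for genes, 2 reads for miRNAs, both in more
#' than 50% of samples.
#'
#' @param counts An [expr_matrix()] of raw counts.
#' @param min_reads Minimum count per sample.
#' @param min_fraction Fraction of samples that must reach `min_reads`;
#'   strict comparison.
#' @return The filtered [expr_matrix()]; a warning (not an error) if no
#'   feature survives.
#' @export
filter_low_expression <- function(counts, min_reads, min_fraction = 0.5) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (value_scale(counts) != "counts")
    stop("filtering applies to raw counts")
  frac <- rowMeans(unclass(counts) >= min_reads)
  keep <- frac > min_fraction
  if (!any(keep)) warning("no feature passes the expression filter")
  rewrap(unclass(counts)[keep, , drop = FALSE], counts)
}

#' Normalize counts to log2 RPKM (genes) or RPM (miRNAs)
#'
#' RPM = count / (library size / 1e6); RPKM additionally divides by the
#' feature length in kilobases. Library size is the column total of the
#' supplied matrix. The result is `log2(value + pseudocount)`.
#'
#' @param counts An [expr_matrix()] of raw counts.
#' @param gene_lengths_kb Named numeric vector of lengths in kb; required
#'   when `feature_kind(counts) == "gene"`, ignored for miRNAs.
#' @param pseudocount Added before the log.
#' @return An [expr_matrix()] on the log2 scale.
#' @export
normalize_counts <- function(counts, gene_lengths_kb = NULL, pseudocount = 1) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (value_scale(counts) != "counts")
    stop("input is already normalized")
  m <- unclass(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("sample(s) with zero total reads: ",
                          paste(colnames(m)[lib <= 0], collapse = ", "))
  x <- sweep(m, 2, lib / 1e6, "/")
  if (feature_kind(counts) == "gene") {
    if (is.null(gene_lengths_kb))
      stop("gene lengths (kb) are required to compute RPKM")
    missing <- setdiff(rownames(m), names(gene_lengths_kb))
    if (length(missing) > 0)
      stop("no length for gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    len <- gene_lengths_kb[rownames(m)]
    if (any(len <= 0)) stop("gene lengths must be positive")
    x <- sweep(x, 1, len, "/")
  }
  expr_matrix(log2(x + pseudocount), feature_kind(counts),
              sample_condition(counts), "log2")
}

# Vectorized Welch two-sample test on rows of two matrices (log scale).
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # Degenerate rows (zero variance in both groups): no evidence either way
  # when the means agree, overwhelming evidence when they differ.
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  tstat[zero & m1 == m2] <- 0
  list(statistic = tstat, df = df, p = p, mean1 = m1, mean2 = m2)
}

#' Two-group differential expression on log-normalized values
#'
#' Welch's unequal-variance t test per feature between tumor and normal
#' samples, Benjamini-Hochberg correction across all tested features, and a
#' direction call: `up` when FDR < `de_fdr` and the linear fold change
#' (larger over smaller mean) exceeds `de_fc` with tumor above normal,
#' `down` symmetrically, otherwise `ns`.
#'
#' @param expr An [expr_matrix()] on the log2 scale containing both
#'   conditions (or supply `normal` separately).
#' @param normal Optional second [expr_matrix()] holding the normal samples
#'   when `expr` holds only tumors.
#' @param cfg An [mtk_config()] providing `de_fdr` and `de_fc`.
#' @return Data frame with columns `feature`, `log2fc`, `p`, `fdr`,
#'   `direction`.
#' @export
differential_expression <- function(expr, normal = NULL, cfg = mtk_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (value_scale(expr) != "log2")
    stop("differential expression expects log-normalized values")
  if (is.null(normal)) {
    tum <- subset_condition(expr, "tumor")
    nor <- subset_condition(expr, "normal")
  } else {
    tum <- expr
    nor <- normal
    if (!setequal(rownames(tum), rownames(nor)))
      stop("tumor and normal matrices cover different features")
    nor <- rewrap(unclass(nor)[rownames(tum), , drop = FALSE], nor)
  }
  if (ncol(nor) < 3)
    stop("fewer than 3 normal samples; differential expression is not ",
         "reliable - supply an external DE result instead")
  if (ncol(tum) < 3) stop("fewer than 3 tumor samples")
  w <- welch_rows(unclass(tum), unclass(nor))
  log2fc <- w$mean1 - w$mean2
  fdr <- stats::p.adjust(w$p, method = "BH")
  fc_linear <- 2^abs(log2fc)
  direction <- rep("ns", nrow(tum))
  sig <- fdr < cfg$de_fdr & fc_linear > cfg$de_fc
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"
  data.frame(feature = rownames(tum), log2fc = log2fc, p = w$p, fdr = fdr,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Dichotomize tumor expression at the per-feature median
#'
#' A tumor sample is `"high"` for a feature when its value is strictly above
#' that feature's median across tumor samples, `"low"` otherwise (values at
#' the median count as low, so `"high"` is strictly above the median).
#'
#' @param expr An [expr_matrix()] on the log2 scale; only tumor samples are
#'   used.
#' @return Character matrix (features x tumor samples) of `"high"`/`"low"`.
#' @export
dichotomize_by_median <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  tum <- unclass(subset_condition(expr, "tumor"))
  med <- apply(tum, 1, stats::median)
  states <- ifelse(tum > med, "high", "low")
  dimnames(states) <- dimnames(tum)
  states
}
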