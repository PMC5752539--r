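#' Expression matrix with sample and feature annotations
#'
#' A thin container around a numeric feature-by-sample matrix that carries
#' the feature kind (`"mirna"` or `"gene"`), the per-sample condition
#' (`"tumor"` or `"normal"`), and the value scale (`"counts"` for raw read
#' counts, `"log2"` for log-normalized abundances). All pipeline stages
#' check these tags rather than guessing what a matrix holds.
#'
#' @param values Numeric matrix, features in rows, samples in columns; both
#'   dimnames must be set and feature IDs unique.
#' @param feature_kind `"mirna"` or `"gene"`.
#' @param condition Character vector of `"tumor"`/`"normal"`, either named by
#'   sample or in column order.
#' @param scale `"counts"` or `"log2"`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, feature_kind = c("mirna", "gene"),
                        condition, scale = c("counts", "log2")) {
  feature_kind <- match.arg(feature_kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have feature and sample names")
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs")
  condition <- stats::setNames(as.character(condition), names(condition))
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(values), names(condition))
    if (length(missing) > 0)
      stop("no condition given for sample(s): ",
           paste(missing, collapse = ", "))
    condition <- condition[colnames(values)]
  } else if (length(condition) != ncol(values)) {
    stop("'condition' must have one entry per sample")
  }
  if (!all(condition %in% c("tumor", "normal")))
    stop("condition values must be 'tumor' or 'normal'")
  names(condition) <- colnames(values)
  structure(values, feature_kind = feature_kind, condition = condition,
            value_scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("expr_matrix: %d %s features x %d samples (%d tumor, %d normal), %s scale\n",
              nrow(x), attr(x, "feature_kind"), ncol(x),
              sum(cond == "tumor"), sum(cond == "normal"),
              attr(x, "value_scale")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
feature_kind <- function(x) attr(x, "feature_kind")

#' @rdname expr_matrix
#' @export
sample_condition <- function(x) attr(x, "condition")

#' @rdname expr_matrix
#' @export
value_scale <- function(x) attr(x, "value_scale")

#' Subset an expression matrix to one condition
#'
#' @param x An `expr_matrix`.
#' @param condition `"tumor"` or `"normal"`.
#' @return An `expr_matrix` containing only the requested samples.
#' @export
subset_condition <- function(x, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  keep <- names(which(sample_condition(x) == condition))
  expr_matrix(unclass(x)[, keep, drop = FALSE], feature_kind(x),
              sample_condition(x)[keep], value_scale(x))
}

# Re-wrap a plain matrix produced by subsetting/arithmetic on an expr_matrix,
# inheriting annotations from the original.
rewrap <- function(values, template) {
  expr_matrix(values, feature_kind(template),
              sample_condition(template)[colnames(values)],
              value_scale(template))
}
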