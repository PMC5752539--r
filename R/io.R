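#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample IDs and feature
#' IDs in the first column. Every body cell must be numeric; duplicated
#' feature IDs are rejected.
#'
#' @param path Path to the TSV file.
#' @param feature_kind `"mirna"` or `"gene"`.
#' @param condition Named character vector mapping sample IDs to
#'   `"tumor"`/`"normal"`; every sample in the file must be covered.
#' @param scale Value scale of the file, `"counts"` or `"log2"`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, feature_kind = c("mirna", "gene"),
                                   condition, scale = c("counts", "log2")) {
  feature_kind <- match.arg(feature_kind)
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a feature column plus samples")
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats))
    stop("duplicated feature ID(s) in ", path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     col[bad[1]], feats[bad[1]], names(body)[j]))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- feats
  expr_matrix(m, feature_kind, condition, scale)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expr_matrix()] (or plain named matrix).
#' @param path Output path.
#' @param feature_col Name of the first (feature ID) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, feature_col = "feature") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample`, `time`, `event`, `age`, `gender`; optional
#' columns `pfs_time`, `pfs_event`, `kps`, `m_stage` are kept when present.
#' Times must be non-negative, events coded 0/1, gender `male`/`female`.
#' Missing values in the optional columns are preserved as `NA`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_clinical_table(df)
}

#' Validate a clinical data frame
#'
#' @param df A data frame with the columns documented in
#'   [read_clinical_table()].
#' @return The validated data frame, classed `clinical_table`.
#' @export
as_clinical_table <- function(df) {
  required <- c("sample", "time", "event", "age", "gender")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicated sample IDs in clinical table")
  if (any(is.na(df$time)) || any(df$time < 0))
    stop("survival times must be non-negative and non-missing")
  if (!all(df$event %in% c(0, 1)))
    stop("unknown event code(s): ",
         paste(unique(df$event[!df$event %in% c(0, 1)]), collapse = ", "))
  ok_gender <- is.na(df$gender) | df$gender %in% c("male", "female")
  if (!all(ok_gender))
    stop("gender must be 'male', 'female', or missing")
  if ("pfs_event" %in% names(df) &&
      !all(is.na(df$pfs_event) | df$pfs_event %in% c(0, 1)))
    stop("unknown pfs_event code")
  if ("pfs_time" %in% names(df) && any(df$pfs_time < 0, na.rm = TRUE))
    stop("pfs_time must be non-negative")
  df$sample <- as.character(df$sample)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table to TSV
#'
#' @param clinical A `clinical_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members. Duplicate
#' members within a set are dropped with a warning; a line with fewer than
#' three fields or an empty member list is an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("GMT line %d defines an empty set", i))
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members removed", fields[1]))
      members <- unique(members)
    }
    if (fields[1] %in% names(sets))
      stop("duplicated set name: ", fields[1])
    sets[[fields[1]]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network edge list
#'
#' Accepts a two-column TSV of endpoints, or the three-column SIF dialect
#' (endpoints in columns 1 and 3, interaction type ignored; SIF lines may be
#' space- instead of tab-separated). Self-loops are dropped with a warning
#' and duplicate edges collapsed.
#'
#' @param path Path to the edge-list file.
#' @param directed Build a directed graph?
#' @param header Does the file start with a header line?
#' @return An `igraph` graph whose node set is the union of all endpoints.
#' @export
read_edge_list <- function(path, directed = FALSE, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) > 0) lines <- lines[-1]
  if (length(lines) == 0) stop("empty edge list: ", path)
  ends <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) == 1) fields <- strsplit(trimws(lines[i]), "[ ]+")[[1]]
    if (length(fields) < 2)
      stop(sprintf("edge-list line %d has fewer than 2 columns", i))
    if (length(fields) >= 3) fields[c(1, 3)] else fields[1:2]
  })
  em <- do.call(rbind, ends)
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    em <- em[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(em, directed = directed)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a two-column edge list
#'
#' @param network An `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  em <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(em, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Each table is written as `<name>.tsv` with its column order preserved,
#' alongside `manifest.yaml` recording the configuration (including the
#' seed) and package/R versions, so a run can be reproduced exactly.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param config Optional [mtk_config()] recorded in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list")
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "mirtarkey",
    package_version = as.character(utils::packageVersion("mirtarkey")),
    r_version = as.character(getRversion()),
    config = if (is.null(config)) NULL else unclass(config),
    tables = names(tables)
  )
  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(c(paths, mp))
}
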