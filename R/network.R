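#' Build the bipartite key miRNA-target network
#'
#' One directed edge per unique interaction, miRNA node to target node.
#' Vertex attribute `kind` marks `"mirna"` vs `"gene"` nodes.
#'
#' @param interactions Data frame with columns `mirna`, `target`.
#' @return A directed `igraph` graph.
#' @export
build_network <- function(interactions) {
  if (nrow(interactions) == 0) stop("no interactions to build a network from")
  edges <- unique(interactions[, c("mirna", "target")])
  overlap <- intersect(edges$mirna, edges$target)
  if (length(overlap) > 0)
    stop("ID(s) appear as both miRNA and target: ",
         paste(overlap, collapse = ", "))
  verts <- data.frame(
    name = c(unique(edges$mirna), unique(edges$target)),
    kind = rep(c("mirna", "gene"),
               c(length(unique(edges$mirna)), length(unique(edges$target)))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Power-law fit of the degree distribution
#'
#' Ordinary least squares of log10 N(k) on log10 k over all degrees k >= 1
#' with a positive count — the straight-line-on-log-log characterization of
#' scale-free structure. Requires at least 3 distinct observed degrees.
#'
#' @param network An `igraph` graph.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (two-sided test
#'   of zero slope) and the underlying `degree`/`count` vectors.
#' @export
degree_powerlaw_fit <- function(network) {
  d <- igraph::degree(network, mode = "all")
  tab <- table(d[d >= 1])
  k <- as.numeric(names(tab))
  nk <- as.numeric(tab)
  if (length(k) < 3)
    stop("fewer than 3 distinct degree values; power-law fit undefined")
  fit <- stats::lm(log10(nk) ~ log10(k))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       degree = k, count = nk)
}

#' Identify hub miRNAs
#'
#' Hubs are miRNA nodes ranking in the top `hub_top_fraction` of all nodes
#' by degree (ties at the cutoff degree are all included) that regulate at
#' least `hub_min_targets` target genes.
#'
#' @param network Bipartite network from [build_network()].
#' @param cfg An [mtk_config()].
#' @return Data frame `mirna`, `degree`, sorted by decreasing degree.
#' @export
find_hubs <- function(network, cfg = mtk_config()) {
  d <- igraph::degree(network, mode = "all")
  n_top <- max(1L, ceiling(cfg$hub_top_fraction * length(d)))
  cutoff <- sort(d, decreasing = TRUE)[n_top]
  top_nodes <- names(d)[d >= cutoff]
  kind <- igraph::vertex_attr(network, "kind")
  names(kind) <- igraph::V(network)$name
  targets <- igraph::degree(network, mode = "out")
  hubs <- top_nodes[kind[top_nodes] == "mirna" &
                      targets[top_nodes] >= cfg$hub_min_targets]
  out <- data.frame(mirna = hubs, degree = unname(d[hubs]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
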