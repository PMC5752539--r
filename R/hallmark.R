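#' Random walk with restart over a network
#'
#' Iterates `p <- (1 - r) * W %*% p + r * p0` with `W` the column-normalized
#' adjacency matrix and `p0` uniform over the seed nodes, until the L1
#' change falls below `tol`. The steady state measures each node's
#' proximity to the seed set; nodes in components containing no seed end at
#' probability zero. Zero-degree nodes are given a self-loop in `W` so the
#' walk conserves probability mass.
#'
#' @param network An `igraph` graph with named vertices (treated as
#'   undirected).
#' @param seeds Character vector of seed node names; at least one must be in
#'   the network.
#' @param restart Restart probability r.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Named numeric vector of steady-state probabilities (sums to 1).
#' @export
rwr <- function(network, seeds, restart = 0.7, tol = 1e-10,
                max_iter = 10000L) {
  if (restart <= 0 || restart > 1) stop("'restart' must be in (0, 1]")
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) stop("network vertices must be named")
  seeds <- unique(seeds)
  present <- intersect(seeds, nodes)
  if (length(present) == 0)
    stop("no seed present in the network; missing: ",
         paste(utils::head(seeds, 10), collapse = ", "))
  A <- igraph::as_adjacency_matrix(igraph::as_undirected(network),
                                   sparse = FALSE)
  deg <- colSums(A)
  if (any(deg == 0)) {
    iso <- which(deg == 0)
    A[cbind(iso, iso)] <- 1
    deg[iso] <- 1
  }
  W <- sweep(A, 2, deg, "/")
  p0 <- stats::setNames(rep(0, length(nodes)), nodes)
  p0[present] <- 1 / length(present)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- (1 - restart) * drop(W %*% p) + restart * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  names(p) <- nodes
  p
}

#' Hallmark impact scores from a propagation profile
#'
#' A hallmark's score is the median steady-state probability over the
#' distinct genes in the union of its associated pathways that are present
#' in the network; genes outside the network are excluded, and a hallmark
#' with no network-resident gene gets `NA` with a warning.
#'
#' @param prob Named probability vector from [rwr()].
#' @param gene_sets Named list of pathway gene sets.
#' @param hallmark_map Data frame `hallmark`, `pathway`.
#' @return Named numeric vector of per-hallmark scores.
#' @export
hallmark_score <- function(prob, gene_sets, hallmark_map) {
  unknown <- setdiff(hallmark_map$pathway, names(gene_sets))
  if (length(unknown) > 0)
    stop("hallmark map names unknown pathway(s): ",
         paste(unknown, collapse = ", "))
  hallmarks <- unique(hallmark_map$hallmark)
  vapply(hallmarks, function(h) {
    sets <- hallmark_map$pathway[hallmark_map$hallmark == h]
    genes <- intersect(unique(unlist(gene_sets[sets])), names(prob))
    if (length(genes) == 0) {
      warning("hallmark '", h, "' has no gene in the network")
      return(NA_real_)
    }
    stats::median(prob[genes])
  }, numeric(1))
}

#' Degree-preserving network rewiring
#'
#' Randomizes the edge set by double-edge swaps that keep every node's
#' degree exactly, attempting `swap_factor` times the edge count so each
#' edge is expected to be rewired several times. Graphs admitting no valid
#' swap (e.g. a triangle) are returned unchanged with a warning.
#'
#' @param network An `igraph` graph; uses the current RNG state.
#' @param swap_factor Attempted swaps per edge.
#' @return A rewired `igraph` graph with the same degree sequence.
#' @export
rewire_network <- function(network, swap_factor = 10L) {
  ne <- igraph::ecount(network)
  if (ne < 2) stop("need at least 2 edges to rewire")
  out <- igraph::rewire(
    network,
    igraph::keeping_degseq(loops = FALSE, niter = swap_factor * ne))
  same <- igraph::ecount(igraph::intersection(network, out)) == ne
  if (same)
    warning("rewiring left the edge set unchanged (no valid swap?)")
  out
}

#' Permutation test of hallmark impact scores
#'
#' Propagates from the seed genes over the observed network, then over
#' `cfg$n_permutations` degree-preserving rewirings, and reports for each
#' hallmark the empirical p-value: the fraction of permutations whose score
#' is greater than or equal to the observed one. By default the observed
#' network counts as one permutation (add-one estimator), so p is never
#' exactly zero; `include_observed = FALSE` gives the plain fraction.
#'
#' @param network The PPI network.
#' @param seeds Seed gene names (key miRNA targets).
#' @param gene_sets Named list of pathway gene sets.
#' @param hallmark_map Data frame `hallmark`, `pathway`.
#' @param cfg An [mtk_config()] (restart probability, permutation count,
#'   seed).
#' @param include_observed Count the observed network in the numerator and
#'   denominator?
#' @return Data frame `hallmark`, `score`, `p`, `n_permutations`,
#'   `significant` (at 0.05).
#' @export
hallmark_permutation_test <- function(network, seeds, gene_sets,
                                      hallmark_map, cfg = mtk_config(),
                                      include_observed = TRUE) {
  obs_prob <- rwr(network, seeds, restart = cfg$restart_prob)
  obs <- hallmark_score(obs_prob, gene_sets, hallmark_map)
  n_perm <- cfg$n_permutations
  ge <- stats::setNames(rep(0L, length(obs)), names(obs))
  set.seed(stage_seed(cfg$seed, "permutation"))
  for (b in seq_len(n_perm)) {
    g_perm <- rewire_network(network)
    p_perm <- rwr(g_perm, seeds, restart = cfg$restart_prob)
    sc <- hallmark_score(p_perm, gene_sets, hallmark_map)
    ge <- ge + as.integer(!is.na(sc) & !is.na(obs) & sc >= obs)
  }
  p <- if (include_observed) (1 + ge) / (n_perm + 1) else ge / n_perm
  data.frame(hallmark = names(obs), score = unname(obs), p = unname(p),
             n_permutations = n_perm, significant = unname(p) < 0.05,
             stringsAsFactors = FALSE, row.names = NULL)
}
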