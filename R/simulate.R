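#' Simulation configuration
#'
#' Parameters of the synthetic TCGA-like cohort generator. Defaults describe
#' a mid-sized cohort: 200 tumors with 40 matched normals, 2,000 genes and
#' 100 miRNAs with negative-binomial counts, 30 planted negative
#' miRNA-to-target regulations of which 10 carry prognostic signal through a
#' proportional-hazards model on the miRNA:target log ratio, a 1,000-node
#' preferential-attachment protein network, and 50 pathway gene sets.
#'
#' @param n_tumor,n_normal Sample counts per condition.
#' @param n_genes,n_mirnas Feature counts.
#' @param n_planted_regulations Number of planted miRNA-target regulations
#'   (each uses a distinct miRNA and target gene).
#' @param n_planted_prognostic Number of planted regulations whose ratio
#'   drives the hazard; must not exceed `n_planted_regulations`.
#' @param regulation_strength Multiplicative suppression of the target's
#'   negative-binomial mean per unit of the regulator miRNA's standardized
#'   log-expression; in (0, 1], with 1 meaning no regulation.
#' @param mirna_fold_change Tumor/normal fold change planted on regulator
#'   miRNAs (applied as x or 1/x according to the pair's direction).
#' @param cox_beta True log-hazard coefficient on the standardized aggregate
#'   ratio risk score.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_hazard Baseline event hazard per day.
#' @param censoring_horizon_days Upper bound of the uniform censoring time.
#' @param ppi_n_nodes,ppi_edges_per_node Size and density of the simulated
#'   protein-protein interaction network.
#' @param n_pathways Number of simulated pathway gene sets.
#' @param pathway_size_min,pathway_size_max Pathway size range.
#' @param n_decoy_mirnas Non-planted miRNAs added to the disease list.
#' @param decoy_pairs_per_mirna Decoy predicted targets per disease miRNA.
#' @param seed Seed of the generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 200L, n_normal = 40L,
                       n_genes = 2000L, n_mirnas = 100L,
                       n_planted_regulations = 30L,
                       n_planted_prognostic = 10L,
                       regulation_strength = 0.5,
                       mirna_fold_change = 2.0,
                       cox_beta = 0.8,
                       nb_dispersion = 0.2,
                       baseline_hazard = 0.01,
                       censoring_horizon_days = 2000,
                       ppi_n_nodes = 1000L, ppi_edges_per_node = 3L,
                       n_pathways = 50L,
                       pathway_size_min = 15L, pathway_size_max = 80L,
                       n_decoy_mirnas = 30L, decoy_pairs_per_mirna = 20L,
                       seed = 1L) {
  cfg <- as.list(environment())
  ints <- c("n_tumor", "n_normal", "n_genes", "n_mirnas",
            "n_planted_regulations", "n_planted_prognostic",
            "ppi_n_nodes", "ppi_edges_per_node", "n_pathways",
            "pathway_size_min", "pathway_size_max",
            "n_decoy_mirnas", "decoy_pairs_per_mirna")
  for (p in ints) {
    cfg[[p]] <- as.integer(cfg[[p]])
    if (is.na(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("'%s' must be a non-negative integer", p))
  }
  if (cfg$n_planted_prognostic > cfg$n_planted_regulations)
    stop("planted prognostic pairs must be a subset of planted regulations")
  if (cfg$n_planted_regulations > min(cfg$n_mirnas, cfg$n_genes))
    stop("more planted regulations than available distinct miRNAs/genes")
  if (cfg$regulation_strength <= 0 || cfg$regulation_strength > 1)
    stop("'regulation_strength' must be in (0, 1]")
  if (cfg$nb_dispersion <= 0) stop("'nb_dispersion' must be positive")
  if (cfg$baseline_hazard <= 0) stop("'baseline_hazard' must be positive")
  if (cfg$censoring_horizon_days <= 0)
    stop("'censoring_horizon_days' must be positive")
  if (cfg$ppi_edges_per_node >= cfg$ppi_n_nodes)
    stop("'ppi_edges_per_node' must be smaller than 'ppi_n_nodes'")
  if (cfg$pathway_size_min > cfg$pathway_size_max)
    stop("infeasible pathway size range")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

mirna_ids <- function(n) sprintf("miR-%03d", seq_len(n))
gene_ids <- function(n) sprintf("gene%04d", seq_len(n))

#' Simulate paired miRNA/mRNA count matrices with planted regulations
#'
#' Counts are negative-binomial around feature-specific baseline means.
#' Planted regulator miRNAs get a tumor/normal fold change (up or down per
#' the pair's direction), and each planted target's mean in every sample is
#' scaled by `regulation_strength^z`, where `z` is the regulator's
#' standardized log2 expression in that sample. Because the regulation acts
#' on the mean, the count noise model is untouched; it yields both the
#' tumor-vs-normal direction reversal and the within-tumor anticorrelation
#' that the screening criteria look for. Non-planted features have equal
#' tumor and normal means.
#'
#' Uses the current RNG state; seed upstream (see [simulate_cohort()]).
#'
#' @param cfg A [sim_config()].
#' @return List with elements `mirna_counts` and `mrna_counts`
#'   ([expr_matrix()] of raw counts) and `truth` (data frame of planted
#'   pairs: `mirna`, `target`, `direction`, `is_regulation`, `is_prognostic`,
#'   `true_beta_sign`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_s <- cfg$n_tumor + cfg$n_normal
  samples <- sprintf("S%04d", seq_len(n_s))
  condition <- stats::setNames(
    rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)), samples)
  mir <- mirna_ids(cfg$n_mirnas)
  gen <- gene_ids(cfg$n_genes)
  size <- 1 / cfg$nb_dispersion

  planted_mir <- sample(mir, cfg$n_planted_regulations)
  planted_gen <- sample(gen, cfg$n_planted_regulations)
  direction <- sample(c("up", "down"), cfg$n_planted_regulations,
                      replace = TRUE)
  prognostic <- seq_len(cfg$n_planted_regulations) <= cfg$n_planted_prognostic

  # Baseline means: log-normal across features; planted features are drawn
  # from a well-expressed stratum (disease-associated miRNAs and their
  # targets are rarely at the detection floor) so they survive read filters.
  base_mir <- stats::setNames(exp(stats::rnorm(cfg$n_mirnas, log(100), 1.2)), mir)
  base_mir[planted_mir] <- exp(stats::rnorm(cfg$n_planted_regulations,
                                            log(300), 0.5))
  base_gen <- stats::setNames(exp(stats::rnorm(cfg$n_genes, log(150), 1.2)), gen)
  base_gen[planted_gen] <- exp(stats::rnorm(cfg$n_planted_regulations,
                                            log(300), 0.5))

  mu_mir <- matrix(base_mir, cfg$n_mirnas, n_s,
                   dimnames = list(mir, samples))
  tum <- condition == "tumor"
  for (i in seq_along(planted_mir)) {
    fc <- if (direction[i] == "up") cfg$mirna_fold_change
          else 1 / cfg$mirna_fold_change
    mu_mir[planted_mir[i], tum] <- base_mir[planted_mir[i]] * fc
  }
  mirna_counts <- matrix(stats::rnbinom(length(mu_mir), mu = mu_mir,
                                        size = size),
                         nrow(mu_mir), ncol(mu_mir), dimnames = dimnames(mu_mir))

  mu_gen <- matrix(base_gen, cfg$n_genes, n_s, dimnames = list(gen, samples))
  for (i in seq_along(planted_gen)) {
    z <- as.numeric(scale(log2(mirna_counts[planted_mir[i], ] + 1)))
    if (anyNA(z)) z <- rep(0, n_s)  # constant regulator (degenerate)
    mu_gen[planted_gen[i], ] <- base_gen[planted_gen[i]] *
      cfg$regulation_strength^z
  }
  mrna_counts <- matrix(stats::rnbinom(length(mu_gen), mu = mu_gen,
                                       size = size),
                        nrow(mu_gen), ncol(mu_gen), dimnames = dimnames(mu_gen))

  truth <- data.frame(
    mirna = planted_mir, target = planted_gen, direction = direction,
    is_regulation = TRUE, is_prognostic = prognostic,
    true_beta_sign = ifelse(direction == "up", 1L, -1L),
    stringsAsFactors = FALSE)

  list(
    mirna_counts = expr_matrix(mirna_counts, "mirna", condition, "counts"),
    mrna_counts = expr_matrix(mrna_counts, "gene", condition, "counts"),
    truth = truth
  )
}

#' Simulate survival outcomes from prognostic expression ratios
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(cox_beta * risk)`, where `risk` is the
#' standardized mean of the per-pair standardized, direction-oriented log
#' ratios: each prognostic pair contributes equally to the risk score, and
#' ratios of down-regulated miRNAs enter with a negative sign, so their
#' pairs carry a negative true Cox coefficient. Censoring times are uniform on
#' (0, `censoring_horizon_days`); the observed time is the minimum and the
#' event indicator marks death before censoring. Age (uniform 40-80) and
#' gender (balanced) are independent of the hazard, as are the optional
#' secondary fields (PFS, KPS, M stage).
#'
#' @param cfg A [sim_config()].
#' @param ratios Matrix of per-pair log2 miRNA:target ratios
#'   (pairs x tumor samples), already oriented, or a vector for one pair.
#'   All-zero (null) input yields a unit-hazard cohort.
#' @param secondary Also simulate `pfs_time`/`pfs_event`, `kps`, `m_stage`?
#' @return A `clinical_table` with one row per tumor sample.
#' @export
simulate_survival <- function(cfg, ratios, secondary = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.vector(ratios)) ratios <- matrix(ratios, nrow = 1,
                                          dimnames = list(NULL, names(ratios)))
  if (ncol(ratios) != cfg$n_tumor)
    stop(sprintf("ratio vectors have %d samples; expected n_tumor = %d",
                 ncol(ratios), cfg$n_tumor))
  sds <- apply(ratios, 1, stats::sd)
  rstd <- (ratios - rowMeans(ratios)) / ifelse(sds > 0, sds, 1)
  agg <- colMeans(rstd)
  risk <- if (stats::sd(agg) > 0) as.numeric(scale(agg)) else rep(0, length(agg))
  n <- cfg$n_tumor
  hazard <- cfg$baseline_hazard * exp(cfg$cox_beta * risk)
  event_time <- stats::rexp(n, rate = hazard)
  censor_time <- stats::runif(n, 0, cfg$censoring_horizon_days)
  time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)
  cl <- data.frame(
    sample = colnames(ratios),
    time = time, event = event,
    age = stats::runif(n, 40, 80),
    gender = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (secondary) {
    pfs_event_time <- event_time * stats::runif(n, 0.5, 1)
    cl$pfs_time <- pmin(pfs_event_time, censor_time)
    cl$pfs_event <- as.integer(pfs_event_time <= censor_time)
    cl$kps <- sample(seq(40, 100, by = 10), n, replace = TRUE,
                     prob = c(1, 1, 2, 3, 4, 5, 5))
    cl$m_stage <- sample(c("M0", "M1"), n, replace = TRUE, prob = c(0.8, 0.2))
  }
  as_clinical_table(cl)
}

#' Simulate a scale-free protein-protein interaction network
#'
#' Preferential attachment (Barabasi-Albert) with `ppi_edges_per_node` edges
#' per incoming node, yielding a connected, heavy-tailed graph. Node names
#' are drawn from the simulated gene universe with all planted target genes
#' guaranteed present and assigned to random positions, so the seed set of
#' downstream propagation always exists in the network.
#'
#' @param cfg A [sim_config()].
#' @param gene_universe Character vector of gene IDs to draw node names from.
#' @param required_genes Genes that must appear as nodes (planted targets).
#' @return An undirected `igraph` graph with named vertices.
#' @export
simulate_ppi_network <- function(cfg, gene_universe = gene_ids(cfg$n_genes),
                                 required_genes = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$ppi_n_nodes
  if (length(gene_universe) < n)
    stop("gene universe smaller than requested network size")
  if (!all(required_genes %in% gene_universe))
    stop("required genes outside the gene universe")
  g <- igraph::sample_pa(n, power = 1, m = cfg$ppi_edges_per_node,
                         directed = FALSE)
  others <- sample(setdiff(gene_universe, required_genes),
                   n - length(required_genes))
  igraph::V(g)$name <- sample(c(required_genes, others))
  g
}

#' Simulate pathway gene sets and a hallmark mapping
#'
#' Generates `n_pathways` gene sets over the network's node universe. Two
#' hallmarks are defined: `"tissue_invasion_and_metastasis"`, whose pathways
#' draw 70% of their members from the first-order network neighborhood of
#' the planted target genes (an enriched hallmark the propagation test
#' should flag; the fraction keeps enriched pathways at least three times
#' denser in seed neighbors than the background rate), and
#' `"neutral_process"`, whose pathways are uniform draws (a null hallmark).
#' Remaining pathways are unmapped background.
#'
#' @param cfg A [sim_config()].
#' @param network The simulated PPI network.
#' @param truth Planted-truth data frame from [simulate_expression()].
#' @param pathways_per_hallmark Pathways assigned to each hallmark.
#' @return List with `gene_sets` (named list) and `hallmark_map`
#'   (data frame `hallmark`, `pathway`).
#' @export
simulate_pathways <- function(cfg, network, truth,
                              pathways_per_hallmark = 5L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (2 * pathways_per_hallmark > cfg$n_pathways)
    stop("not enough pathways for two hallmarks")
  pool <- igraph::V(network)$name
  if (cfg$pathway_size_max > length(pool))
    stop("infeasible pathway size range for this network")
  seeds_in <- intersect(truth$target, pool)
  neigh <- if (length(seeds_in) > 0) {
    idx <- unique(unlist(igraph::adjacent_vertices(network, seeds_in)))
    unique(c(seeds_in, igraph::V(network)$name[idx]))
  } else character(0)
  neigh <- intersect(neigh, pool)

  sizes <- sample(seq(cfg$pathway_size_min, cfg$pathway_size_max),
                  cfg$n_pathways, replace = TRUE)
  pnames <- sprintf("pathway_%02d", seq_len(cfg$n_pathways))
  enriched_idx <- seq_len(pathways_per_hallmark)
  neutral_idx <- pathways_per_hallmark + seq_len(pathways_per_hallmark)
  gene_sets <- vector("list", cfg$n_pathways)
  names(gene_sets) <- pnames
  for (i in seq_len(cfg$n_pathways)) {
    s <- sizes[i]
    if (i %in% enriched_idx && length(neigh) > 0) {
      k <- min(ceiling(0.7 * s), length(neigh))
      members <- c(sample(neigh, k), sample(setdiff(pool, neigh), s - k))
    } else {
      members <- sample(pool, s)
    }
    gene_sets[[i]] <- unique(members)
  }
  hallmark_map <- data.frame(
    hallmark = rep(c("tissue_invasion_and_metastasis", "neutral_process"),
                   each = pathways_per_hallmark),
    pathway = pnames[c(enriched_idx, neutral_idx)],
    stringsAsFactors = FALSE)
  list(gene_sets = gene_sets, hallmark_map = hallmark_map)
}

#' Simulate disease-miRNA and predicted-pair candidate lists
#'
#' Stand-ins for curated disease-association and target-prediction inputs:
#' the disease list contains every planted regulator miRNA plus random
#' decoys, and the predicted-pair list contains every planted regulation
#' plus `decoy_pairs_per_mirna` random decoy targets per disease miRNA.
#'
#' @param cfg A [sim_config()].
#' @param truth Planted-truth data frame.
#' @param mirna_universe,gene_universe Feature ID pools.
#' @return List with `disease_mirnas` (character) and `predicted_pairs`
#'   (data frame `mirna`, `target`, `is_planted`).
#' @export
simulate_candidate_lists <- function(cfg, truth,
                                     mirna_universe = mirna_ids(cfg$n_mirnas),
                                     gene_universe = gene_ids(cfg$n_genes)) {
  stopifnot(inherits(cfg, "sim_config"))
  decoy_pool <- setdiff(mirna_universe, truth$mirna)
  n_dec <- min(cfg$n_decoy_mirnas, length(decoy_pool))
  disease <- sort(c(truth$mirna, sample(decoy_pool, n_dec)))
  pairs <- data.frame(mirna = truth$mirna, target = truth$target,
                      is_planted = TRUE, stringsAsFactors = FALSE)
  for (m in disease) {
    planted_t <- truth$target[truth$mirna == m]
    decs <- sample(setdiff(gene_universe, planted_t),
                   cfg$decoy_pairs_per_mirna)
    pairs <- rbind(pairs, data.frame(mirna = m, target = decs,
                                     is_planted = FALSE,
                                     stringsAsFactors = FALSE))
  }
  pairs <- pairs[!duplicated(pairs[c("mirna", "target")]), ]
  rownames(pairs) <- NULL
  list(disease_mirnas = disease, predicted_pairs = pairs)
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator with seeds derived deterministically from
#' `cfg$seed`: expression with planted regulations, survival driven by the
#' planted prognostic ratios, a PPI network containing all planted targets,
#' pathway sets with an enriched and a neutral hallmark, and candidate
#' lists. Gene lengths are fixed at 1 kb so RPKM and RPM arithmetic
#' coincide.
#'
#' @param cfg A [sim_config()].
#' @return List with all pipeline inputs: `mirna_counts`, `mrna_counts`,
#'   `gene_lengths`, `clinical`, `ppi`, `gene_sets`, `hallmark_map`,
#'   `disease_mirnas`, `predicted_pairs`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "expression"))
  ex <- simulate_expression(cfg)
  lengths_kb <- stats::setNames(rep(1, cfg$n_genes), gene_ids(cfg$n_genes))

  # Ratios of the planted prognostic pairs on the normalized log scale,
  # oriented by regulation direction (see simulate_survival).
  mir_log <- normalize_counts(subset_condition(ex$mirna_counts, "tumor"))
  gen_log <- normalize_counts(subset_condition(ex$mrna_counts, "tumor"),
                              gene_lengths_kb = lengths_kb)
  prog <- ex$truth[ex$truth$is_prognostic, ]
  ratios <- t(vapply(seq_len(nrow(prog)), function(i) {
    prog$true_beta_sign[i] *
      expression_ratio(unclass(mir_log)[prog$mirna[i], ],
                       unclass(gen_log)[prog$target[i], ])
  }, numeric(ncol(mir_log))))
  colnames(ratios) <- colnames(mir_log)

  set.seed(stage_seed(cfg$seed, "survival"))
  clinical <- simulate_survival(cfg, ratios)
  set.seed(stage_seed(cfg$seed, "network"))
  ppi <- simulate_ppi_network(cfg, required_genes = ex$truth$target)
  set.seed(stage_seed(cfg$seed, "pathways"))
  pw <- simulate_pathways(cfg, ppi, ex$truth)
  set.seed(stage_seed(cfg$seed, "candidates"))
  cand <- simulate_candidate_lists(cfg, ex$truth)

  list(mirna_counts = ex$mirna_counts, mrna_counts = ex$mrna_counts,
       gene_lengths = lengths_kb, clinical = clinical, ppi = ppi,
       gene_sets = pw$gene_sets, hallmark_map = pw$hallmark_map,
       disease_mirnas = cand$disease_mirnas,
       predicted_pairs = cand$predicted_pairs, truth = ex$truth)
}
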