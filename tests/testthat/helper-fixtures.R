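# Shared fixtures for the test suite: small, fast synthetic objects built in
# code. Unit tests use reduced cohort sizes; only the acceptance tests run
# the generator at its default operating point.

small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_tumor = 120L, n_normal = 30L, n_genes = 400L,
               n_mirnas = 40L, n_planted_regulations = 12L,
               n_planted_prognostic = 6L, ppi_n_nodes = 200L,
               n_pathways = 20L, pathway_size_min = 10L,
               pathway_size_max = 30L, n_decoy_mirnas = 10L,
               decoy_pairs_per_mirna = 5L, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, ...) {
    key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_cohort(small_sim_config(seed = seed, ...))
    cache[[key]]
  }
})

# A deterministic toy expression matrix.
toy_expr <- function(values, kind = "mirna", scale = "counts",
                     n_tumor = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(n_tumor)) n_tumor <- ncol(m)
  cond <- rep(c("tumor", "normal"), c(n_tumor, ncol(m) - n_tumor))
  expr_matrix(m, kind, cond, scale)
}

# A small clinical table with exponential survival, all fields valid.
toy_clinical <- function(n = 40, seed = 7, event_prob = 0.9) {
  set.seed(seed)
  as_clinical_table(data.frame(
    sample = sprintf("s%d", seq_len(n)),
    time = round(rexp(n, 0.01), 2),
    event = rbinom(n, 1, event_prob),
    age = runif(n, 40, 80),
    gender = sample(c("male", "female"), n, TRUE),
    stringsAsFactors = FALSE))
}

# Brute-force oracles, written independently of the implementation paths.

# Cox partial log-likelihood with Efron ties, evaluated directly from the
# definition; maximized with optimize() over a bracket.
oracle_cox_beta <- function(x, time, event) {
  ll <- function(beta) {
    total <- 0
    for (t in unique(time[event == 1])) {
      D <- which(time == t & event == 1)
      R <- which(time >= t)
      d <- length(D)
      wD <- exp(beta * x[D])
      wR <- exp(beta * x[R])
      total <- total + sum(beta * x[D])
      for (l in seq_len(d) - 1)
        total <- total - log(sum(wR) - (l / d) * sum(wD))
    }
    total
  }
  stats::optimize(ll, c(-20, 20), maximum = TRUE, tol = 1e-10)$maximum
}

# Two-group log-rank statistic from the textbook O-E / V formula.
oracle_logrank <- function(time, event, group) {
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Kaplan-Meier median CI by direct inversion of the log-log Greenwood band.
oracle_km_median_ci <- function(time, event, conf = 0.95) {
  ts <- sort(unique(time[event == 1]))
  s <- 1; gw <- 0
  surv <- lower <- upper <- numeric(length(ts))
  z <- qnorm(1 - (1 - conf) / 2)
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    if (n > d) gw <- gw + d / (n * (n - d))
    surv[i] <- s
    if (s > 0 && s < 1) {
      # CI on the log(-log S) scale
      se <- sqrt(gw) / abs(log(s))
      lower[i] <- s^exp(z * se)
      upper[i] <- s^exp(-z * se)
    } else {
      lower[i] <- upper[i] <- NA
    }
  }
  first_below <- function(v) {
    i <- which(!is.na(v) & v <= 0.5)
    if (length(i) == 0) NA_real_ else ts[min(i)]
  }
  # A time is a plausible median while the band still contains 0.5, so the
  # CI runs from where the lower band first reaches 0.5 to where the upper
  # band does.
  list(median = first_below(surv),
       lower = first_below(lower),
       upper = first_below(upper))
}

# Two-sided Fisher exact p by full enumeration over tables with the
# observed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# BH adjustment from the step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
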