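sig_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- small_cohort()
      res <- run_pipeline(cohort, mtk_config(n_resamples = 50L, seed = 1L))
      cache <<- list(cohort = cohort, res = res)
    }
    cache
  }
})

test_that("ratio matrix rows follow the interactions and drop missing features", {
  fx <- sig_fixture()
  dys <- fx$res$dysregulated
  rmat <- ratio_matrix(dys, fx$res$mirna_log, fx$res$gene_log)
  expect_equal(nrow(rmat), nrow(dys))
  expect_equal(rownames(rmat), paste(dys$mirna, dys$target, sep = "|"))
  i <- 1
  manual <- unclass(fx$res$mirna_log)[dys$mirna[i], ] -
    unclass(fx$res$gene_log)[dys$target[i], ]
  expect_equal(rmat[1, ], manual)

  with_missing <- rbind(dys, data.frame(
    mirna = "miR-absent", target = "gene-absent",
    mirna_dir = "up", target_dir = "down", pattern_fraction = 0.5))
  expect_warning(r2 <- ratio_matrix(with_missing, fx$res$mirna_log,
                                    fx$res$gene_log), "dropped")
  expect_equal(nrow(r2), nrow(dys))
  none <- dys[1, ]; none$mirna <- "nope"
  expect_error(ratio_matrix(none, fx$res$mirna_log, fx$res$gene_log),
               "no interaction")
})

test_that("k-means clustering recovers separated blobs deterministically", {
  set.seed(24)
  blob <- cbind(matrix(rnorm(5 * 20, -3), 5, 20), matrix(rnorm(5 * 20, 3), 5, 20))
  colnames(blob) <- paste0("p", 1:40)
  rownames(blob) <- paste0("i", 1:5)
  cl <- cluster_patients(blob, seed = 1L)
  expect_s3_class(cl, "patient_clustering")
  lab <- cl$cluster
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)
  expect_false(lab[1] == lab[40])
  cl2 <- cluster_patients(blob, seed = 1L)
  expect_identical(cl$cluster, cl2$cluster)

  same <- matrix(1, 3, 10, dimnames = list(paste0("i", 1:3), paste0("p", 1:10)))
  expect_error(cluster_patients(same), "degenerate")
  expect_error(cluster_patients(blob[, 1, drop = FALSE]), "fewer patients")
})

test_that("signature evaluation orients the hazard ratio to the poor cluster", {
  set.seed(25)
  n <- 120
  cl_lab <- rep(1:2, each = n / 2)
  time <- rexp(n, 0.01 * exp(ifelse(cl_lab == 2, 1, 0)))
  clinical <- as_clinical_table(data.frame(
    sample = paste0("p", 1:n), time = time, event = 1,
    age = runif(n, 40, 80),
    gender = sample(c("male", "female"), n, TRUE)))
  clus <- structure(list(cluster = setNames(cl_lab, clinical$sample),
                         inertia = 0, k = 2, n_restarts = 1, seed = 1),
                    class = "patient_clustering")
  ev <- evaluate_signature(clus, clinical)
  expect_equal(ev$poor_cluster, 2)
  expect_gt(ev$hr, 1)
  expect_lt(ev$logrank_p, 0.01)

  # swapping the labels leaves the poor cluster's identity, HR and p intact
  clus_sw <- clus
  clus_sw$cluster <- setNames(3 - cl_lab, clinical$sample)
  ev_sw <- evaluate_signature(clus_sw, clinical)
  expect_equal(ev_sw$poor_cluster, 1)
  expect_equal(ev_sw$hr, ev$hr, tolerance = 1e-9)
  expect_equal(ev_sw$logrank_p, ev$logrank_p, tolerance = 1e-12)

  # patient order invariance
  perm <- sample(n)
  clus_p <- clus
  clus_p$cluster <- clus$cluster[perm]
  ev_p <- evaluate_signature(clus_p, clinical)
  expect_equal(ev_p$logrank_p, ev$logrank_p, tolerance = 1e-12)
  expect_equal(ev_p$hr, ev$hr, tolerance = 1e-9)
})

test_that("random clusters give uniform log-rank p under null survival", {
  set.seed(26)
  ps <- replicate(60, {
    n <- 60
    clinical <- as_clinical_table(data.frame(
      sample = paste0("p", 1:n), time = rexp(n, 0.01),
      event = rbinom(n, 1, 0.9), age = runif(n, 40, 80),
      gender = sample(c("male", "female"), n, TRUE)))
    clus <- structure(list(cluster = setNames(sample(rep(1:2, n / 2)),
                                              clinical$sample),
                           inertia = 0, k = 2, n_restarts = 1, seed = 1),
                      class = "patient_clustering")
    evaluate_signature(clus, clinical)$logrank_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("clustering on the planted prognostic profile separates survival", {
  fx <- sig_fixture()
  prog <- fx$cohort$truth[fx$cohort$truth$is_prognostic, ]
  rmat <- ratio_matrix(prog, fx$res$mirna_log, fx$res$gene_log)
  # aggregate direction-oriented profile: the axis the hazard acts on
  agg <- rbind(aggregate = colMeans(rmat * prog$true_beta_sign))
  clus <- cluster_patients(agg, seed = 2L)
  ev <- evaluate_signature(clus, fx$cohort$clinical)
  expect_lt(ev$logrank_p, 0.05)
  expect_gt(ev$hr, 1)
})

test_that("self-transfer reproduces the direct evaluation exactly", {
  fx <- sig_fixture()
  prog <- fx$cohort$truth[fx$cohort$truth$is_prognostic, ]
  rmat <- ratio_matrix(prog, fx$res$mirna_log, fx$res$gene_log)
  direct_clus <- cluster_patients(rmat, seed = 3L)
  direct <- evaluate_signature(direct_clus, fx$cohort$clinical)
  transfer <- cross_cohort_evaluation(prog, fx$res$mirna_log,
                                      fx$res$gene_log, fx$cohort$clinical,
                                      seed = 3L)
  expect_identical(transfer$logrank_p, direct$logrank_p)
  expect_identical(transfer$hr, direct$hr)
  expect_equal(transfer$fraction_transferable, 1)
  expect_error(cross_cohort_evaluation(prog[1:2, ], fx$res$mirna_log,
                                       fx$res$gene_log, fx$cohort$clinical),
               "fewer than 3")
})

test_that("baseline comparison returns one log-rank p per strategy", {
  fx <- sig_fixture()
  key <- fx$res$key_interactions
  if (nrow(key) < 3) key <- fx$cohort$truth[fx$cohort$truth$is_prognostic, ]
  bl <- baseline_comparison(key, fx$res$dysregulated,
                            unique(key$mirna), fx$res$mirna_log,
                            fx$res$gene_log, fx$cohort$clinical, seed = 4L)
  expect_setequal(bl$baseline,
                  c("key_interactions", "all_interactions", "key_mirnas"))
  expect_true(all(bl$logrank_p > 0 & bl$logrank_p <= 1))
  expect_equal(bl$neglog10_p, -log10(bl$logrank_p))
})

test_that("chi-square matches the textbook formula and published rounding", {
  lit_risk <- matrix(c(42, 9, 45, 35), 2, byrow = TRUE)
  lit_met <- matrix(c(34, 17, 32, 48), 2, byrow = TRUE)
  expect_equal(round(chi_square_2x2(lit_risk)$p, 3), 0.004)
  expect_equal(round(chi_square_2x2(lit_met)$p, 3), 0.005)

  flat <- matrix(10, 2, 2)
  res <- chi_square_2x2(flat, continuity = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # uncorrected statistic equals sum((O-E)^2/E) computed by hand
  tab <- matrix(c(12, 5, 9, 14), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_2x2(tab, continuity = FALSE)$statistic,
               sum((tab - E)^2 / E), tolerance = 1e-12)

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_error(chi_square_2x2(matrix(-1, 2, 2)), "non-negative")
})

test_that("Fisher's exact test matches full enumeration and is transpose-invariant", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)
  set.seed(27)
  for (r in 1:10) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab)), fisher_exact_2x2(tab),
                 tolerance = 1e-12)
  }
})

test_that("chi-square and Fisher agree in call on well-filled tables", {
  set.seed(28)
  agree <- replicate(100, {
    tab <- matrix(rpois(4, 30) + 10, 2, 2)
    (chi_square_2x2(tab)$p < 0.05) == (fisher_exact_2x2(tab) < 0.05)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("secondary outcome tests use available columns and skip others", {
  fx <- sig_fixture()
  prog <- fx$cohort$truth[fx$cohort$truth$is_prognostic, ]
  rmat <- ratio_matrix(prog, fx$res$mirna_log, fx$res$gene_log)
  clus <- cluster_patients(rmat, seed = 5L)
  res <- secondary_outcome_tests(clus, fx$cohort$clinical)
  expect_true(all(res$available))
  expect_true(all(res$p[res$available] >= 0 & res$p[res$available] <= 1))

  bare <- fx$cohort$clinical[, c("sample", "time", "event", "age", "gender")]
  res2 <- secondary_outcome_tests(clus, as_clinical_table(bare))
  expect_false(any(res2$available))
  expect_true(all(is.na(res2$p)))
})

test_that("KPS exactly 60 is not poor functional status", {
  set.seed(29)
  n <- 80
  cl <- as_clinical_table(data.frame(
    sample = paste0("p", 1:n), time = rexp(n, 0.01), event = 1,
    age = runif(n, 40, 80), gender = sample(c("male", "female"), n, TRUE),
    kps = rep(c(60, 50), each = n / 2)))
  clus <- structure(list(cluster = setNames(rep(1:2, n / 2), cl$sample),
                         inertia = 0, k = 2, n_restarts = 1, seed = 1),
                    class = "patient_clustering")
  res <- secondary_outcome_tests(clus, cl)
  # the 2x2 built internally must classify all kps = 60 patients as not-poor:
  # reproduce the table and p
  low <- factor(cl$kps < 60, levels = c(FALSE, TRUE))
  tab <- table(factor(clus$cluster), low)
  expect_equal(sum(tab[, "TRUE"]), n / 2)
  expect_equal(res$p[res$test == "kps_fisher"],
               fisher_exact_2x2(matrix(tab, 2, 2)))
})
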