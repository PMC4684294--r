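# ROC/AUC, KS, hypergeometric, silent players, log-rank, alpha sweep.

test_that("AUC handles perfect, tied and random rankings per the rank convention", {
  ev <- roc_auc(c(a = 0.9, b = 0.8, c = 0.1), c(a = 1L, b = 1L, c = 0L))
  expect_equal(ev$auc, 1)
  expect_equal(ev$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(as.numeric(ev$roc_points[nrow(ev$roc_points), ]), c(1, 1))

  tied <- roc_auc(c(a = 0.5, b = 0.5), c(a = 1L, b = 0L))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_auc(c(a = 1), c(a = 1L)), class = "netsilent_degenerate_error")

  for (seed in 1:5) {
    set.seed(seed)
    s <- stats::setNames(sample(round(runif(200), 2)), sprintf("g%03d", 1:200))
    l <- stats::setNames(rbinom(200, 1, 0.3), names(s))
    if (sum(l) %in% c(0, 200)) next
    expect_equal(roc_auc(s, l)$auc, pair_count_auc(s, l), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  s <- stats::setNames(runif(150), sprintf("g%03d", 1:150))
  l <- stats::setNames(rbinom(150, 1, 0.2), names(s))
  base <- roc_auc(s, l)$auc
  expect_equal(roc_auc(stats::qlogis(s * 0.98 + 0.01), l)$auc, base)
  expect_equal(roc_auc(s^3, l)$auc, base)
})

test_that("ROC points are monotone and pROC agrees on the AUC", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- stats::setNames(runif(300), sprintf("g%03d", 1:300))
  l <- stats::setNames(rbinom(300, 1, 0.25), names(s))
  ev <- roc_auc(s, l)
  expect_true(all(diff(ev$roc_points$fpr) >= 0))
  expect_true(all(diff(ev$roc_points$tpr) >= 0))
  ref <- pROC::auc(pROC::roc(response = l, predictor = s, quiet = TRUE,
                             direction = "<"))
  expect_equal(ev$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("KS comparison matches an explicit CDF max-gap scan", {
  same <- stats::setNames(rep(c(1, 2, 3), 4), sprintf("g%02d", 1:12))
  lab_half <- stats::setNames(rep(c(1L, 0L), 6), names(same))
  res <- ks_compare(same, lab_half)
  expect_equal(res$D, 0)
  expect_equal(res$p_value, 1)

  vals <- stats::setNames(c(runif(50), runif(50) + 2), sprintf("g%03d", 1:100))
  labs <- stats::setNames(rep(c(1L, 0L), each = 50), names(vals))
  expect_equal(ks_compare(vals, labs)$D, 1)  # disjoint supports

  set.seed(10)
  x <- rnorm(60); y <- rnorm(40) + 0.5
  v <- stats::setNames(c(x, y), sprintf("g%03d", 1:100))
  l <- stats::setNames(rep(c(1L, 0L), c(60, 40)), names(v))
  grid <- sort(unique(v))
  gap <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(ks_compare(v, l)$D, gap, tolerance = 1e-12)
})

test_that("hypergeometric tail equals exhaustive enumeration for all N <= 20", {
  expect_equal(hypergeometric_tail(10, 5, 4, 3), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(10, 5, 4, 0), 1)
  expect_equal(hypergeometric_tail(10, 2, 4, 3), 0)  # k > min(K, n)
  expect_error(hypergeometric_tail(5, 6, 2, 1), class = "netsilent_input_error")

  for (N in c(5, 12, 20)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:n) {
      expect_equal(hypergeometric_tail(N, K, n, k), enum_hyper_tail(N, K, n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("silent-player selection equals the set-filter oracle and is anti-monotone", {
  genes <- sprintf("g%03d", 1:80)
  set.seed(12)
  comb <- stats::setNames(runif(80, 0, 0.6), genes)
  mo <- stats::setNames(runif(80, 0, 0.4), genes)
  eo <- stats::setNames(runif(80, 0, 0.4), genes)
  pw <- gene_set(sample(genes, 15))
  got <- select_silent_players(comb, mo, eo, pw, threshold = 0.2)
  want <- genes[!(genes %in% pw$members) & comb >= 0.2 & mo < 0.2 & eo < 0.2]
  expect_setequal(got$gene, want)
  expect_true(all(diff(got$combined_score) <= 0))

  # single-gene contract cases
  one <- function(c, m, e) nrow(select_silent_players(
    c(g = c), c(g = m), c(g = e), gene_set("other"), threshold = 0.2))
  expect_equal(one(0.41, 0.05, 0.10), 1L)
  expect_equal(one(0.41, 0.25, 0.10), 0L)

  # an unreachable threshold empties the list (combined scores live in (0,1))
  expect_equal(nrow(select_silent_players(comb, mo, eo, pw, threshold = 1)), 0L)

  expect_error(select_silent_players(comb, mo[-1], eo, pw),
               class = "netsilent_input_error")
})

test_that("log-rank handles symmetric, hand-computed and degenerate inputs", {
  # identical event-time multisets in both groups: O = E everywhere
  cl <- data.frame(sample = sprintf("s%d", 1:8),
                   time = rep(c(1, 2, 3, 4), 2), event = 1L)
  status <- stats::setNames(rep(c(1L, 0L), each = 4), cl$sample)
  res <- logrank_by_gene(status, cl)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # one event in group 1 at t=1, group 0 censored later:
  # O - E = 0.5, Var = 0.25, chisq = 1
  cl2 <- data.frame(sample = c("a", "b"), time = c(1, 2), event = c(1L, 0L))
  st2 <- c(a = 1L, b = 0L)
  res2 <- logrank_by_gene(st2, cl2)
  expect_equal(res2$chisq, 1, tolerance = 1e-12)
  expect_equal(res2$p_value, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-9)

  # all samples in one group: untestable, not an error
  res3 <- logrank_by_gene(stats::setNames(rep(1L, 8), cl$sample), cl)
  expect_false(res3$testable)
  expect_true(is.na(res3$p_value))
})

test_that("log-rank agrees with a manual O-E computation and a permutation null", {
  set.seed(14)
  n <- 60
  cl <- data.frame(sample = sprintf("s%02d", 1:n),
                   time = round(rexp(n, 0.1), 2),
                   event = rbinom(n, 1, 0.7))
  status <- stats::setNames(rbinom(n, 1, 0.4), cl$sample)
  res <- logrank_by_gene(status, cl)
  expect_equal(res$chisq,
               logrank_chisq_manual(cl$time, cl$event, status[cl$sample]),
               tolerance = 1e-9)

  # permutation reference for the p-value
  n_perm <- 10000
  set.seed(15)
  perm_stats <- replicate(n_perm, {
    logrank_chisq_manual(cl$time, cl$event, sample(status))
  })
  p_perm <- mean(perm_stats >= res$chisq)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(res$p_value - p_perm), 3 * max(se, 1e-3))
})

test_that("survival screen covers top genes and marks missing columns untestable", {
  co <- tiny_cohort(seed = 41)
  cohort <- co$cohort
  scores <- stats::setNames(seq(1, 0, length.out = ncol(cohort$M)),
                            colnames(cohort$M))
  pw <- gene_set(names(scores)[3:10])
  tab <- survival_screen(scores, pw, cohort$M, cohort$D, cohort$clinical,
                         top_k = 5L)
  expect_equal(nrow(tab), 5L)
  expect_false(any(tab$gene %in% pw$members))
  expect_true(all(tab$score == sort(tab$score, decreasing = TRUE)))

  # single best gene reduces to logrank_by_gene
  tab1 <- survival_screen(scores, pw, cohort$M, cohort$D, cohort$clinical,
                          top_k = 1L)
  g <- tab1$gene[1]
  ref <- logrank_by_gene(stats::setNames(cohort$M[, g], rownames(cohort$M)),
                         cohort$clinical)
  expect_equal(tab1$mutation_p, ref$p_value)

  # gene absent from M: untestable mutation split
  M2 <- cohort$M[, colnames(cohort$M) != g]
  tab2 <- survival_screen(scores, pw, M2, cohort$D, cohort$clinical, top_k = 1L)
  expect_false(tab2$mutation_testable[1])
  expect_true(is.na(tab2$mutation_p[1]))
})

test_that("planted survival signal is detected on the truth split", {
  # single planted module, hazard ratio 3: the module-activity split should
  # separate survival in the vast majority of replicates
  hits <- vapply(1:30, function(seed) {
    cfg <- sim_config(n_genes = 150L, n_samples = 300L, n_causal = 1L,
                      min_causal_degree = 5L, hazard_ratio = 3, seed = seed)
    net <- generate_network(cfg)
    co <- generate_cohort(cfg, net)
    status <- stats::setNames(as.integer(co$truth$any_active), co$clinical$sample)
    logrank_by_gene(status, co$clinical)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("alpha sweep reduces to the direct pipeline at a single alpha", {
  co <- tiny_cohort(seed = 42)
  pw <- cohort_pathway(co$cohort, n_background = 20L)
  sw <- suppressWarnings(alpha_sweep(co$network, co$cohort$M, co$cohort$D, pw,
                                     alphas = 0.8))
  run <- suppressWarnings(run_pipeline(co$network, co$cohort$M, co$cohort$D, pw))
  expect_equal(sw$auc, unname(run$evaluation$model_auc[["combined"]]),
               tolerance = 1e-12)
  expect_equal(nrow(sw), 1L)
})

test_that("near-zero alpha collapses propagation toward the raw prior", {
  co <- tiny_cohort(seed = 43)
  netN <- laplacian_normalize(co$network)
  MP <- propagate_matrix(netN, co$cohort$M, alpha = 0.01)
  prior <- matrix(0, nrow(MP), ncol(MP), dimnames = dimnames(MP))
  shared <- intersect(colnames(co$cohort$M), colnames(MP))
  prior[, shared] <- co$cohort$M[, shared]
  expect_lt(max(abs(MP - 0.99 * prior)), 0.02)  # F ~ (1 - alpha) Y
})
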