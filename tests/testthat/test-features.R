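# The thirteen-feature consolidation and eigenvector centrality.

test_that("hand-computed feature values on a two-sample column are exact", {
  samples <- c("s1", "s2")
  genes <- c("g", "h")
  MP <- matrix(c(0.6, 0.4, 0.2, 0.1), nrow = 2, dimnames = list(samples, genes))
  DP <- matrix(c(0.1, 0.5, 0.2, 0.3), nrow = 2, dimnames = list(samples, genes))
  M <- matrix(0L, 2, 2, dimnames = list(samples, genes))
  D <- matrix(0L, 2, 2, dimnames = list(samples, genes))
  ft <- compute_feature_table(M, D, MP, DP, c(g = 0.5, h = 0.5))
  g <- ft[ft$gene == "g", ]
  expect_equal(g$delta, 0.6 * 0.1 + 0.4 * 0.5)        # 0.26
  expect_equal(g$chi_max, 0.6)
  expect_equal(g$chi_mean, 0.55)
  expect_equal(g$nu_max, 0.4)
  expect_equal(g$nu_mean, 0.25)
  expect_equal(g$rho, -1)                             # opposite two-point ranks

  # identical propagated columns: rho = 1 and chi coincides with nu
  DP2 <- MP
  ft2 <- suppressWarnings(compute_feature_table(M, D, MP, DP2, c(g = 1, h = 1)))
  expect_equal(ft2$rho, c(1, 1))
  expect_equal(ft2$chi_max, ft2$nu_max)
  expect_equal(ft2$chi_mean, ft2$nu_mean)
})

test_that("all thirteen columns match the per-definition loop oracle", {
  for (seed in 1:5) {
    genes <- sprintf("g%02d", 1:6)
    set.seed(seed)
    MP <- matrix(runif(48), nrow = 8, dimnames = list(sprintf("s%02d", 1:8), genes))
    DP <- matrix(runif(48), nrow = 8, dimnames = list(sprintf("s%02d", 1:8), genes))
    # M/D cover a superset of the universe; one universe gene missing from M
    M <- random_binary_matrix(8, c(genes[-2], "outside"), 0.4, seed = seed + 10)
    D <- random_binary_matrix(8, c(genes, "outside2"), 0.4, seed = seed + 20)
    rownames(M) <- rownames(D) <- rownames(MP)
    gamma <- stats::setNames(runif(6), genes)
    got <- compute_feature_table(M, D, MP, DP, gamma)
    want <- naive_feature_table(M, D, MP, DP, gamma)
    for (col in feature_names()) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12, label = col)
    }
    expect_equal(got[got$gene == genes[2], "mu_M"], 0)  # absent from M
  }
})

test_that("structural inequalities hold on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:10, 1)
    genes <- sprintf("g%d", 1:4)
    MP <- matrix(runif(4 * n), nrow = n, dimnames = list(sprintf("s%d", 1:n), genes))
    DP <- matrix(runif(4 * n), nrow = n, dimnames = list(sprintf("s%d", 1:n), genes))
    M <- D <- matrix(0L, n, 4, dimnames = dimnames(MP))
    ft <- suppressWarnings(compute_feature_table(M, D, MP, DP,
                                                 stats::setNames(rep(1, 4), genes)))
    expect_true(all(ft$chi_max >= ft$nu_max))
    expect_true(all(ft$chi_mean >= ft$nu_mean))
    expect_true(all(ft$delta <= n * ft$chi_max^2 + 1e-12))
    expect_true(all(ft$rho >= -1 & ft$rho <= 1))
    expect_true(all(ft$var_MP >= 0 & ft$var_DP >= 0))
  }
})

test_that("features are invariant under joint sample permutation but not independent ones", {
  co <- tiny_cohort(seed = 21)
  netN <- laplacian_normalize(co$network)
  MP <- propagate_matrix(netN, co$cohort$M)
  DP <- propagate_matrix(netN, co$cohort$D)
  gamma <- eigenvector_centrality(co$network)
  ft <- suppressWarnings(compute_feature_table(co$cohort$M, co$cohort$D, MP, DP, gamma))
  set.seed(1)
  perm <- sample(nrow(MP))
  ft_perm <- suppressWarnings(compute_feature_table(
    co$cohort$M[perm, ], co$cohort$D[perm, ], MP[perm, ], DP[perm, ], gamma))
  expect_equal(ft_perm, ft, tolerance = 1e-12)

  # permuting MP values independently of DP must perturb the cross-source
  # features (sample labels kept aligned so only the pairing changes)
  MP_shuf <- MP[perm, ]
  rownames(MP_shuf) <- rownames(MP)
  ft_bad <- suppressWarnings(compute_feature_table(
    co$cohort$M, co$cohort$D, MP_shuf, DP, gamma))
  expect_failure(expect_equal(ft_bad$delta, ft$delta, tolerance = 1e-8))
  expect_failure(expect_equal(ft_bad$rho, ft$rho, tolerance = 1e-8))

  # misaligned sample labels are rejected outright
  expect_error(compute_feature_table(co$cohort$M[perm, ], co$cohort$D, MP, DP, gamma),
               class = "netsilent_input_error")
})

test_that("constant propagated columns give rho = 0 with a warning", {
  genes <- c("g1", "g2")
  MP <- matrix(c(0.3, 0.3, 0.1, 0.4), nrow = 2,
               dimnames = list(c("s1", "s2"), genes))
  DP <- matrix(runif(4), nrow = 2, dimnames = dimnames(MP))
  M <- D <- matrix(0L, 2, 2, dimnames = dimnames(MP))
  expect_warning(
    ft <- compute_feature_table(M, D, MP, DP, c(g1 = 1, g2 = 1)),
    "constant")
  expect_equal(ft$rho[1], 0)
})

test_that("a gene bridging both signal types out-scores single-type genes in nu_mean", {
  # star-of-stars: 'both' neighbors a mutated and a DE seed; 'mutonly' two
  # mutated seeds; 'deonly' two DE seeds — all at matched degree 2
  edges <- data.frame(
    gene_a = c("both", "both", "mutonly", "mutonly", "deonly", "deonly"),
    gene_b = c("mut1", "de1", "mut2", "mut3", "de2", "de3"),
    weight = 1)
  net <- gene_network(edges)
  netN <- laplacian_normalize(net)
  samples <- sprintf("s%d", 1:4)
  M <- D <- matrix(0L, 4, length(net$nodes), dimnames = list(samples, net$nodes))
  M[, c("mut1", "mut2", "mut3")] <- 1L
  D[, c("de1", "de2", "de3")] <- 1L
  MP <- propagate_matrix(netN, M)
  DP <- propagate_matrix(netN, D)
  ft <- suppressWarnings(compute_feature_table(M, D, MP, DP,
                                               eigenvector_centrality(net)))
  nu <- stats::setNames(ft$nu_mean, ft$gene)
  expect_gt(nu[["both"]], nu[["mutonly"]])
  expect_gt(nu[["both"]], nu[["deonly"]])
})

test_that("eigenvector centrality matches dense eigensolver and known structures", {
  # complete graph: all scores equal by symmetry
  K4 <- expand.grid(a = c("A", "B", "C", "D"), b = c("A", "B", "C", "D"))
  K4 <- K4[as.character(K4$a) < as.character(K4$b), ]
  net_k <- gene_network(data.frame(gene_a = K4$a, gene_b = K4$b, weight = 1))
  ck <- eigenvector_centrality(net_k)
  expect_equal(max(ck) - min(ck), 0, tolerance = 1e-9)

  # star with 4 leaves: hub/leaf ratio sqrt(4), hub = 1/sqrt(2)
  star <- gene_network(data.frame(gene_a = "hub",
                                  gene_b = sprintf("leaf%d", 1:4), weight = 1))
  cs <- eigenvector_centrality(star)
  expect_equal(unname(cs["hub"] / cs["leaf1"]), 2, tolerance = 1e-8)
  expect_equal(unname(cs["hub"]), 1 / sqrt(2), tolerance = 1e-8)

  # random weighted graph vs dense eigen()
  for (seed in 4:6) {
    net <- random_network(25, 60, seed = seed)
    got <- eigenvector_centrality(net)
    ev <- eigen(as.matrix(net$W), symmetric = TRUE)
    ref <- abs(ev$vectors[, which.max(ev$values)])
    expect_lt(max(abs(got - ref / sqrt(sum(ref^2)))), 1e-8)
    expect_equal(sum(got^2), 1, tolerance = 1e-10)
    expect_true(all(got >= 0))
  }
})
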