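# Independent brute-force oracles and small fixture builders shared by the
# suite. Oracles deliberately avoid the code paths they check.

# random connected-ish weighted graph as an edge data frame
random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  # spanning path guarantees a connected backbone
  path <- data.frame(gene_a = nodes[-n_nodes], gene_b = nodes[-1L],
                     weight = round(runif(n_nodes - 1L, 0.1, 1), 6))
  extra <- n_edges - (n_nodes - 1L)
  if (extra > 0L) {
    a <- sample(nodes, extra, replace = TRUE)
    b <- sample(nodes, extra, replace = TRUE)
    keep <- a != b
    path <- rbind(path, data.frame(gene_a = a[keep], gene_b = b[keep],
                                   weight = round(runif(sum(keep), 0.1, 1), 6)))
  }
  path
}

random_network <- function(n_nodes, n_edges, seed) {
  gene_network(random_edges(n_nodes, n_edges, seed))
}

random_binary_matrix <- function(n_samples, genes, p, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_samples * length(genes), 1L, p),
              nrow = n_samples,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)), genes))
  storage.mode(m) <- "integer"
  m
}

# dense reference for the propagation fixed point
dense_fixed_point <- function(net, Y, alpha) {
  W <- as.matrix(net$W)
  d <- rowSums(W)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Wp <- diag(inv) %*% W %*% diag(inv)
  as.numeric(solve(diag(nrow(W)) - alpha * Wp, (1 - alpha) * Y))
}

# per-definition loop over the thirteen features
naive_feature_table <- function(M, D, MP, DP, gamma) {
  genes <- colnames(MP)
  n <- nrow(MP)
  out <- lapply(genes, function(g) {
    mp <- MP[, g]; dp <- DP[, g]
    rho <- if (length(unique(mp)) > 1L && length(unique(dp)) > 1L) {
      suppressWarnings(cor(mp, dp, method = "spearman"))
    } else 0
    data.frame(
      gene = g,
      mu_M = if (g %in% colnames(M)) sum(M[, g]) / n else 0,
      mu_MP = sum(mp) / n,
      var_MP = var(mp),
      mu_D = if (g %in% colnames(D)) sum(D[, g]) / n else 0,
      mu_DP = sum(dp) / n,
      var_DP = var(dp),
      rho = rho,
      delta = sum(mp * dp),
      chi_max = max(mapply(max, mp, dp)),
      chi_mean = mean(mapply(max, mp, dp)),
      nu_max = max(mapply(min, mp, dp)),
      nu_mean = mean(mapply(min, mp, dp)),
      gamma = unname(gamma[g]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# AUC by exhaustive concordant-pair counting
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# upper-tail hypergeometric by exhaustive enumeration over choose()
enum_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (k > min(K, n)) return(0)
  kk <- seq.int(k, min(K, n))
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# two-group log-rank chi-square from first principles (O-E tables)
logrank_chisq_manual <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1)
    }
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# small cohort used across tests
tiny_cohort <- function(seed = 11L, ...) {
  cfg <- sim_config(n_genes = 120L, n_samples = 40L, n_causal = 3L,
                    min_causal_degree = 4L, seed = seed, ...)
  net <- generate_network(cfg)
  list(config = cfg, network = net, cohort = generate_cohort(cfg, net))
}
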