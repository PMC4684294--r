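# Per-gene consolidation of raw and propagated mutation / differential
# expression signals into the 13-column feature table driving the
# logistic model.

#' Canonical order of the thirteen feature columns
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c("mu_M", "mu_MP", "var_MP", "mu_D", "mu_DP", "var_DP",
    "rho", "delta", "chi_max", "chi_mean", "nu_max", "nu_mean", "gamma")
}

# features derived from each single data source; cross-source features
# (rho, delta, chi, nu) exist only in the combined model
mutation_feature_names <- function() c("mu_M", "mu_MP", "var_MP")
expression_feature_names <- function() c("mu_D", "mu_DP", "var_DP")

#' Compute the per-gene feature table
#'
#' For each network gene `g` over the `n` shared samples:
#' * `mu_M`, `mu_D`: raw mutation / differential-expression frequency
#'   (0 for genes absent from the respective matrix);
#' * `mu_MP`, `mu_DP`: mean of the propagated column — mean network
#'   proximity to mutated / differentially expressed genes;
#' * `var_MP`, `var_DP`: variance of the propagated column — how
#'   inconsistently the gene's neighborhood carries signal across samples;
#' * `rho`: Spearman correlation between the propagated mutation and
#'   expression columns (average ranks for ties; 0 when either column is
#'   constant, with a warning);
#' * `delta`: dot product of the two propagated columns — unnormalized
#'   co-proximity magnitude;
#' * `chi_max`, `chi_mean`: per-sample `max(MP, DP)` aggregated by max /
#'   mean — proximity to either signal type;
#' * `nu_max`, `nu_mean`: per-sample `min(MP, DP)` aggregated by max /
#'   mean — proximity to both signal types, the silent-player signature;
#' * `gamma`: eigenvector centrality, copied from the `gamma` argument.
#'
#' @param M,D binary omic matrices (samples x genes; genes may extend
#'   beyond the network universe).
#' @param MP,DP propagated matrices (samples x network genes) with
#'   identical sample order as `M` and `D` and identical gene order.
#' @param gamma named per-gene centrality vector over the network genes
#'   (see [eigenvector_centrality()]).
#' @param var_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return Data frame with column `gene` followed by the 13 features in
#'   [feature_names()] order.
#' @export
compute_feature_table <- function(M, D, MP, DP, gamma,
                                  var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  genes <- colnames(MP)
  samples <- rownames(MP)
  if (!identical(colnames(DP), genes)) {
    ns_input_error("MP and DP must share an identical gene universe")
  }
  for (nm in list(c("M", "MP"), c("D", "MP"), c("DP", "MP"))) {
    a <- get(nm[1L]); b <- get(nm[2L])
    if (!identical(rownames(a), samples)) {
      ns_input_error(sprintf("sample sets of %s and %s are not aligned", nm[1L], nm[2L]))
    }
  }
  n <- length(samples)

  freq_in_universe <- function(A) {
    mu <- stats::setNames(numeric(length(genes)), genes)
    shared <- intersect(colnames(A), genes)
    mu[shared] <- colMeans(A[, shared, drop = FALSE])
    mu
  }
  col_var <- function(X) {
    v <- colMeans(sweep(X, 2L, colMeans(X))^2)  # two-pass population variance
    if (var_type == "sample" && n > 1L) v <- v * n / (n - 1L)
    v
  }
  # Spearman: Pearson correlation of average ranks, column by column
  spearman_cols <- function(X, Y) {
    rx <- apply(X, 2L, rank)
    ry <- apply(Y, 2L, rank)
    rx <- sweep(rx, 2L, colMeans(rx))
    ry <- sweep(ry, 2L, colMeans(ry))
    sx <- sqrt(colSums(rx^2))
    sy <- sqrt(colSums(ry^2))
    num <- colSums(rx * ry)
    rho <- ifelse(sx > 0 & sy > 0, num / (sx * sy), 0)
    n_const <- sum(sx == 0 | sy == 0)
    if (n_const > 0L) {
      warning(sprintf("Spearman correlation undefined for %d constant gene column(s); set to 0",
                      n_const), call. = FALSE)
    }
    rho
  }

  pmx <- pmax(MP, DP)
  pmn <- pmin(MP, DP)

  if (is.null(names(gamma))) {
    if (length(gamma) != length(genes)) {
      ns_input_error("gamma must be named or match the gene universe length")
    }
    gamma <- stats::setNames(gamma, genes)
  }

  data.frame(
    gene     = genes,
    mu_M     = unname(freq_in_universe(M)),
    mu_MP    = unname(colMeans(MP)),
    var_MP   = unname(col_var(MP)),
    mu_D     = unname(freq_in_universe(D)),
    mu_DP    = unname(colMeans(DP)),
    var_DP   = unname(col_var(DP)),
    rho      = unname(spearman_cols(MP, DP)),
    delta    = unname(colSums(MP * DP)),
    chi_max  = unname(apply(pmx, 2L, max)),
    chi_mean = unname(colMeans(pmx)),
    nu_max   = unname(apply(pmn, 2L, max)),
    nu_mean  = unname(colMeans(pmn)),
    gamma    = unname(gamma[genes]),
    stringsAsFactors = FALSE
  )
}

#' Eigenvector centrality of the weighted network
#'
#' Principal-eigenvector scores of the weighted adjacency matrix, computed
#' by power iteration from a uniform start vector and L2-normalized. The
#' iteration applies `W + I` rather than `W`: the shift leaves the
#' eigenvectors untouched but makes the Perron eigenvalue strictly
#' dominant, so the iteration also converges on bipartite graphs (where
#' `W` alone has the paired eigenvalue `-lambda_max` and oscillates).
#' Scores are non-negative (Perron vector). In a disconnected network the
#' iteration converges on the spectrally dominant component; other
#' components receive scores near zero.
#'
#' @param net a `gene_network`.
#' @param tol L2 tolerance on the change of the normalized vector.
#' @param max_iter iteration cap.
#' @return Named non-negative numeric vector over the network nodes, unit
#'   L2 norm.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  n <- length(net$nodes)
  W <- net$W
  v <- rep(1 / sqrt(n), n)
  resid <- Inf
  for (t in seq_len(max_iter)) {
    v_new <- as.numeric(W %*% v) + v  # spectral shift: iterate W + I
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) ns_convergence_error("eigenvector centrality undefined: W v vanished (empty network?)")
    v_new <- v_new / nrm
    resid <- sqrt(sum((v_new - v)^2))
    v <- v_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    ns_convergence_error(sprintf(
      "eigenvector centrality power iteration did not converge in %d iterations (residual %.3g)",
      max_iter, resid))
  }
  v <- abs(v)  # Perron vector, fix sign
  stats::setNames(v / sqrt(sum(v^2)), net$nodes)
}

#' Write a feature table as TSV
#' @param ft data frame from [compute_feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path path to the TSV.
#' @return Data frame with `gene` plus the 13 feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("feature-table file not found: %s", path))
  ft <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", feature_names()), names(ft))
  if (length(missing)) {
    ns_input_error(sprintf("feature table %s lacks column(s): %s",
                           path, paste(missing, collapse = ", ")))
  }
  ft
}
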