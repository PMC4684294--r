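# Evaluation machinery: ROC/AUC, feature-distribution KS tests,
# hypergeometric enrichment, silent-player selection, survival
# stratification and the alpha sweep.

#' ROC curve and AUC for a gene ranking
#'
#' The AUC is the normalized Mann-Whitney U statistic of the scores
#' (average-rank handling of ties); the ROC curve is built by a threshold
#' sweep over the distinct score values, grouping ties, with trapezoidal
#' geometry.
#'
#' @param scores named numeric score vector.
#' @param labels named 0/1 labels over the same genes.
#' @return Object of class `ranking_evaluation`: list with `auc`,
#'   `roc_points` (data frame of `fpr`, `tpr` from (0,0) to (1,1)),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    if (!setequal(names(scores), names(labels))) {
      ns_input_error("scores and labels cover different gene universes")
    }
    labels <- labels[names(scores)]
  }
  if (anyNA(scores)) ns_input_error("scores contain missing values")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    ns_degenerate_error("ROC requires both positive and negative labels")
  }
  r <- rank(scores)  # average ranks
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))        # tie groups of the sorted scores
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
  structure(list(auc = auc, roc_points = roc, n_pos = n_pos, n_neg = n_neg),
            class = "ranking_evaluation")
}

#' @export
print.ranking_evaluation <- function(x, ...) {
  cat(sprintf("ranking_evaluation: AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of a feature by label
#'
#' Compares the distribution of one feature between positive-labeled and
#' negative-labeled genes (as in per-feature CDF plots), returning the KS D
#' statistic and the asymptotic p-value.
#'
#' @param feature_values named numeric vector of one feature.
#' @param labels named 0/1 labels over the same genes.
#' @return List with `D` and `p_value`.
#' @export
ks_compare <- function(feature_values, labels) {
  if (!is.null(names(feature_values)) && !is.null(names(labels))) {
    labels <- labels[names(feature_values)]
  }
  pos <- feature_values[labels == 1L]
  neg <- feature_values[labels == 0L]
  if (!length(pos) || !length(neg)) {
    ns_degenerate_error("KS comparison requires both label classes to be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(pos, neg, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` when drawing `n` genes without replacement from a population
#' of `N` containing `K` successes. Evaluated in log space via
#' [stats::phyper()] so extreme tails do not underflow.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @param k observed successes among the draws.
#' @return The p-value.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || K > N) {
    ns_input_error(sprintf("inconsistent hypergeometric parameters N=%s K=%s n=%s k=%s",
                           N, K, n, k))
  }
  if (k == 0) return(1)
  if (k > min(K, n)) return(0)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Select candidate silent players
#'
#' A silent player is a gene outside the training pathway whose combined
#' model score reaches the threshold while neither the mutation-only nor
#' the expression-only model score does — a gene implicated only when the
#' two data types are integrated over the network.
#'
#' @param combined,mut_only,expr_only named score vectors over the same
#'   gene universe.
#' @param pathway the training `gene_set` (excluded from candidacy).
#' @param threshold high-score threshold; default 0.2.
#' @return Data frame (gene, combined_score, mutation_only_score,
#'   expression_only_score, threshold) sorted by combined score descending.
#' @export
select_silent_players <- function(combined, mut_only, expr_only, pathway,
                                  threshold = 0.2) {
  genes <- names(combined)
  if (!setequal(genes, names(mut_only)) || !setequal(genes, names(expr_only))) {
    ns_input_error("the three score vectors cover different gene universes")
  }
  mut_only <- mut_only[genes]
  expr_only <- expr_only[genes]
  keep <- !(genes %in% pathway$members) &
    combined >= threshold & mut_only < threshold & expr_only < threshold
  out <- data.frame(gene = genes[keep],
                    combined_score = unname(combined[keep]),
                    mutation_only_score = unname(mut_only[keep]),
                    expression_only_score = unname(expr_only[keep]),
                    threshold = rep(threshold, sum(keep)),
                    stringsAsFactors = FALSE)
  out[order(out$combined_score, decreasing = TRUE), , drop = FALSE]
}

#' Log-rank test of survival stratified by one gene's binary status
#'
#' Splits samples by the gene's 0/1 status (mutation or differential
#' expression), drops samples without clinical data, and runs the standard
#' two-group log-rank test (1 df, censoring respected). A split with an
#' empty group is reported as untestable rather than an error, since genes
#' with no mutations occur routinely.
#'
#' @param status named per-sample 0/1 vector (one column of M or D).
#' @param clinical data frame with columns sample, time, event.
#' @return List with `testable`, `chisq`, `p_value`, `n_group0`, `n_group1`.
#' @export
logrank_by_gene <- function(status, clinical) {
  common <- intersect(names(status), clinical$sample)
  cl <- clinical[match(common, clinical$sample), ]
  grp <- as.integer(status[common])
  n1 <- sum(grp == 1L); n0 <- sum(grp == 0L)
  if (n0 == 0L || n1 == 0L) {
    return(list(testable = FALSE, chisq = NA_real_, p_value = NA_real_,
                n_group0 = n0, n_group1 = n1))
  }
  sd <- survival::survdiff(survival::Surv(cl$time, cl$event) ~ grp)
  chisq <- unname(sd$chisq)
  list(testable = TRUE, chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n_group0 = n0, n_group1 = n1)
}

#' Survival screen of the top-scoring non-pathway genes
#'
#' For the `top_k` highest-scoring genes outside the training pathway, runs
#' two log-rank tests each: samples split by the gene's mutation status and
#' by its differential-expression status. Genes absent from a matrix are
#' marked untestable for that split.
#'
#' @param scores named per-gene scores.
#' @param pathway training `gene_set`.
#' @param M,D binary omic matrices.
#' @param clinical clinical table (sample, time, event).
#' @param top_k number of genes to screen; default 25.
#' @return Data frame with one row per screened gene: score, per-split
#'   chi-square and p-values (NA when untestable).
#' @export
survival_screen <- function(scores, pathway, M, D, clinical, top_k = 25L) {
  cand <- scores[!(names(scores) %in% pathway$members)]
  cand <- cand[order(cand, decreasing = TRUE)]
  top <- utils::head(cand, top_k)
  one <- function(g, A) {
    if (!g %in% colnames(A)) {
      return(list(testable = FALSE, chisq = NA_real_, p_value = NA_real_))
    }
    logrank_by_gene(stats::setNames(A[, g], rownames(A)), clinical)
  }
  rows <- lapply(names(top), function(g) {
    mres <- one(g, M); dres <- one(g, D)
    data.frame(gene = g, score = unname(top[g]),
               mutation_testable = mres$testable,
               mutation_chisq = mres$chisq, mutation_p = mres$p_value,
               expression_testable = dres$testable,
               expression_chisq = dres$chisq, expression_p = dres$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hypergeometric enrichment of high-scoring genes in an independent census
#'
#' Tests whether genes scoring at or above the threshold (outside the
#' training pathway) are enriched for membership in an independent cancer
#' gene census. The population is the scored gene universe minus the
#' pathway genes; census genes inside the pathway are likewise removed.
#'
#' @param scores named per-gene scores.
#' @param census independent `gene_set` (e.g. a cancer gene census).
#' @param pathway training `gene_set` to exclude.
#' @param threshold high-score threshold; default 0.2.
#' @return List with the hypergeometric parameters (`N`, `K`, `n`, `k`) and
#'   the upper-tail `p_value`.
#' @export
census_enrichment <- function(scores, census, pathway, threshold = 0.2) {
  universe <- setdiff(names(scores), pathway$members)
  census_u <- intersect(census$members, universe)
  high <- universe[scores[universe] >= threshold]
  k <- length(intersect(high, census_u))
  res <- list(N = length(universe), K = length(census_u), n = length(high), k = k)
  res$p_value <- if (res$n == 0L) 1 else
    hypergeometric_tail(res$N, res$K, res$n, res$k)
  res
}

#' AUC stability across the propagation parameter
#'
#' Runs the full pipeline (propagation, feature consolidation, logistic fit,
#' AIC step-down, ROC) once per value of `alpha` and reports the resulting
#' pathway-recovery AUC, as used to check that performance does not hinge
#' on the choice of the propagation parameter.
#'
#' @param net a `gene_network`.
#' @param M,D binary omic matrices.
#' @param pathway training `gene_set`.
#' @param alphas numeric vector in (0, 1); the reference grid is
#'   `c(0.01, 0.05, 0.1, 0.2, 0.5, 0.8, 0.9, 0.95, 0.99)`.
#' @param tol,max_iter propagation controls.
#' @return Data frame with columns `alpha`, `auc`, `n_features_retained`.
#' @export
alpha_sweep <- function(net, M, D, pathway,
                        alphas = c(0.01, 0.05, 0.1, 0.2, 0.5, 0.8, 0.9, 0.95, 0.99),
                        tol = 1e-6, max_iter = 1000L) {
  netN <- laplacian_normalize(net)
  gamma <- eigenvector_centrality(net)
  rows <- lapply(alphas, function(a) {
    MP <- propagate_matrix(netN, M, alpha = a, tol = tol, max_iter = max_iter)
    DP <- propagate_matrix(netN, D, alpha = a, tol = tol, max_iter = max_iter)
    ft <- suppressWarnings(compute_feature_table(M, D, MP, DP, gamma))
    y <- gene_labels(ft$gene, pathway)
    m <- suppressWarnings(step_down_aic(fit_logistic(ft, y), ft, y))
    auc <- roc_auc(predict_scores(m, ft), y)$auc
    data.frame(alpha = a, auc = auc, n_features_retained = length(m$features))
  })
  do.call(rbind, rows)
}
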