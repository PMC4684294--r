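# End-to-end workflow: propagation -> features -> models -> evaluation.

#' Run the full silent-player workflow
#'
#' Wires the modules together: aligns the omic matrices to the network,
#' Laplacian-normalizes it, propagates every sample's mutation and
#' differential-expression vector, consolidates the 13 per-gene features,
#' fits and AIC-steps three logistic models (combined, mutation-only,
#' expression-only), scores every network gene, and runs the downstream
#' evaluations (ROC, silent-player selection, optional census enrichment
#' and survival screen, optional alpha sweep).
#'
#' @param network a `gene_network`.
#' @param M,D binary omic matrices (samples x genes); sample sets must
#'   match.
#' @param pathway training `gene_set` of known disease genes.
#' @param census optional independent `gene_set` for enrichment.
#' @param clinical optional clinical table for the survival screen.
#' @param alpha propagation parameter; default 0.8.
#' @param tol,max_iter propagation controls (defaults 1e-6, 1000).
#' @param threshold high-score threshold for silent players; default 0.2.
#' @param top_k_survival genes screened for survival association; default 25.
#' @param alpha_grid optional vector of alphas for a stability sweep.
#' @return Object of class `netsilent_run`: list with `alignment`,
#'   `features`, `models` (combined/mutation_only/expression_only),
#'   `scores` (three score vectors), `evaluation` (model and univariate
#'   AUCs), `silent_players`, and — when inputs allow — `enrichment`,
#'   `survival`, `sweep`.
#' @export
run_pipeline <- function(network, M, D, pathway,
                         census = NULL, clinical = NULL,
                         alpha = 0.8, tol = 1e-6, max_iter = 1000L,
                         threshold = 0.2, top_k_survival = 25L,
                         alpha_grid = NULL) {
  if (!identical(rownames(M), rownames(D))) {
    ns_input_error("M and D must cover the same samples in the same order")
  }
  alignment <- list(mutation = align_to_network(M, network),
                    expression = align_to_network(D, network))

  netN <- laplacian_normalize(network)
  MP <- propagate_matrix(netN, M, alpha = alpha, tol = tol, max_iter = max_iter)
  DP <- propagate_matrix(netN, D, alpha = alpha, tol = tol, max_iter = max_iter)
  gamma <- eigenvector_centrality(network)
  features <- suppressWarnings(compute_feature_table(M, D, MP, DP, gamma))

  y <- gene_labels(features$gene, pathway)
  n_pathway_outside <- length(setdiff(pathway$members, features$gene))

  fit_set <- function(cols) {
    suppressWarnings(step_down_aic(fit_logistic(features, y, cols), features, y))
  }
  models <- list(combined = fit_set(feature_names()),
                 mutation_only = fit_set(mutation_feature_names()),
                 expression_only = fit_set(expression_feature_names()))
  scores <- lapply(models, function(m) predict_scores(m, features))

  # headline + univariate rankings (raw and propagated frequencies)
  uni <- c("mu_M", "mu_MP", "mu_D", "mu_DP")
  evaluation <- list(
    model_auc = vapply(scores, function(s) roc_auc(s, y)$auc, numeric(1)),
    univariate_auc = vapply(uni, function(f) {
      roc_auc(stats::setNames(features[[f]], features$gene), y)$auc
    }, numeric(1)),
    roc_combined = roc_auc(scores$combined, y)
  )

  silent <- select_silent_players(scores$combined, scores$mutation_only,
                                  scores$expression_only, pathway,
                                  threshold = threshold)

  out <- list(alignment = alignment, features = features, models = models,
              scores = scores, evaluation = evaluation,
              silent_players = silent,
              n_pathway_genes_outside_network = n_pathway_outside,
              alpha = alpha, threshold = threshold)

  if (!is.null(census)) {
    out$enrichment <- census_enrichment(scores$combined, census, pathway,
                                        threshold = threshold)
    out$evaluation$census_auc <- roc_auc(scores$combined,
                                         gene_labels(features$gene, census))$auc
  }
  if (!is.null(clinical)) {
    out$survival <- survival_screen(scores$combined, pathway, M, D, clinical,
                                    top_k = top_k_survival)
  }
  if (!is.null(alpha_grid)) {
    out$sweep <- alpha_sweep(network, M, D, pathway, alphas = alpha_grid,
                             tol = tol, max_iter = max_iter)
  }
  class(out) <- "netsilent_run"
  out
}

#' @export
print.netsilent_run <- function(x, ...) {
  cat("netsilent_run\n")
  cat(sprintf("  genes in network universe : %d\n", nrow(x$features)))
  cat(sprintf("  alpha = %g, silent-player threshold = %g\n", x$alpha, x$threshold))
  cat("  model AUC (pathway recovery):\n")
  for (nm in names(x$evaluation$model_auc)) {
    cat(sprintf("    %-16s %.4f  (%d features retained)\n", nm,
                x$evaluation$model_auc[[nm]], length(x$models[[nm]]$features)))
  }
  cat("  univariate AUC:\n")
  for (nm in names(x$evaluation$univariate_auc)) {
    cat(sprintf("    %-16s %.4f\n", nm, x$evaluation$univariate_auc[[nm]]))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  census enrichment: %d/%d high-scoring in census (K=%d, N=%d), p = %.3g\n",
                x$enrichment$k, x$enrichment$n, x$enrichment$K, x$enrichment$N,
                x$enrichment$p_value))
  }
  cat(sprintf("  silent players (score >= %g in combined model only): %d\n",
              x$threshold, nrow(x$silent_players)))
  if (nrow(x$silent_players)) {
    print(utils::head(x$silent_players, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Write the artifacts of a pipeline run to a directory
#'
#' Emits the feature table, the three serialized models, the three score
#' tables, the ROC points of the combined model, the silent-player table,
#' and — when computed — enrichment, survival and sweep tables, plus a
#' JSON run report.
#'
#' @param run a `netsilent_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(run$features, file.path(dir, "features.tsv"))
  for (nm in names(run$models)) {
    write_model(run$models[[nm]], file.path(dir, paste0("model_", nm, ".json")))
    write_scores(run$scores[[nm]], file.path(dir, paste0("scores_", nm, ".tsv")))
  }
  utils::write.table(run$evaluation$roc_combined$roc_points,
                     file.path(dir, "roc_combined.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$silent_players, file.path(dir, "silent_players.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$survival)) {
    utils::write.table(run$survival, file.path(dir, "survival_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$sweep)) {
    utils::write.table(run$sweep, file.path(dir, "alpha_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    alpha = run$alpha, threshold = run$threshold,
    alignment = run$alignment[c("mutation", "expression")],
    model_auc = as.list(run$evaluation$model_auc),
    univariate_auc = as.list(run$evaluation$univariate_auc),
    n_silent_players = nrow(run$silent_players),
    n_pathway_genes_outside_network = run$n_pathway_genes_outside_network,
    enrichment = run$enrichment
  )
  report$alignment <- lapply(report$alignment, function(a) a[c("n_data_only", "n_network_only", "n_shared")])
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
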