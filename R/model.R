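# Logistic scoring of candidate cancer genes.
#
# The model is standard (unpenalized) logistic regression of pathway
# membership on the per-gene features:
#     log(p / (1 - p)) = beta0 + beta1 x1 + ... + betan xn
# fitted by IRLS, followed by greedy backward elimination on AIC: at each
# round the term whose removal most lowers AIC is dropped, stopping when no
# removal improves AIC. The probabilistic output of the stepped-down model
# is the per-gene prediction score. Features enter on their raw scale (no
# standardization).

#' Label genes by membership in a gene set
#' @param genes character vector of genes (e.g. the feature-table genes).
#' @param positive_set a `gene_set` of positive (pathway) genes.
#' @return Named integer 0/1 vector over `genes`.
#' @export
gene_labels <- function(genes, positive_set) {
  stats::setNames(as.integer(genes %in% positive_set$members), genes)
}

#' Fit a logistic gene-scoring model
#'
#' Maximum-likelihood logistic regression of the labels on the selected
#' feature columns (IRLS via [stats::glm()], coefficient tolerance 1e-8,
#' at most 100 iterations, no penalty). Non-convergence or perfect
#' separation is flagged on the returned object rather than raised.
#'
#' @param X feature table (data frame with `gene` and feature columns).
#' @param y named 0/1 labels aligned with `X$gene` (see [gene_labels()]).
#' @param features character vector of feature columns to use; `character(0)`
#'   fits an intercept-only model. Default: all 13 features.
#' @return Object of class `logit_gene_model`: list with `features`, `beta`
#'   (intercept first; exactly collinear terms are aliased to `NA` and
#'   contribute nothing to prediction), `loglik`, `aic` (computed as
#'   `2k - 2 loglik` with `k` = declared coefficients including intercept,
#'   so redundant features are always penalized), `pvalues` (Wald),
#'   `converged`/`separation` flags and the fitted `glm` object.
#' @export
fit_logistic <- function(X, y, features = feature_names()) {
  if (!is.null(names(y))) y <- y[X$gene]
  y <- as.integer(y)
  if (length(y) != nrow(X) || anyNA(y)) {
    ns_input_error("labels must cover every feature-table gene")
  }
  if (length(unique(y)) < 2L) {
    ns_degenerate_error("labels are single-class: need at least one positive and one negative gene")
  }
  missing <- setdiff(features, names(X))
  if (length(missing)) {
    ns_input_error(sprintf("feature table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dat <- if (length(features)) X[features] else data.frame(row.names = seq_along(y))
  dat$.label <- y

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.label ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation || !fit$converged) {
    warning(sprintf("logistic fit [%s]: %s; coefficients taken at last IRLS iterate",
                    if (length(features)) paste(features, collapse = ",") else "intercept-only",
                    if (separation) "possible perfect separation" else "IRLS did not converge"),
            call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  beta <- stats::coef(fit)
  aliased <- names(beta)[is.na(beta)]  # exactly collinear terms dropped by IRLS
  if (length(aliased)) {
    warning(sprintf("feature(s) %s aliased (exact collinearity); coefficient treated as 0",
                    paste(aliased, collapse = ", ")), call. = FALSE)
  }
  loglik <- as.numeric(stats::logLik(fit))
  structure(list(
    features = features,
    beta = beta,
    aliased = aliased,
    loglik = loglik,
    # k counts every declared coefficient (incl. intercept and aliased
    # terms), so carrying a redundant feature always costs 2 AIC units
    aic = 2 * (length(features) + 1) - 2 * loglik,
    pvalues = stats::setNames(sm[, "Pr(>|z|)"], rownames(sm)),
    converged = fit$converged,
    separation = separation,
    fit = fit
  ), class = "logit_gene_model")
}

#' @export
print.logit_gene_model <- function(x, ...) {
  cat(sprintf("logit_gene_model: %d feature(s), logLik %.3f, AIC %.3f%s\n",
              length(x$features), x$loglik, x$aic,
              if (x$separation) " [separation flagged]" else ""))
  print(data.frame(estimate = x$beta, p_value = x$pvalues))
  invisible(x)
}

#' Greedy AIC step-down of a fitted model
#'
#' Backward elimination: refit with each single retained feature removed;
#' drop the feature whose removal yields the lowest AIC, provided that AIC
#' is strictly below the current model's; repeat until no removal improves
#' AIC. The intercept is never removed. Ties in AIC (difference below 1e-10)
#' are broken by removing the candidate occurring later in the canonical
#' feature order, making the procedure deterministic.
#'
#' @param model a `logit_gene_model` from [fit_logistic()].
#' @param X,y as in [fit_logistic()].
#' @return The final `logit_gene_model`, with attribute `trace`: a data
#'   frame of the removals (feature, AIC before and after each round).
#' @export
step_down_aic <- function(model, X, y) {
  current <- model
  trace <- data.frame(removed = character(0), aic_before = numeric(0),
                      aic_after = numeric(0), stringsAsFactors = FALSE)
  canon <- c(feature_names(), setdiff(current$features, feature_names()))
  repeat {
    feats <- current$features
    if (!length(feats)) break
    cand_aic <- vapply(feats, function(f) {
      fit_logistic(X, y, setdiff(feats, f))$aic
    }, numeric(1))
    best_aic <- min(cand_aic)
    if (!(best_aic < current$aic)) break
    tied <- feats[cand_aic <= best_aic + 1e-10]
    drop <- tied[which.max(match(tied, canon))]
    nxt <- fit_logistic(X, y, setdiff(feats, drop))
    trace <- rbind(trace, data.frame(removed = drop, aic_before = current$aic,
                                     aic_after = nxt$aic, stringsAsFactors = FALSE))
    current <- nxt
  }
  attr(current, "trace") <- trace
  current
}

#' Per-gene prediction scores from a fitted model
#'
#' Evaluates `plogis(beta0 + sum_i beta_i x_i)` for every gene of the
#' feature table.
#'
#' @param model a `logit_gene_model`.
#' @param X feature table containing all retained feature columns.
#' @return Named numeric vector of scores in (0, 1), indexed by gene.
#' @export
predict_scores <- function(model, X) {
  missing <- setdiff(model$features, names(X))
  if (length(missing)) {
    ns_input_error(sprintf("feature table lacks retained column(s): %s",
                           paste(missing, collapse = ", ")))
  }
  beta <- model$beta
  beta[is.na(beta)] <- 0  # aliased terms contribute nothing, as in predict.glm
  eta <- rep(beta[["(Intercept)"]], nrow(X))
  if (length(model$features)) {
    eta <- eta + as.matrix(X[model$features]) %*% beta[model$features]
  }
  stats::setNames(as.numeric(stats::plogis(eta)), X$gene)
}

#' Serialize a fitted model to a structured text (JSON) file
#' @param model a `logit_gene_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  trace <- attr(model, "trace")
  jsonlite::write_json(list(
    features = model$features,
    beta = as.list(model$beta),
    loglik = model$loglik,
    aic = model$aic,
    pvalues = as.list(model$pvalues),
    converged = model$converged,
    separation = model$separation,
    removal_trace = if (is.null(trace)) list() else trace
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' Restores coefficients and metadata for scoring; the underlying `glm`
#' object is not stored, so refitting diagnostics require [fit_logistic()].
#'
#' @param path path to the JSON file.
#' @return A `logit_gene_model` (without the `fit` element).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("model file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- structure(list(
    features = as.character(j$features),
    beta = unlist(j$beta),
    loglik = j$loglik,
    aic = j$aic,
    pvalues = unlist(j$pvalues),
    converged = isTRUE(j$converged),
    separation = isTRUE(j$separation),
    fit = NULL
  ), class = "logit_gene_model")
  attr(m, "trace") <- j$removal_trace
  m
}
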