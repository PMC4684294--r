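# Synthetic cohort generator.
#
# Emulates the structure the silent-player hypothesis assumes: a scale-free
# interaction network; a handful of planted causal genes that are NEVER
# mutated or differentially expressed themselves; per-sample binary
# mutation / DE signals concentrated in the network neighborhoods of the
# causal genes whose module is active in that sample; background noise
# everywhere else; and survival times whose hazard is raised in samples
# with an active causal module. It makes no attempt to imitate real
# mutation spectra or expression platforms; it provides the minimal
# structure under which co-proximity features carry signal.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 500-gene network with 200 samples, 10 planted causal genes,
#' preferential-attachment parameter 3, module activity probability 0.5,
#' neighborhood mutation/DE probabilities 0.4, background rates 0.02
#' (mutation) and 0.05 (DE), hazard ratio 3 for module-active samples on an
#' exponential baseline (rate 0.02 per month) with administrative censoring
#' at 60 months.
#'
#' @param n_genes,n_samples,n_causal cohort dimensions.
#' @param attach_m preferential-attachment edges per new node.
#' @param p_active per-sample probability that a causal gene's module is active.
#' @param p_mut_near,p_de_near per-sample probability that a neighbor of an
#'   active causal gene is mutated / differentially expressed.
#' @param q_mut,q_de background per-gene rates for non-causal genes.
#' @param min_causal_degree minimum interaction degree for a gene to be
#'   eligible as a planted causal gene. Causal genes emulate signaling
#'   mediators (kinases, phosphatases, transcription factors), which are
#'   well-connected in interaction networks; a module of several
#'   interactors is also what makes the per-sample conjunction of nearby
#'   mutation and DE signals average stably across samples. Default 5;
#'   must be at least 2 so proximity to both signal types is realizable.
#' @param hazard_ratio hazard multiplier when any causal module is active.
#' @param base_hazard exponential baseline hazard (events per month).
#' @param censor_time administrative censoring horizon (months).
#' @param seed integer seed; the whole cohort is byte-reproducible given
#'   the configuration.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 500L, n_samples = 200L, n_causal = 10L,
                       attach_m = 3L, p_active = 0.5,
                       p_mut_near = 0.4, p_de_near = 0.4,
                       q_mut = 0.02, q_de = 0.05, min_causal_degree = 5L,
                       hazard_ratio = 3, base_hazard = 0.02,
                       censor_time = 60, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_causal = as.integer(n_causal), attach_m = as.integer(attach_m),
              p_active = p_active, p_mut_near = p_mut_near, p_de_near = p_de_near,
              q_mut = q_mut, q_de = q_de,
              min_causal_degree = as.integer(min_causal_degree),
              hazard_ratio = hazard_ratio,
              base_hazard = base_hazard, censor_time = censor_time,
              seed = as.integer(seed))
  probs <- c(p_active = p_active, p_mut_near = p_mut_near,
             p_de_near = p_de_near, q_mut = q_mut, q_de = q_de)
  if (any(probs < 0 | probs > 1)) {
    ns_input_error("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_genes < 2L || cfg$n_samples < 1L || cfg$n_causal < 1L) {
    ns_input_error("counts must be positive (and n_genes >= 2)")
  }
  if (cfg$n_causal >= cfg$n_genes) ns_input_error("n_causal must be below n_genes")
  if (cfg$attach_m < 1L) ns_input_error("attach_m must be at least 1")
  if (cfg$min_causal_degree < 2L) {
    ns_input_error("min_causal_degree must be at least 2")
  }
  if (cfg$n_genes < cfg$attach_m + 1L) {
    ns_input_error("n_genes must be at least attach_m + 1")
  }
  if (hazard_ratio <= 0 || base_hazard <= 0 || censor_time <= 0) {
    ns_input_error("hazard_ratio, base_hazard and censor_time must be positive")
  }
  if (abs(cfg$seed) > .Machine$integer.max - 1L) ns_input_error("seed out of range")
  structure(cfg, class = "sim_config")
}

#' Generate a scale-free gene network
#'
#' Preferential attachment (linear, `attach_m` edges per incoming node,
#' undirected, no multi-edges), echoing the degree heterogeneity of protein
#' interaction networks; edge reliabilities drawn uniformly from (0.5, 1].
#' For `n` nodes the construction yields
#' `attach_m * (n - attach_m) + choose(attach_m, 2)`-ish edges; with the
#' standard single-seed growth used here, node `k` contributes
#' `min(k - 1, attach_m)` edges.
#'
#' @param config a `sim_config`.
#' @return A connected `gene_network` with nodes `G0001`, `G0002`, ...
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- igraph::sample_pa(config$n_genes, power = 1, m = config$attach_m,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  pad <- nchar(as.character(config$n_genes))
  nm <- sprintf(paste0("G%0", pad, "d"), seq_len(config$n_genes))
  gene_network(data.frame(gene_a = nm[el[, 1L]], gene_b = nm[el[, 2L]],
                          weight = 1 - 0.5 * stats::runif(nrow(el)),
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort with planted silent players
#'
#' Picks `n_causal` causal genes among nodes of interaction degree at least
#' `min_causal_degree` (see [sim_config()]). For each sample, each causal gene's
#' module is active with probability `p_active`; if active, every network
#' neighbor of that causal gene is mutated with probability `p_mut_near` and
#' differentially expressed with probability `p_de_near`, independently.
#' Every non-causal gene is additionally mutated / DE'd at the background
#' rates. Causal genes' own columns are forced to zero in both matrices —
#' they are silent by construction. Survival time is exponential with rate
#' `base_hazard * hazard_ratio^(any module active)`, administratively
#' censored at `censor_time`.
#'
#' @param config a `sim_config`.
#' @param network a `gene_network`, typically from [generate_network()].
#' @return Object of class `synthetic_cohort`: list with `network`, `M`,
#'   `D`, `causal` (a `gene_set`), `clinical`, `truth` (sample x causal
#'   activity matrix plus per-sample `any_active`), and `config`.
#' @export
generate_cohort <- function(config, network) {
  stopifnot(inherits(config, "sim_config"), inherits(network, "gene_network"))
  deg_count <- Matrix::rowSums(network$W != 0)
  eligible <- network$nodes[deg_count >= config$min_causal_degree]
  if (length(eligible) < config$n_causal) {
    ns_input_error(sprintf("only %d node(s) of degree >= %d; cannot plant %d causal genes",
                           length(eligible), config$min_causal_degree, config$n_causal))
  }
  set.seed(config$seed + 1L)
  causal <- sort(sample(eligible, config$n_causal), method = "radix")
  nbrs <- lapply(causal, function(g) setdiff(network$nodes[network$W[g, ] != 0], g))
  names(nbrs) <- causal

  genes <- network$nodes
  n <- config$n_samples
  samples <- sprintf(paste0("S%0", nchar(as.character(n)), "d"), seq_len(n))
  M <- D <- matrix(0L, nrow = n, ncol = length(genes),
                   dimnames = list(samples, genes))
  active <- matrix(stats::rbinom(n * config$n_causal, 1L, config$p_active) == 1L,
                   nrow = n, dimnames = list(samples, causal))
  for (i in seq_len(n)) {
    for (g in causal[active[i, ]]) {
      nb <- nbrs[[g]]
      M[i, nb] <- M[i, nb] | (stats::rbinom(length(nb), 1L, config$p_mut_near) == 1L)
      D[i, nb] <- D[i, nb] | (stats::rbinom(length(nb), 1L, config$p_de_near) == 1L)
    }
    noncausal <- setdiff(genes, causal)
    M[i, noncausal] <- M[i, noncausal] | (stats::rbinom(length(noncausal), 1L, config$q_mut) == 1L)
    D[i, noncausal] <- D[i, noncausal] | (stats::rbinom(length(noncausal), 1L, config$q_de) == 1L)
  }
  M[, causal] <- 0L  # planted genes are silent in both data types
  D[, causal] <- 0L
  storage.mode(M) <- "integer"
  storage.mode(D) <- "integer"

  any_active <- apply(active, 1L, any)
  rate <- config$base_hazard * config$hazard_ratio^as.numeric(any_active)
  t_raw <- stats::rexp(n, rate)
  clinical <- data.frame(sample = samples,
                         time = pmin(t_raw, config$censor_time),
                         event = as.integer(t_raw <= config$censor_time),
                         stringsAsFactors = FALSE)

  structure(list(network = network, M = M, D = D,
                 causal = gene_set(causal, name = "planted_causal"),
                 clinical = clinical,
                 truth = list(active = active, any_active = any_active),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d genes, %d planted causal genes, %d events\n",
              nrow(x$M), ncol(x$M), length(x$causal$members), sum(x$clinical$event)))
  invisible(x)
}

#' Emulate a curated disease pathway for a synthetic cohort
#'
#' Builds a training gene set the way curated pathways relate to a real
#' cohort: pathway membership is cohort-independent, so it covers only part
#' of the genes actually carrying signal and also lists genes not
#' implicated in this cohort. Concretely, takes a random fraction
#' (`coverage`) of the planted modules' neighbor genes — the genes that are
#' recurrently mutated or differentially expressed when a module is active
#' — and adds `n_background` genes unrelated to any module. The planted
#' causal genes themselves are never included, leaving them discoverable.
#' Training on such a noisy label set keeps the logistic fit away from
#' perfect separation, which is what lets combined-only high scorers
#' (silent players) emerge.
#'
#' @param cohort a `synthetic_cohort`.
#' @param coverage fraction of module-neighbor genes included; default 0.6.
#' @param n_background unrelated genes included; default 40.
#' @param seed RNG seed for the subsampling; defaults to the cohort seed
#'   plus 2 so it is reproducible but independent of the cohort draws.
#' @return A `gene_set` named `"synthetic_pathway"`.
#' @export
cohort_pathway <- function(cohort, coverage = 0.6, n_background = 40L,
                           seed = cohort$config$seed + 2L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (coverage <= 0 || coverage > 1) ns_input_error("coverage must be in (0, 1]")
  net <- cohort$network
  causal <- cohort$causal$members
  nbrs <- setdiff(unique(unlist(lapply(causal, function(g)
    net$nodes[net$W[g, ] != 0]))), causal)
  pool <- setdiff(net$nodes, c(nbrs, causal))
  n_background <- min(n_background, length(pool))
  set.seed(seed)
  gene_set(c(sample(nbrs, round(coverage * length(nbrs))),
             sample(pool, n_background)),
           name = "synthetic_pathway")
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Emits `network.tsv` (edge list), `mutations.tsv` and `expression.tsv`
#' (binary matrices), `causal_genes.txt` (the planted gene set),
#' `clinical.tsv` and `sim_config.json`, all readable through the package's
#' standard readers.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(cohort$network, file.path(dir, "network.tsv"))
  write_omic_matrix(cohort$M, file.path(dir, "mutations.tsv"))
  write_omic_matrix(cohort$D, file.path(dir, "expression.tsv"))
  write_gene_set(cohort$causal, file.path(dir, "causal_genes.txt"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulation configuration written by [write_cohort()]
#' @param path path to `sim_config.json`.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("config file not found: %s", path))
  do.call(sim_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
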