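# IO for binary omic matrices, gene sets, clinical tables and score tables,
# plus alignment of omic data to the network gene universe.
#
# Gene identity is the symbol string, case-sensitive; no alias mapping is
# attempted, so identifiers must be pre-harmonized across network and omic
# inputs.

#' Read a binary sample-by-gene matrix
#'
#' Expects a TSV with a header row of gene symbols, the sample identifier in
#' the first column, and a body of 0/1 entries (mutation status or
#' differential-expression status).
#'
#' @param path path to the TSV file.
#' @return Integer matrix with samples as rownames and genes as colnames;
#'   every entry is 0 or 1.
#' @export
read_binary_matrix <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("matrix file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) ns_input_error(sprintf("%s: no samples", path))
  if (ncol(df) < 2L) ns_input_error(sprintf("%s: no gene columns", path))
  samples <- as.character(df[[1L]])
  if (anyDuplicated(samples)) {
    ns_input_error(sprintf("%s: duplicate sample identifier '%s'",
                           path, samples[anyDuplicated(samples)]))
  }
  genes <- colnames(df)[-1L]
  if (anyDuplicated(genes)) {
    ns_input_error(sprintf("%s: duplicate gene column '%s'",
                           path, genes[anyDuplicated(genes)]))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    ns_input_error(sprintf("%s: entry for sample '%s', gene '%s' is not 0/1",
                           path, samples[i], genes[j]))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(samples, genes)
  m
}

#' Write a binary sample-by-gene matrix as TSV
#' @param m binary matrix with sample rownames and gene colnames.
#' @param path output path.
#' @param digits decimal places for non-integer matrices (used when writing
#'   propagated matrices; binary matrices are written as integers).
#' @return `path`, invisibly.
#' @export
write_omic_matrix <- function(m, path, digits = 6L) {
  vals <- if (is.integer(m) || all(m == as.integer(m))) {
    apply(m, 1L, function(r) paste(as.integer(r), collapse = "\t"))
  } else {
    apply(m, 1L, function(r) paste(sprintf(paste0("%.", digits, "f"), r), collapse = "\t"))
  }
  writeLines(c(paste(c("sample", colnames(m)), collapse = "\t"),
               paste(rownames(m), vals, sep = "\t")),
             path)
  invisible(path)
}

#' Read a real-valued sample-by-gene matrix (e.g. a propagated matrix)
#' @param path path to a TSV written by [write_omic_matrix()].
#' @return Numeric matrix with sample rownames and gene colnames.
#' @export
read_omic_matrix <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("matrix file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) ns_input_error(sprintf("%s: no samples", path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  dimnames(m) <- list(as.character(df[[1L]]), colnames(df)[-1L])
  m
}

#' Read a gene set (one symbol per line, `#` comments allowed)
#' @param path path to the file.
#' @param name optional set name; defaults to the file name.
#' @return An object of class `gene_set`: list with `name` and `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) ns_input_error(sprintf("gene-set file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) ns_input_error(sprintf("%s: empty gene set", path))
  gene_set(unique(lines), name = if (is.null(name)) basename(path) else name)
}

#' Construct a gene set
#' @param members character vector of gene symbols (deduplicated).
#' @param name set name.
#' @return A `gene_set` object.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- unique(as.character(members))
  if (!length(members)) ns_input_error("gene set must be non-empty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Write a gene set, one symbol per line
#' @param gs a `gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(gs$members, path)
  invisible(path)
}

#' Read a clinical table (columns: sample, time, event)
#'
#' @param path TSV with columns `sample`, `time` (non-negative follow-up
#'   time) and `event` (1 = death observed, 0 = censored).
#' @return Data frame with one validated row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("clinical file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df))) {
    ns_input_error(sprintf("%s: clinical table must have columns %s",
                           path, paste(need, collapse = ", ")))
  }
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    ns_input_error(sprintf("%s: duplicate sample '%s'", path,
                           df$sample[anyDuplicated(df$sample)]))
  }
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    ns_input_error(sprintf("%s: survival times must be non-negative", path))
  }
  if (!all(df$event %in% c(0, 1))) {
    ns_input_error(sprintf("%s: event flags must be 0 or 1", path))
  }
  df[need]
}

#' Write a clinical table as TSV
#' @param clinical data frame with columns sample, time, event.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical[c("sample", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-gene prediction scores (gene, score to 6 decimals)
#' @param scores named numeric vector of scores.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  writeLines(c("gene\tscore",
               sprintf("%s\t%.6f", names(scores), scores)),
             path)
  invisible(path)
}

#' Read per-gene prediction scores
#' @param path TSV with columns gene, score.
#' @return Named numeric vector.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) ns_input_error(sprintf("score file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$score), as.character(df$gene))
}

#' Report the overlap between an omic matrix and the network gene universe
#'
#' Computes how many genes of a binary omic matrix are covered by the
#' network: propagation priors are built from the intersection, so an empty
#' intersection would make propagation vacuous and is an error. Inputs are
#' not modified.
#'
#' @param A binary omic matrix (genes as colnames).
#' @param net a `gene_network`.
#' @return List with `n_data_only`, `n_network_only`, `n_shared`, and the
#'   `shared` gene symbols.
#' @export
align_to_network <- function(A, net) {
  genes <- colnames(A)
  shared <- intersect(genes, net$nodes)
  if (!length(shared)) {
    ns_input_error("no overlap between omic-matrix genes and network nodes; propagation would be vacuous")
  }
  list(n_data_only = length(setdiff(genes, net$nodes)),
       n_network_only = length(setdiff(net$nodes, genes)),
       n_shared = length(shared),
       shared = shared)
}
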