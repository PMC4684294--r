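# Gene/protein interaction network container and edge-list IO.

#' Construct a gene interaction network from an edge table
#'
#' Builds the weighted undirected network used throughout the package from a
#' three-column edge table. Self-loops are dropped, duplicate edges (in either
#' orientation) are collapsed by keeping the maximum weight, and nodes are
#' stored in a fixed lexicographic (C-locale) order so that all downstream
#' vectors and matrices align reproducibly.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `weight`.
#' @return An object of class `gene_network`: a list with elements
#'   `nodes` (ordered character vector), `W` (symmetric sparse weight matrix
#'   with zero diagonal, `dimnames = list(nodes, nodes)`), and `degree`
#'   (named vector of weighted degrees, the row sums of `W`).
#' @seealso [read_edge_list()], [laplacian_normalize()]
#' @export
gene_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("gene_a", "gene_b", "weight") %in% names(edges))) {
    ns_input_error("edges must be a data frame with columns gene_a, gene_b, weight")
  }
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w <= 0)) {
    bad <- which(!is.finite(w) | w <= 0)[1L]
    ns_input_error(sprintf("edge weight must be a positive number (edge %d: %s-%s has weight %s)",
                           bad, a[bad], b[bad], format(edges$weight[bad])))
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- w[keep]

  nodes <- sort(unique(c(as.character(edges$gene_a), as.character(edges$gene_b))),
                method = "radix")
  if (length(a)) {
    # canonical orientation, then max-weight collapse of duplicates
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    w <- vapply(split(w, key), max, numeric(1))
    pairs <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    i <- match(pairs[, 1L], nodes)
    j <- match(pairs[, 2L], nodes)
    W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
  } else {
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
  }
  structure(list(nodes = nodes, W = W,
                 degree = stats::setNames(Matrix::rowSums(W), nodes)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges, weights in [%s, %s]\n",
              length(x$nodes), n_edges(x),
              format(if (n_edges(x)) min(x$W@x) else NA),
              format(if (n_edges(x)) max(x$W@x) else NA)))
  invisible(x)
}

#' Number of (undirected) edges in a network
#' @param net a `gene_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  length(net$W@x) %/% 2L
}

#' Read a weighted edge list
#'
#' Reads a tab-separated edge list into a [gene_network()]. The `generic`
#' dialect expects columns `gene_a`, `gene_b`, `weight` (a header row is
#' detected and skipped if the third field is not numeric). The `hippie`
#' dialect reads the HIPPIE flat file layout: protein symbols in columns 1
#' and 3 (an optional `_HUMAN` suffix is stripped) and the interaction
#' confidence score in column 5.
#'
#' @param path path to the edge-list file.
#' @param dialect `"generic"` or `"hippie"`.
#' @return A `gene_network`. Self-loops are dropped; duplicate edges keep the
#'   maximum weight; weights must be strictly positive.
#' @export
read_edge_list <- function(path, dialect = c("generic", "hippie")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) ns_input_error(sprintf("edge-list file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) ns_input_error(sprintf("empty edge-list file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)

  min_cols <- if (dialect == "generic") 3L else 5L
  cols <- if (dialect == "generic") c(1L, 2L, 3L) else c(1L, 3L, 5L)

  start <- 1L
  first <- fields[[1L]]
  if (length(first) >= min_cols &&
      is.na(suppressWarnings(as.numeric(first[cols[3L]])))) {
    start <- 2L  # header row
  }
  if (start > length(fields)) ns_input_error(sprintf("no edges in file: %s", path))

  n <- length(fields)
  ga <- gb <- character(n - start + 1L)
  wt <- numeric(n - start + 1L)
  for (k in seq.int(start, n)) {
    f <- fields[[k]]
    if (length(f) < min_cols) {
      ns_input_error(sprintf("%s: malformed line %d (expected >= %d tab-separated fields, got %d)",
                             path, k, min_cols, length(f)))
    }
    w <- suppressWarnings(as.numeric(f[cols[3L]]))
    if (is.na(w)) {
      ns_input_error(sprintf("%s: line %d: weight '%s' is not numeric", path, k, f[cols[3L]]))
    }
    if (w <= 0) {
      ns_input_error(sprintf("%s: line %d: weight %s is not positive", path, k, format(w)))
    }
    i <- k - start + 1L
    ga[i] <- f[cols[1L]]
    gb[i] <- f[cols[2L]]
    wt[i] <- w
  }
  if (dialect == "hippie") {
    ga <- sub("_HUMAN$", "", ga)
    gb <- sub("_HUMAN$", "", gb)
  }
  gene_network(data.frame(gene_a = ga, gene_b = gb, weight = wt,
                          stringsAsFactors = FALSE))
}

#' Write a network as a tab-separated edge list
#'
#' One line per undirected edge, endpoints in lexicographic order, with a
#' `gene_a  gene_b  weight` header. Weights are written with full double
#' precision so a read back through [read_edge_list()] reproduces the network
#' exactly.
#'
#' @param net a `gene_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  tri <- Matrix::triu(net$W)
  s <- Matrix::summary(tri)
  out <- c("gene_a\tgene_b\tweight",
           if (nrow(s)) sprintf("%s\t%s\t%.17g", net$nodes[s$i], net$nodes[s$j], s$x))
  writeLines(out, path)
  invisible(path)
}

#' Laplacian-normalize a network
#'
#' Rescales the weight matrix as `W' = D^(-1/2) W D^(-1/2)` where `D` is the
#' diagonal matrix of weighted degrees, i.e. `w'(u,v) = w(u,v) /
#' sqrt(deg(u) deg(v))`. The spectrum of `W'` lies in `[-1, 1]`, so
#' `alpha * W'` is a contraction for any propagation parameter `alpha < 1`.
#' Rows and columns of degree-zero (isolated) nodes are identically zero.
#'
#' @param net a `gene_network`.
#' @return An object of class `normalized_network`: list with `nodes`,
#'   `Wprime` (symmetric sparse matrix), and `degree` (the raw weighted
#'   degrees of `net`).
#' @export
laplacian_normalize <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  d <- net$degree
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- Matrix::Diagonal(x = inv_sqrt)
  Wp <- S %*% net$W %*% S
  Wp <- methods::as(Wp, "CsparseMatrix")
  dimnames(Wp) <- list(net$nodes, net$nodes)
  structure(list(nodes = net$nodes, Wprime = Wp, degree = d),
            class = "normalized_network")
}
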