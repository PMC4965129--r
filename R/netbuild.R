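#' Gene network container
#'
#' A gene network is an ordered vector of unique gene labels plus a
#' symmetric matrix of edge weights in `[0, 1]`.  Standardized networks
#' carry a diagonal of 1, which implements self-voting in the
#' neighbor-voting predictor downstream.
#'
#' @param genes character vector of unique gene labels.
#' @param weights symmetric numeric matrix, `length(genes)` square,
#'   entries in `[0, 1]`.
#' @param kind `"weighted"` or `"binary"` (binary networks contain only 0
#'   and 1).
#' @return object of class `"gene_network"`.
#' @export
gene_network <- function(genes, weights, kind = c("weighted", "binary")) {
  kind <- match.arg(kind)
  genes <- as.character(genes)
  stopifnot(!anyDuplicated(genes), is.matrix(weights),
            nrow(weights) == length(genes), ncol(weights) == length(genes))
  if (!isSymmetric(unname(weights), tol = 1e-12)) {
    stop("gene network weights must be symmetric")
  }
  if (any(weights < 0) || any(weights > 1)) {
    stop("gene network weights must lie in [0, 1]")
  }
  if (kind == "binary" && !all(weights %in% c(0, 1))) {
    stop("binary gene network may contain only 0 and 1")
  }
  dimnames(weights) <- list(genes, genes)
  structure(list(genes = genes, weights = weights, kind = kind),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("gene_network (", x$kind, "): ", length(x$genes), " genes, ",
      nz, " non-zero edges\n", sep = "")
  invisible(x)
}

#' Rank-standardize a symmetric weight matrix
#'
#' Replaces each off-diagonal entry by its tied-average rank among the
#' upper-triangle entries, divided by the number of entries, yielding
#' weights in `(0, 1]`.  Any strictly monotone transform of the input
#' gives the same output.  The diagonal is set to 1.
#'
#' @param x symmetric numeric matrix or `"gene_network"`.
#' @param genes gene labels when `x` is a bare matrix (defaults to
#'   dimnames or `g1..gn`).
#' @return a weighted `"gene_network"`.
#' @export
rank_standardize <- function(x, genes = NULL) {
  if (inherits(x, "gene_network")) {
    genes <- x$genes
    x <- x$weights
  }
  if (is.null(genes)) {
    genes <- if (!is.null(rownames(x))) rownames(x) else
      paste0("g", seq_len(nrow(x)))
  }
  stopifnot(isSymmetric(unname(x), tol = 1e-8))
  ut <- upper.tri(x)
  v <- x[ut]
  w <- matrix(0, nrow(x), ncol(x))
  w[ut] <- rank(v, ties.method = "average") / length(v)
  w <- w + t(w)
  diag(w) <- 1
  gene_network(genes, w, kind = "weighted")
}

#' Sequence-similarity network from pairwise E-values
#'
#' Edge strength is `-log10(E-value)` (E-values capped below at `floor`),
#' then rank-standardized.  Pairs absent from the table are treated as no
#' similarity and rank tied at the bottom.
#'
#' @param evalue_table data frame with columns `gene_a`, `gene_b`,
#'   `e_value` (positive).
#' @param genes gene universe; defaults to genes appearing in the table.
#' @param floor smallest representable E-value before the log transform.
#' @return a weighted `"gene_network"`.
#' @export
build_blastp_network <- function(evalue_table, genes = NULL,
                                 floor = 1e-300) {
  stopifnot(all(c("gene_a", "gene_b", "e_value") %in% names(evalue_table)))
  if (any(evalue_table$e_value <= 0)) {
    stop("E-values must be positive; cap tiny values with `floor` instead")
  }
  if (is.null(genes)) {
    genes <- sort(unique(c(evalue_table$gene_a, evalue_table$gene_b)))
  }
  n <- length(genes)
  mat <- matrix(-Inf, n, n, dimnames = list(genes, genes))
  ia <- match(evalue_table$gene_a, genes)
  ib <- match(evalue_table$gene_b, genes)
  keep <- !is.na(ia) & !is.na(ib)
  val <- -log10(pmax(evalue_table$e_value[keep], floor))
  mat[cbind(ia[keep], ib[keep])] <- val
  mat[cbind(ib[keep], ia[keep])] <- val
  diag(mat) <- 0
  rank_standardize(mat, genes = genes)
}

#' Ligand-similarity network from SEA pair scores
#'
#' Binary mode keeps an edge where the E-value is at or below `threshold`
#' ("1e-5 or better", inclusive).  Weighted mode takes `-log10(E-value)`
#' and rank-standardizes.
#'
#' @param results data frame from [score_all_pairs()].
#' @param threshold E-value threshold for binary mode.
#' @param mode `"weighted"` or `"binary"`.
#' @param genes gene/target universe; defaults to targets in `results`.
#' @param floor E-value floor before the log transform (weighted mode).
#' @return a `"gene_network"`.
#' @export
build_lignet <- function(results, threshold = 1e-5,
                         mode = c("weighted", "binary"), genes = NULL,
                         floor = 1e-300) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0,
            all(c("target_a", "target_b", "e_value") %in% names(results)))
  if (is.null(genes)) {
    genes <- sort(unique(c(results$target_a, results$target_b)))
  }
  n <- length(genes)
  ia <- match(results$target_a, genes)
  ib <- match(results$target_b, genes)
  keep <- !is.na(ia) & !is.na(ib)
  if (mode == "binary") {
    mat <- matrix(0, n, n, dimnames = list(genes, genes))
    edge <- as.numeric(results$e_value[keep] <= threshold)
    mat[cbind(ia[keep], ib[keep])] <- edge
    mat[cbind(ib[keep], ia[keep])] <- edge
    diag(mat) <- 1
    gene_network(genes, mat, kind = "binary")
  } else {
    mat <- matrix(-Inf, n, n, dimnames = list(genes, genes))
    val <- -log10(pmax(results$e_value[keep], floor))
    mat[cbind(ia[keep], ib[keep])] <- val
    mat[cbind(ib[keep], ia[keep])] <- val
    diag(mat) <- 0
    rank_standardize(mat, genes = genes)
  }
}

#' Aggregate co-expression network
#'
#' Each experiment's gene-by-sample matrix yields a Spearman-correlation
#' network which is rank-standardized; the aggregate is the elementwise
#' sum of the per-experiment networks, rank-standardized again.  Genes
#' missing from an experiment contribute no information (zero correlation
#' in that experiment).  Genes with zero expression variance in an
#' experiment get zero correlation to all others there.
#'
#' @param experiments list of numeric matrices, genes as rows (rownames
#'   required), samples as columns.
#' @param genes gene universe; defaults to the union over experiments.
#' @param min_samples minimum samples per experiment (default 10, the
#'   inclusion floor for expression experiments); fewer than 3 is always
#'   an error.
#' @return a weighted `"gene_network"`.
#' @export
build_coexp_network <- function(experiments, genes = NULL,
                                min_samples = 10L) {
  stopifnot(length(experiments) >= 1L)
  min_samples <- max(3L, as.integer(min_samples))
  for (e in experiments) {
    stopifnot(is.matrix(e), !is.null(rownames(e)))
    if (ncol(e) < min_samples) {
      stop("expression experiment has ", ncol(e), " samples; at least ",
           min_samples, " required")
    }
  }
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(experiments, rownames))))
  }
  n <- length(genes)
  total <- matrix(0, n, n)
  for (e in experiments) {
    common <- intersect(genes, rownames(e))
    cc <- suppressWarnings(stats::cor(t(e[common, , drop = FALSE]),
                                      method = "spearman"))
    cc[!is.finite(cc)] <- 0
    full <- matrix(0, n, n, dimnames = list(genes, genes))
    full[common, common] <- cc
    diag(full) <- 0
    total <- total + rank_standardize(full, genes = genes)$weights
  }
  diag(total) <- 0
  rank_standardize(total, genes = genes)
}

#' Path-extended physical interaction network
#'
#' Direct interactions get weight 1; indirect pairs at unweighted
#' shortest-path length `L` with `2 <= L <= max_path` get weight `1/L`;
#' longer or disconnected pairs get 0.  Self-loops in the input are
#' ignored with a warning.
#'
#' @param edges data frame with columns `gene_a`, `gene_b` (binary
#'   undirected interactions).
#' @param max_path maximum path length contributing an edge (default 6,
#'   i.e. path length strictly less than 7).
#' @param genes gene universe; defaults to genes in the edge list.
#' @return a weighted `"gene_network"`.
#' @export
extend_ppi <- function(edges, max_path = 6L, genes = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) in interaction list ignored")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (is.null(genes)) {
    genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  }
  g <- igraph::graph_from_data_frame(edges[c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  d <- igraph::distances(g)[genes, genes]
  w <- ifelse(d >= 1 & d <= max_path, 1 / d, 0)
  diag(w) <- 1
  gene_network(genes, w, kind = "weighted")
}

#' Restrict networks to their common gene set
#'
#' Every network is restricted to the sorted intersection of all gene
#' sets, in the same order.
#'
#' @param networks list of `"gene_network"` objects (at least 2).
#' @return list of restricted `"gene_network"` objects.
#' @export
intersect_networks <- function(networks) {
  stopifnot(length(networks) >= 2L)
  common <- Reduce(intersect, lapply(networks, `[[`, "genes"))
  common <- sort(common)
  if (length(common) == 0L) stop("networks share no genes")
  lapply(networks, function(nw) {
    gene_network(common, nw$weights[common, common, drop = FALSE],
                 kind = nw$kind)
  })
}

#' Aggregate standardized networks
#'
#' Elementwise sum of the input weight matrices, rank-standardized.
#' Inputs must share an identical gene ordering (use
#' [intersect_networks()] first).
#'
#' @param networks list of `"gene_network"` objects over identical genes.
#' @return a weighted `"gene_network"`.
#' @export
aggregate_networks <- function(networks) {
  stopifnot(length(networks) >= 1L)
  genes <- networks[[1]]$genes
  for (nw in networks) {
    if (!identical(nw$genes, genes)) {
      stop("networks have mismatched gene sets; intersect first")
    }
  }
  total <- Reduce(`+`, lapply(networks, `[[`, "weights"))
  diag(total) <- 0
  rank_standardize(total, genes = genes)
}

#' Filter an annotated edge list by a predicate
#'
#' Thin helper for curation-style filters on interaction lists that carry
#' extra columns (throughput, method, ...).
#'
#' @param edges data frame of edges with metadata columns.
#' @param predicate function taking the data frame, returning a logical
#'   row mask.
#' @return the retained rows.
#' @export
filter_edges <- function(edges, predicate) {
  keep <- predicate(edges)
  stopifnot(is.logical(keep), length(keep) == nrow(edges))
  edges[keep & !is.na(keep), , drop = FALSE]
}
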