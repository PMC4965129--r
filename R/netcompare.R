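#' Unordered pair count
#'
#' Number of unordered gene pairs among `n` genes, `n (n - 1) / 2`.
#'
#' @param n universe size, `>= 2`.
#' @return integer-valued count.
#' @export
pair_count <- function(n) {
  stopifnot(n >= 2)
  n * (n - 1) / 2
}

#' Fraction of pairs expected within a subgroup at random
#'
#' The fraction of all unordered pairs that fall inside a subgroup of size
#' `k` out of `n`: `pair_count(k) / pair_count(n)`.
#'
#' @param k subgroup size (`2 <= k <= n`).
#' @param n universe size.
#' @return fraction in `(0, 1]`.
#' @export
expected_random_fraction <- function(k, n) {
  stopifnot(k >= 2, k <= n)
  pair_count(k) / pair_count(n)
}

#' Cross-network concordance curve
#'
#' For each threshold, among gene pairs whose weight in `net_x` is at or
#' above the threshold, the fraction that are edges in the binary network
#' `net_y`.  Thresholds selecting no pair are omitted.  At threshold 0 the
#' fraction equals the edge density of `net_y`.
#'
#' @param net_x a `"gene_network"` (typically weighted).
#' @param net_y a binary `"gene_network"` over the same genes.
#' @param grid numeric threshold grid.
#' @return data frame with columns `threshold`, `n_pairs`, `n_hits`,
#'   `fraction`.
#' @export
concordance_curve <- function(net_x, net_y,
                              grid = seq(0, 0.99, by = 0.01)) {
  stopifnot(identical(net_x$genes, net_y$genes))
  ut <- upper.tri(net_x$weights)
  wx <- net_x$weights[ut]
  ey <- net_y$weights[ut] > 0
  rows <- lapply(grid, function(th) {
    sel <- wx >= th
    if (!any(sel)) return(NULL)
    data.frame(threshold = th, n_pairs = sum(sel),
               n_hits = sum(ey[sel]), fraction = mean(ey[sel]))
  })
  do.call(rbind, rows)
}

#' Truth table between two binary networks
#'
#' Cross-tabulates every unordered gene pair by edge presence in the two
#' networks and tests independence by a 1-df chi-square without continuity
#' correction.  The test is marked undefined when a margin is degenerate
#' (an all-0 or all-1 network).
#'
#' @param net_x,net_y binary `"gene_network"` objects over the same genes.
#' @return object of class `"truth_table"`: list with `counts` (2x2
#'   matrix, rows = related in x, columns = related in y), `chi_square`,
#'   `p_value`.
#' @export
truth_table <- function(net_x, net_y) {
  stopifnot(identical(net_x$genes, net_y$genes))
  ut <- upper.tri(net_x$weights)
  ex <- factor(net_x$weights[ut] > 0, levels = c(TRUE, FALSE))
  ey <- factor(net_y$weights[ut] > 0, levels = c(TRUE, FALSE))
  counts <- table(x = ex, y = ey)
  counts <- matrix(as.numeric(counts), 2, 2,
                   dimnames = list(x = c("related", "unrelated"),
                                   y = c("related", "unrelated")))
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate) {
    chi <- NA_real_; p <- NA_real_
  } else {
    # small expected counts are routine for sparse pair tables; the
    # accuracy warning is not actionable here
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    chi <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(counts = counts, chi_square = chi, p_value = p),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  print(x$counts)
  if (is.finite(x$chi_square)) {
    cat(sprintf("chi-square = %.4g, p = %.3g\n", x$chi_square, x$p_value))
  } else {
    cat("chi-square test undefined (degenerate margin)\n")
  }
  invisible(x)
}

#' Keep the top fraction of edges
#'
#' Retains edges whose tied-average descending rank falls within the top
#' `fraction` of upper-triangle entries; ties straddling the cut are all
#' kept, so the realized density can slightly exceed `fraction`.  Kept
#' edges retain their weights, the rest become 0.
#'
#' @param net a `"gene_network"`.
#' @param fraction proportion of edges to keep, in `(0, 1)` (default
#'   0.01).
#' @return a `"gene_network"` of the same kind with most edges zeroed.
#' @export
sparsify_top <- function(net, fraction = 0.01) {
  stopifnot(inherits(net, "gene_network"), fraction > 0, fraction < 1)
  w <- net$weights
  ut <- upper.tri(w)
  v <- w[ut]
  n_keep <- max(1L, floor(fraction * length(v)))
  cutoff <- sort(v, decreasing = TRUE)[n_keep]
  keep <- v >= cutoff
  v[!keep] <- 0
  out <- matrix(0, nrow(w), ncol(w))
  out[ut] <- v
  out <- out + t(out)
  diag(out) <- diag(w)
  gene_network(net$genes, out, kind = net$kind)
}

#' Jaccard overlap of two genes' annotation sets
#'
#' `|terms(u) n terms(v)| / |terms(u) u terms(v)|`; 0 by convention when
#' both genes are unannotated.  Used as a simple semantic-similarity
#' measure.
#'
#' @param gene_u,gene_v gene labels present in `A`.
#' @param A an [annotation_matrix()].
#' @return coefficient in `[0, 1]`.
#' @export
jaccard_annotation_overlap <- function(gene_u, gene_v, A) {
  stopifnot(inherits(A, "annotation_matrix"),
            gene_u %in% A$genes, gene_v %in% A$genes)
  au <- A$values[gene_u, ]; av <- A$values[gene_v, ]
  un <- sum(au | av)
  if (un == 0L) return(0)
  sum(au & av) / un
}

# Jaccard overlap for many gene pairs at once (rows of idx are gene index
# pairs into A$genes)
jaccard_pairs <- function(idx, A) {
  V <- A$values * 1
  inter <- rowSums(V[idx[, 1], , drop = FALSE] * V[idx[, 2], , drop = FALSE])
  un <- rowSums((V[idx[, 1], , drop = FALSE] + V[idx[, 2], , drop = FALSE]) > 0)
  ifelse(un == 0, 0, inter / un)
}

#' Greedily prune low-overlap edges while preserving precision
#'
#' Edges of a sparse network are visited in ascending order of annotation
#' Jaccard overlap and removed one at a time (or in batches); after each
#' removal the cross-validated mean average precision is recomputed.  The
#' procedure stops at the last state whose MAP is still at or above
#' `target_map` (the dense network's MAP), restoring the final removal
#' that broke the target.
#'
#' @param net_sparse a sparse `"gene_network"` (see [sparsify_top()]).
#' @param A an [annotation_matrix()] aligned to the network.
#' @param target_map MAP level to preserve.
#' @param folds a [make_folds()] split of `A`.
#' @param batch number of edges removed between MAP recomputations
#'   (default 1).
#' @return list with `network` (the pruned `"gene_network"`), `audit`
#'   (data frame `step`, `gene_a`, `gene_b`, `overlap`, `map_after`) and
#'   `map` (final MAP).
#' @export
greedy_prune <- function(net_sparse, A, target_map, folds, batch = 1L) {
  stopifnot(inherits(net_sparse, "gene_network"),
            inherits(A, "annotation_matrix"), batch >= 1L)
  cv_map <- function(w) {
    nw <- gene_network(net_sparse$genes, w, kind = "weighted")
    # pruning inevitably isolates genes; the per-call warning from
    # neighbor voting would fire once per removal step
    summarize_scores(suppressWarnings(cross_validate(nw, A, folds)))$map
  }
  w <- net_sparse$weights
  ut_idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ov <- jaccard_pairs(ut_idx, A)
  start_map <- cv_map(w)
  if (start_map < target_map) {
    stop(sprintf(paste0("sparse network MAP (%.4f) is already below the ",
                        "target MAP (%.4f); nothing to prune"),
                 start_map, target_map))
  }
  ord <- order(ov)
  audit <- vector("list", length(ord))
  step <- 0L
  i <- 1L
  while (i <= length(ord)) {
    js <- ord[i:min(length(ord), i + batch - 1L)]
    prev <- w
    for (j in js) {
      w[ut_idx[j, 1], ut_idx[j, 2]] <- 0
      w[ut_idx[j, 2], ut_idx[j, 1]] <- 0
    }
    m <- cv_map(w)
    if (m < target_map) {
      w <- prev
      break
    }
    for (j in js) {
      step <- step + 1L
      audit[[step]] <- data.frame(
        step = step,
        gene_a = net_sparse$genes[ut_idx[j, 1]],
        gene_b = net_sparse$genes[ut_idx[j, 2]],
        overlap = ov[j], map_after = m,
        stringsAsFactors = FALSE)
    }
    i <- i + batch
  }
  audit <- if (step > 0L) do.call(rbind, audit[seq_len(step)]) else
    data.frame(step = integer(0), gene_a = character(0),
               gene_b = character(0), overlap = numeric(0),
               map_after = numeric(0))
  list(network = gene_network(net_sparse$genes, w, kind = "weighted"),
       audit = audit, map = cv_map(w))
}

#' Overlap-matched random null network
#'
#' Uniformly samples `n_edges` gene pairs whose annotation Jaccard overlap
#' is at least `min_overlap` (candidate pairs are all gene pairs, not only
#' edges of the input network) and returns them as a binary network.  A
#' null for the optimized networks of [greedy_prune()].
#'
#' @param net_sparse a `"gene_network"` supplying the gene universe.
#' @param A an [annotation_matrix()] aligned to the network.
#' @param n_edges number of pairs to sample.
#' @param min_overlap minimum Jaccard overlap of candidate pairs.
#' @param seed integer seed.
#' @return a binary `"gene_network"`.
#' @export
null_sample_matched <- function(net_sparse, A, n_edges, min_overlap, seed) {
  stopifnot(inherits(net_sparse, "gene_network"),
            inherits(A, "annotation_matrix"))
  n <- length(net_sparse$genes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ov <- jaccard_pairs(idx, A)
  cand <- which(ov >= min_overlap)
  if (length(cand) < n_edges) {
    stop("only ", length(cand), " candidate pairs at overlap >= ",
         min_overlap, "; cannot sample ", n_edges)
  }
  take <- if (length(cand) == n_edges) cand else
    with_local_seed(seed, sample(cand, n_edges))
  w <- matrix(0, n, n)
  w[idx[take, , drop = FALSE]] <- 1
  w <- w + t(w)
  diag(w) <- 1
  gene_network(net_sparse$genes, w, kind = "binary")
}

#' Write a pruning audit log
#'
#' TSV with columns `step`, `gene_a`, `gene_b`, `overlap`, `map_after`.
#'
#' @param audit audit data frame from [greedy_prune()].
#' @param path file path.
#' @export
write_prune_audit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
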