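# evaluate expr with a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomized cross-validation folds over annotation positives
#'
#' Assigns every positive (gene, term) cell to one of `n_folds` folds,
#' independently per term, with fold sizes balanced within one.
#'
#' @param A an [annotation_matrix()].
#' @param n_folds number of folds (default 3).
#' @param seed integer seed.
#' @return object of class `"fold_split"`: list with `seed`, `n_folds` and
#'   `assignment`, an integer genes-by-terms matrix (0 for negatives).
#' @export
make_folds <- function(A, n_folds = 3L, seed = 1L) {
  stopifnot(inherits(A, "annotation_matrix"), n_folds >= 2L)
  assignment <- matrix(0L, length(A$genes), length(A$terms),
                       dimnames = list(A$genes, A$terms))
  with_local_seed(seed, {
    for (j in seq_along(A$terms)) {
      pos <- which(A$values[, j])
      if (length(pos) == 0L) next
      folds <- rep_len(seq_len(n_folds), length(pos))
      assignment[sample(pos), j] <- folds
    }
  })
  structure(list(seed = seed, n_folds = as.integer(n_folds),
                 assignment = assignment),
            class = "fold_split")
}

#' Neighbor-voting predictor
#'
#' Scores each gene for each term by the degree-normalized weighted
#' fraction of its network neighbors (including itself, through the unit
#' diagonal) annotated to the term:
#' `P[i, j] = sum_k N[i, k] A[k, j] / sum_k N[i, k]`.
#'
#' @param N a `"gene_network"` (or symmetric matrix) with unit diagonal.
#' @param A_train logical genes-by-terms training annotation matrix (or an
#'   [annotation_matrix()]), gene order matching `N`.
#' @return numeric genes-by-terms prediction matrix with values in
#'   `[0, 1]`.
#' @export
neighbor_voting <- function(N, A_train) {
  W <- if (inherits(N, "gene_network")) N$weights else N
  A <- if (inherits(A_train, "annotation_matrix")) A_train$values else A_train
  stopifnot(nrow(W) == nrow(A))
  if (!is.null(rownames(W)) && !is.null(rownames(A)) &&
      !identical(rownames(W), rownames(A))) {
    stop("network and annotation gene orders differ")
  }
  deg <- rowSums(W)
  P <- W %*% A
  zero <- deg == 0
  if (any(zero)) {
    warning(sum(zero), " isolated gene(s) with zero degree scored 0")
    deg[zero] <- 1
    P[zero, ] <- 0
  }
  P / deg
}

#' Node-degree null predictor
#'
#' Ranks genes by their (weighted) node degree, identically for every
#' term; a generic predictor that measures how much apparent performance
#' is driven by hub genes.
#'
#' @param N a `"gene_network"` or symmetric matrix.
#' @return numeric vector of per-gene degrees.
#' @export
degree_null <- function(N) {
  W <- if (inherits(N, "gene_network")) N$weights else N
  rowSums(W)
}

#' Area under the ROC curve by rank comparison
#'
#' The probability that a withheld positive outscores an eligible
#' negative, ties counting one half: the Mann-Whitney U statistic divided
#' by `np * nn`.  Invariant to strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric per-gene scores (named or positional).
#' @param pos,neg disjoint index (or name) vectors of withheld positives
#'   and eligible negatives.
#' @return AUROC in `[0, 1]`, or `NA` if either side is empty.
#' @export
auroc <- function(scores, pos, neg) {
  sp <- scores[pos]; sn <- scores[neg]
  np <- length(sp); nn <- length(sn)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(c(sp, sn), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision of withheld positives
#'
#' Positives are ranked among the eligible genes (rank 1 = best score;
#' ties broken by a seeded shuffle of gene order so the statistic is
#' deterministic given the seed) and scored as
#' `AP = (1/k) * sum_i i / rank_i` over the `k` positives sorted by rank.
#' `1 / AP` approximates the expected number of tests to the first hit.
#'
#' @param scores numeric per-gene scores.
#' @param pos index (or name) vector of withheld positives.
#' @param eligible index vector of the evaluation pool (must contain
#'   `pos`; training positives are excluded by the caller).
#' @param tie_seed seed for the tie-breaking shuffle.
#' @return AP in `(0, 1]`, or `NA` if `pos` is empty.
#' @export
average_precision <- function(scores, pos, eligible, tie_seed = 1L) {
  if (length(pos) == 0L) return(NA_real_)
  stopifnot(all(pos %in% eligible))
  s <- scores[eligible]
  perm <- with_local_seed(tie_seed, sample.int(length(s)))
  r_perm <- rank(-s[perm], ties.method = "first")
  r <- integer(length(s))
  r[perm] <- r_perm
  pos_rank <- sort(r[match(pos, eligible)])
  mean(seq_along(pos_rank) / pos_rank)
}

#' Cross-validated per-term network evaluation
#'
#' For each fold, the fold's positives are hidden from the training
#' annotations, predictions are computed on the remaining positives, and
#' each term is scored by AUROC and average precision of the hidden
#' positives against genes never annotated to the term (training positives
#' are excluded from the evaluation pool).  Per-term scores are averaged
#' over folds.
#'
#' @param N a `"gene_network"`.
#' @param A an [annotation_matrix()] aligned to `N` (term-filtered).
#' @param folds a [make_folds()] split of `A`.
#' @param predictor `"neighbor_voting"` or `"degree_null"`.
#' @return data frame with one row per scored term: `term`, `branch`,
#'   `n_pos`, `n_neg`, `auroc`, `avg_precision`, `null_prior`,
#'   `ap_fold_change`, `n_folds_used`.
#' @export
cross_validate <- function(N, A, folds,
                           predictor = c("neighbor_voting", "degree_null")) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(N, "gene_network"), inherits(A, "annotation_matrix"),
            inherits(folds, "fold_split"))
  if (!identical(N$genes, A$genes)) {
    stop("network and annotation matrix gene orders differ; intersect first")
  }
  nf <- folds$n_folds
  nt <- length(A$terms)
  acc <- array(NA_real_, dim = c(nt, nf, 4),
               dimnames = list(A$terms, NULL,
                               c("auroc", "ap", "prior", "fc")))
  deg_scores <- degree_null(N)
  for (f in seq_len(nf)) {
    hidden_mask <- folds$assignment == f
    A_train <- A$values & !hidden_mask
    P <- if (predictor == "neighbor_voting") {
      neighbor_voting(N, A_train)
    } else {
      matrix(deg_scores, length(A$genes), nt)
    }
    for (j in seq_len(nt)) {
      hidden <- which(hidden_mask[, j])
      if (length(hidden) == 0L) next
      negs <- which(!A$values[, j])
      if (length(negs) == 0L) next
      eligible <- c(hidden, negs)
      acc[j, f, "auroc"] <- auroc(P[, j], hidden, negs)
      ap <- average_precision(P[, j], hidden, eligible,
                              tie_seed = folds$seed + f)
      prior <- length(hidden) / length(eligible)
      acc[j, f, "ap"] <- ap
      acc[j, f, "prior"] <- prior
      acc[j, f, "fc"] <- ap / prior
    }
  }
  slab <- function(stat) {
    matrix(acc[, , stat, drop = FALSE], nrow = nt, ncol = nf)
  }
  fold_mean <- function(x) {
    m <- rowMeans(x, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  out <- data.frame(term = A$terms,
                    branch = unname(A$branch),
                    n_pos = colSums(A$values),
                    n_neg = colSums(!A$values),
                    auroc = fold_mean(slab("auroc")),
                    avg_precision = fold_mean(slab("ap")),
                    null_prior = fold_mean(slab("prior")),
                    ap_fold_change = fold_mean(slab("fc")),
                    n_folds_used = rowSums(!is.na(slab("auroc"))),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!is.na(out$auroc), , drop = FALSE]
}

#' Summarize per-term scores
#'
#' @param scores data frame from [cross_validate()].
#' @return list with `mean_auroc`, `map` (mean average precision),
#'   `mean_ap_fold_change` (terms with zero prior excluded with a
#'   warning), `mean_null_prior` and `n_terms`.
#' @export
summarize_scores <- function(scores) {
  stopifnot(nrow(scores) > 0)
  fc <- scores$ap_fold_change
  bad <- !is.finite(fc)
  if (any(bad)) {
    warning(sum(bad), " term(s) with zero/undefined null prior excluded ",
            "from the fold-change mean")
  }
  list(mean_auroc = mean(scores$auroc, na.rm = TRUE),
       map = mean(scores$avg_precision, na.rm = TRUE),
       mean_ap_fold_change = mean(fc[!bad]),
       mean_null_prior = mean(scores$null_prior, na.rm = TRUE),
       n_terms = nrow(scores))
}

#' Gaussian kernel density of per-term scores
#'
#' Direct sum-of-kernels density with a Gaussian kernel and fixed
#' bandwidth, evaluated on a grid over `[0, 1]` (the density integrates to
#' 1 over the whole real line).
#'
#' @param scores numeric vector (e.g. per-term AUROCs), length >= 2.
#' @param bw kernel bandwidth (default 0.05).
#' @param grid evaluation grid.
#' @return data frame with columns `x` and `density`.
#' @export
auroc_density <- function(scores, bw = 0.05,
                          grid = seq(0, 1, length.out = 201)) {
  stopifnot(length(scores) >= 2)
  d <- vapply(grid, function(x) mean(stats::dnorm(x, scores, bw)),
              numeric(1))
  data.frame(x = grid, density = d)
}

#' Write a per-term score table
#'
#' TSV with the [cross_validate()] columns.
#'
#' @param scores data frame from [cross_validate()].
#' @param path file path.
#' @export
write_term_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
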