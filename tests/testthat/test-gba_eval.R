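toy_net <- function(w, genes = paste0("g", seq_len(nrow(w)))) {
  dimnames(w) <- list(genes, genes)
  gene_network(genes, w, kind = if (all(w %in% c(0, 1))) "binary"
               else "weighted")
}

test_that("neighbor voting scores are degree-normalized neighbor
           fractions", {
  N <- toy_net(matrix(c(1, 1, 0,
                        1, 1, 1,
                        0, 1, 1), 3, 3, byrow = TRUE))
  A <- matrix(c(TRUE, FALSE, FALSE), 3, 1,
              dimnames = list(N$genes, "t1"))
  P <- neighbor_voting(N, A)
  expect_equal(unname(P[, 1]), c(0.5, 1 / 3, 0))

  # all-gene term -> all scores 1; empty term -> all scores 0
  A2 <- cbind(t_all = rep(TRUE, 3), t_none = rep(FALSE, 3))
  rownames(A2) <- N$genes
  P2 <- neighbor_voting(N, A2)
  expect_equal(unname(P2[, "t_all"]), rep(1, 3))
  expect_equal(unname(P2[, "t_none"]), rep(0, 3))
})

test_that("neighbor voting matches brute-force loops on random instances", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:30, 1); t <- sample(2:10, 1)
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    A <- matrix(runif(n * t) < 0.3, n, t)
    expect_equal(unname(neighbor_voting(w, A)), bf_neighbor_voting(w, A))
  }
})

test_that("isolated genes score zero with a warning rather than failing", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  diag(w) <- c(1, 1, 0)  # gene 3 fully isolated
  A <- matrix(c(TRUE, TRUE, FALSE), 3, 1)
  expect_warning(P <- neighbor_voting(w, A), "isolated")
  expect_equal(P[3, 1], 0)
})

test_that("degree null is the row sum, constant across terms", {
  w <- matrix(c(1, 0.2, 0.7,
                0.2, 1, 0.1,
                0.7, 0.1, 1), 3, 3)
  expect_equal(degree_null(w), rowSums(w))
  # star graph: hub has highest score
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1; diag(star) <- 1
  expect_equal(which.max(degree_null(star)), 1L)
})

test_that("auroc equals brute-force pair counting and handles ties and
           monotone transforms", {
  expect_equal(auroc(c(5, 4, 1, 2), 1:2, 3:4), 1)
  expect_equal(auroc(c(1, 2, 5, 4), 1:2, 3:4), 0)
  expect_equal(auroc(rep(2, 6), 1:2, 3:6), 0.5)
  set.seed(17)
  for (rep in 1:50) {
    np <- sample(1:10, 1); nn <- sample(1:50, 1)
    scores <- sample(0:5, np + nn, replace = TRUE)  # many ties
    expect_equal(auroc(scores, seq_len(np), np + seq_len(nn)),
                 bf_auroc(scores, seq_len(np), np + seq_len(nn)))
  }
  s <- runif(30)
  expect_equal(auroc(s, 1:5, 6:30), auroc(exp(3 * s), 1:5, 6:30))
})

test_that("average precision follows the rank formula", {
  # positives at the top ranks
  expect_equal(average_precision(c(9, 8, 7, 1, 2), 1:3, 1:5), 1)
  # one positive at rank r
  expect_equal(average_precision(c(1, 9, 8, 7), 1, 1:4), 1 / 4)
  # two positives at ranks 1 and 3
  expect_equal(average_precision(c(9, 8, 7, 1), c(1, 3), 1:4),
               (1 / 1 + 2 / 3) / 2)
})

test_that("cross validation is deterministic and folds are balanced", {
  pl <- default_pipeline()
  expect_identical(make_folds(pl$A, 3, seed = 5)$assignment,
                   make_folds(pl$A, 3, seed = 5)$assignment)
  f <- make_folds(pl$A, 3, seed = 5)
  for (j in seq_along(pl$A$terms)) {
    counts <- tabulate(f$assignment[, j][f$assignment[, j] > 0], 3)
    expect_lte(diff(range(counts)), 1)
    expect_equal(sum(counts), sum(pl$A$values[, j]))
  }
  s1 <- cross_validate(pl$coexp, pl$A, f)
  s2 <- cross_validate(pl$coexp, pl$A, f)
  expect_identical(s1, s2)
})

test_that("summaries average per-term statistics with the documented
           null handling", {
  scores <- data.frame(term = c("t1", "t2"), branch = "BP",
                       n_pos = c(10, 20), n_neg = c(90, 80),
                       auroc = c(0.8, 0.6),
                       avg_precision = c(0.5, 0.25),
                       null_prior = c(0.1, 0.25),
                       ap_fold_change = c(5, 1),
                       n_folds_used = 3L)
  s <- summarize_scores(scores)
  expect_equal(s$mean_auroc, 0.7)
  expect_equal(s$map, 0.375)
  expect_equal(s$mean_ap_fold_change, 3)
  one <- summarize_scores(scores[1, ])
  expect_equal(one$map, 0.5)

  # AP equal to the prior for every term -> mean fold change 1
  flat <- scores
  flat$avg_precision <- flat$null_prior
  flat$ap_fold_change <- 1
  expect_equal(summarize_scores(flat)$mean_ap_fold_change, 1)
})

test_that("average precision of random scores matches the analytic null", {
  set.seed(23)
  n <- 200
  # one positive at a uniform random rank: AP = 1/rank, so E[AP] = H_n / n
  h_n <- sum(1 / seq_len(n))
  ap <- vapply(seq_len(4000), function(j) {
    average_precision(runif(n), sample(n, 1), seq_len(n), tie_seed = j)
  }, numeric(1))
  expect_lt(abs(mean(ap) - h_n / n), 0.01)
  # the null AP exceeds the prior 1/n, which is why fold changes compare
  # against the prior only as a coarse reference
  expect_gt(mean(ap), 1 / n)
})

test_that("per-term score density is a normalized Gaussian kernel sum", {
  d <- auroc_density(rep(0.7, 10))
  expect_equal(d$x[which.max(d$density)], 0.7, tolerance = 0.01)

  set.seed(2)
  scores <- runif(50, 0.3, 0.9)
  grid <- seq(-0.5, 1.5, length.out = 2001)
  d2 <- auroc_density(scores, grid = grid)
  integral <- sum(d2$density) * diff(grid)[1]
  expect_equal(integral, 1, tolerance = 1e-3)

  # matches a direct sum of kernels at arbitrary points
  pts <- seq(0.1, 0.9, length.out = 10)
  ref <- vapply(pts, function(x) mean(dnorm(x, scores, 0.05)), numeric(1))
  expect_equal(auroc_density(scores, grid = pts)$density, ref)
})

test_that("training positives are excluded from the evaluation pool", {
  # one term, 6 genes; network ranks training positives at the top, so a
  # pooled evaluation would deflate AUROC while exclusion keeps it exact
  genes <- paste0("g", 1:6)
  w <- matrix(0, 6, 6, dimnames = list(genes, genes))
  w[1, 2] <- w[2, 1] <- 1   # hidden positive g2 linked to training pos g1
  diag(w) <- 1
  nw <- gene_network(genes, w)
  values <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 6, 1,
                   dimnames = list(genes, "t1"))
  A <- annotation_matrix(genes, "t1", values)
  folds <- make_folds(A, 2, seed = 3)
  sc <- cross_validate(nw, A, folds)
  # in the fold hiding g2, its score 0.5 beats all negatives (0); in the
  # fold hiding g1, g1 scores 0.5 via g2; either way AUROC is 1
  expect_equal(sc$auroc, 1)
  expect_equal(sc$n_neg, 4)
})
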