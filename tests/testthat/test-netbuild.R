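sym_from_upper <- function(v, n, genes = paste0("g", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  m[upper.tri(m)] <- v
  m + t(m)
}

test_that("rank standardization divides tied-average ranks by the number
           of edges and fixes the diagonal at 1", {
  m <- sym_from_upper(c(5, 2, 9), 3)
  nw <- rank_standardize(m)
  expect_equal(nw$weights[upper.tri(nw$weights)], c(2 / 3, 1 / 3, 1))
  expect_equal(unname(diag(nw$weights)), rep(1, 3))

  # two tied maxima among 6 edges share the average of ranks 5 and 6
  m2 <- sym_from_upper(c(1, 2, 7, 7, 0, 0), 4)
  nw2 <- rank_standardize(m2)
  w2 <- nw2$weights[upper.tri(nw2$weights)]
  expect_equal(sort(w2, decreasing = TRUE)[1:2], c(5.5 / 6, 5.5 / 6))
})

test_that("rank standardization is invariant to monotone transforms and
           idempotent", {
  set.seed(4)
  m <- sym_from_upper(runif(45), 10)
  a <- rank_standardize(m)
  b <- rank_standardize(m ^ 2)
  expect_equal(a$weights, b$weights)
  expect_equal(rank_standardize(a)$weights, a$weights)
})

test_that("all-equal weights standardize without error", {
  m <- sym_from_upper(rep(3, 6), 4)
  nw <- rank_standardize(m)
  expect_true(all(nw$weights[upper.tri(nw$weights)] ==
                    nw$weights[2, 1]))
})

test_that("blastp network ranks -log10 E-values with missing pairs tied at
           the bottom", {
  tab <- data.frame(gene_a = c("a", "a", "b"),
                    gene_b = c("b", "c", "c"),
                    e_value = c(1e-10, 1e-5, 1e-2))
  nw <- build_blastp_network(tab, genes = c("a", "b", "c", "d"))
  # hand ranking: ab > ac > bc > (ad, bd, cd tied at bottom)
  expect_equal(nw$weights["a", "b"], 6 / 6)
  expect_equal(nw$weights["a", "c"], 5 / 6)
  expect_equal(nw$weights["b", "c"], 4 / 6)
  expect_equal(unname(nw$weights["a", "d"]), 2 / 6)  # mean rank of 1,2,3
  expect_gt(nw$weights["a", "b"], nw$weights["a", "c"])
  expect_error(build_blastp_network(data.frame(gene_a = "a", gene_b = "b",
                                               e_value = 0)),
               "positive")
})

test_that("binary ligand network applies an inclusive E-value threshold", {
  res <- data.frame(target_a = c("a", "a", "b"),
                    target_b = c("b", "c", "c"),
                    e_value = c(1e-6, 1e-5, 1e-4))
  nw <- build_lignet(res, threshold = 1e-5, mode = "binary")
  expect_equal(nw$weights["a", "b"], 1)  # better than threshold
  expect_equal(nw$weights["a", "c"], 1)  # exactly at threshold: included
  expect_equal(nw$weights["b", "c"], 0)  # worse
  expect_equal(nw$kind, "binary")

  wn <- build_lignet(res, mode = "weighted")
  expect_gt(wn$weights["a", "b"], wn$weights["a", "c"])
})

test_that("co-expression aggregation is rank-invariant under duplication
           and recovers planted modules", {
  set.seed(8)
  genes <- sprintf("g%02d", 1:40)
  module <- rep(1:2, each = 20)
  latent <- matrix(rnorm(2 * 50), 2, 50)
  x <- latent[module, ] + 0.5 * matrix(rnorm(40 * 50), 40, 50)
  rownames(x) <- genes

  one <- build_coexp_network(list(x))
  two <- build_coexp_network(list(x, x))
  expect_equal(one$weights, two$weights)

  ut <- upper.tri(one$weights)
  same <- outer(module, module, "==")[ut]
  expect_gt(mean(one$weights[ut][same]), mean(one$weights[ut][!same]))

  expect_error(build_coexp_network(list(x[, 1:2])), "samples")
})

test_that("path-extended interaction network weights by inverse minimum
           path length up to six steps", {
  # 8-node path graph
  genes <- letters[1:8]
  edges <- data.frame(gene_a = genes[1:7], gene_b = genes[2:8])
  nw <- extend_ppi(edges)
  expect_equal(nw$weights["a", "b"], 1)       # direct edge
  expect_equal(nw$weights["a", "c"], 0.5)     # two steps
  expect_equal(nw$weights["a", "g"], 1 / 6)   # six steps
  expect_equal(nw$weights["a", "h"], 0)       # seven steps: excluded
  expect_warning(extend_ppi(data.frame(gene_a = c("a", "a"),
                                       gene_b = c("a", "b"))),
                 "self-loop")
})

test_that("path extension matches a brute-force BFS oracle on random
           graphs", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    genes <- sprintf("n%02d", 1:n)
    adj <- matrix(0, n, n)
    ij <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(ij)) < 0.06
    adj[ij[on, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    edges <- data.frame(gene_a = genes[el[, 1]], gene_b = genes[el[, 2]])
    nw <- extend_ppi(edges, genes = genes)
    expect_equal(unname(nw$weights), bf_extend_ppi(adj))
  }
})

test_that("network intersection restricts to the sorted common gene set", {
  n1 <- rank_standardize(sym_from_upper(1:3, 3, genes = c("a", "b", "c")))
  n2 <- rank_standardize(sym_from_upper(1:3, 3, genes = c("b", "c", "d")))
  out <- intersect_networks(list(n1, n2))
  expect_identical(out[[1]]$genes, c("b", "c"))
  expect_identical(out[[2]]$genes, c("b", "c"))
  expect_true(isSymmetric(out[[1]]$weights))
  expect_error(intersect_networks(list(n1,
    rank_standardize(sym_from_upper(1, 2, genes = c("x", "y"))))),
    "share no genes")
})

test_that("aggregation is order-invariant and self-aggregation is a
           fixed point", {
  set.seed(9)
  a <- rank_standardize(sym_from_upper(runif(45), 10))
  b <- rank_standardize(sym_from_upper(runif(45), 10))
  expect_equal(aggregate_networks(list(a, a))$weights, a$weights)
  expect_equal(aggregate_networks(list(a, b))$weights,
               aggregate_networks(list(b, a))$weights)
  c_other <- rank_standardize(sym_from_upper(runif(3), 3,
                                             genes = c("x", "y", "z")))
  expect_error(aggregate_networks(list(a, c_other)), "mismatched")
})

test_that("constructed networks satisfy the container invariants", {
  pl <- default_pipeline()
  for (nw in list(pl$lignet, pl$coexp, pl$extppi, pl$aggregate)) {
    expect_true(isSymmetric(unname(nw$weights)))
    expect_true(all(nw$weights >= 0 & nw$weights <= 1))
    expect_equal(unname(diag(nw$weights)), rep(1, length(nw$genes)))
    expect_false(anyDuplicated(nw$genes) > 0)
  }
})
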