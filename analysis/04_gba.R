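#!/usr/bin/env Rscript
# Stage 4: guilt-by-association evaluation.
#
# Cross-validated neighbor voting of the planted function terms on each
# network, with the degree null alongside, writing per-term score tables
# and a one-line summary per network.

suppressPackageStartupMessages(library(seagba))

config <- read_run_config(file.path("results", "run_config.json"))
out <- file.path("results", "gba")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

net_genes <- read_network_tsv(
  file.path("results", "networks", "lignet.tsv"))$genes
A <- filter_terms(
  annotation_from_triplets(
    read_annotation_tsv(file.path("results", "data", "annotations.tsv")),
    genes = net_genes),
  min_genes = config$term_min_genes, max_genes = config$term_max_genes)
cat("evaluating", length(A$terms), "terms over", length(A$genes), "genes\n")

folds <- make_folds(A, config$n_folds, seed = config$seed + 7L)

net_dir <- file.path("results", "networks")
summary_rows <- list()
for (nm in c("lignet", "coexp", "extppi", "aggregate")) {
  nw <- read_network_tsv(file.path(net_dir, paste0(nm, ".tsv")))
  for (pred in c("neighbor_voting", "degree_null")) {
    sc <- cross_validate(nw, A, folds, predictor = pred)
    write_term_scores(sc, file.path(out, sprintf("%s_%s.tsv", nm, pred)))
    s <- summarize_scores(sc)
    summary_rows[[paste(nm, pred)]] <-
      data.frame(network = nm, predictor = pred, n_terms = s$n_terms,
                 mean_auroc = s$mean_auroc, map = s$map,
                 mean_ap_fold_change = s$mean_ap_fold_change)
    cat(sprintf("%-9s %-16s AUROC %.3f  MAP %.3f\n",
                nm, pred, s$mean_auroc, s$map))
  }
}
summary <- do.call(rbind, summary_rows)
write.table(summary, file.path(out, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
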