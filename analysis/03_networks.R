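#!/usr/bin/env Rscript
# Stage 3: build the gene networks.
#
# One network per evidence modality -- ligand-set similarity, aggregated
# co-expression, path-extended physical interactions -- each rank-
# standardized to [0, 1], plus their aggregate.

suppressPackageStartupMessages(library(seagba))

config <- read_run_config(file.path("results", "run_config.json"))
data_dir <- file.path("results", "data")
out <- file.path("results", "networks")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- sort(names(read_ligand_tsv(file.path(data_dir, "ligands.tsv"))))

sea <- read_sea_results(file.path("results", "sea", "pair_scores.tsv"))
lignet <- build_lignet(sea, threshold = config$e_value_threshold,
                       mode = "weighted", genes = genes)

expr_files <- list.files(data_dir, pattern = "^expr_", full.names = TRUE)
coexp <- build_coexp_network(lapply(expr_files, read_expression_tsv),
                             genes = genes)

extppi <- extend_ppi(read_edge_tsv(file.path(data_dir, "ppi_edges.tsv")),
                     max_path = config$max_path, genes = genes)

aggregate <- aggregate_networks(list(lignet, coexp, extppi))

for (nm in c("lignet", "coexp", "extppi", "aggregate")) {
  write_network_tsv(get(nm), file.path(out, paste0(nm, ".tsv")))
  nw <- get(nm)
  dens <- mean(nw$weights[upper.tri(nw$weights)] > 0)
  cat(sprintf("%-9s density %.3f\n", nm, dens))
}
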