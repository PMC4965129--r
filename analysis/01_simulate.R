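#!/usr/bin/env Rscript
# Stage 1: simulate the study world.
#
# Builds the synthetic gene universe -- chemotype families, co-expression
# modules, interaction blocks, and planted function terms -- and writes
# every dataset in the same text formats the downstream readers consume,
# so the rest of the workflow never touches in-memory objects from this
# stage.

suppressPackageStartupMessages(library(seagba))

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

config <- list(seed = 42L, tc_cutoff = 0.28, e_value_threshold = 1e-5,
               max_path = 6L, n_folds = 3L,
               term_min_genes = 20L, term_max_genes = 1000L)
write_run_config(config, file.path("results", "run_config.json"))

world <- make_world(world_params(), seed = config$seed)
cat("world:", length(world$genes), "genes,", length(world$terms),
    "planted terms\n")

sets <- make_ligands(world)
write_ligand_tsv(sets, file.path(out, "ligands.tsv"))

expr <- make_expression(world)
for (i in seq_along(expr)) {
  write_expression_tsv(expr[[i]], file.path(out, sprintf("expr_%02d.tsv", i)))
}

write_edge_tsv(make_ppi(world), file.path(out, "ppi_edges.tsv"))

ann <- make_annotations(world)
write_annotation_triplets(ann$annotations, file.path(out, "annotations.tsv"))
write.table(ann$truth, file.path(out, "term_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote ligands, ", length(expr), " expression experiments, ",
    "interactions and annotations under ", out, "\n", sep = "")
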