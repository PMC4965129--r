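#!/usr/bin/env Rscript
# Stage 2: ligand-set similarity scoring.
#
# Calibrates raw ligand-set scores against random same-size sets drawn
# from the pooled ligand universe (power-law mean and spread, extreme-
# value tail), then scores every pair of targets and writes the scored
# pairs plus the fitted background model.

suppressPackageStartupMessages(library(seagba))

config <- read_run_config(file.path("results", "run_config.json"))
data_dir <- file.path("results", "data")
out <- file.path("results", "sea")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sets <- read_ligand_tsv(file.path(data_dir, "ligands.tsv"))
sets <- lapply(sets, function(s) {
  s$ligands <- filter_ligands(s$ligands)
  s
})
universe <- do.call(rbind, lapply(sets, function(s) s$ligands))
cat("universe:", nrow(universe), "ligands over", length(sets), "targets\n")

sizes <- c(5L, 6L, 8L, 10L, 12L, 14L, 17L, 20L)
grid <- expand.grid(a = sizes, b = sizes)
grid <- as.matrix(grid[grid$a <= grid$b, ])
bg <- sample_background(universe, grid, n_samples = 50,
                        seed = config$seed + 101L,
                        tc_cutoff = config$tc_cutoff)
model <- fit_background(bg)
print(model)
write_background_model(model, file.path(out, "background_model.json"))

sea <- score_all_pairs(sets, model)
write_sea_results(sea, file.path(out, "pair_scores.tsv"))
cat("scored", nrow(sea), "target pairs;",
    sum(sea$e_value <= config$e_value_threshold),
    "at E <=", config$e_value_threshold, "\n")
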