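# Shared synthetic-study fixtures, built lazily once per test run.
# Seed 42 and the default world parameters are the study conditions for
# the full-pipeline checks.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

background_size_grid <- function() {
  sizes <- c(5L, 6L, 8L, 10L, 12L, 14L, 17L, 20L)
  grid <- expand.grid(a = sizes, b = sizes)
  as.matrix(grid[grid$a <= grid$b, ])
}

build_pipeline <- function(params = world_params(), seed = 42L) {
  world <- make_world(params, seed)
  sets <- make_ligands(world)
  universe <- do.call(rbind, lapply(sets, function(s) s$ligands))
  bg <- sample_background(universe, background_size_grid(),
                          n_samples = 50, seed = seed + 101L)
  model <- fit_background(bg)
  sea <- score_all_pairs(sets, model)
  lignet <- build_lignet(sea, mode = "weighted", genes = world$genes)
  coexp <- build_coexp_network(make_expression(world), genes = world$genes)
  extppi <- extend_ppi(make_ppi(world), genes = world$genes)
  ann <- make_annotations(world)
  A <- filter_terms(ann$annotations)
  folds <- make_folds(A, 3L, seed = seed + 7L)
  list(world = world, sets = sets, background = bg, model = model,
       sea = sea, lignet = lignet, coexp = coexp, extppi = extppi,
       aggregate = aggregate_networks(list(lignet, coexp, extppi)),
       truth = ann$truth, A = A, folds = folds)
}

default_pipeline <- function() {
  cached("default_pipeline", function() build_pipeline())
}

# pooled ligands of a small synthetic world: the chemotype families give
# random sets a non-degenerate chance of cross-pairs above the cutoff, as
# in a real compound collection
make_structured_universe <- function() {
  cached("structured_universe", function() {
    w <- make_world(world_params(n_genes = 60L, n_terms = 12L,
                                 term_size = c(8L, 10L)), seed = 5)
    sets <- make_ligands(w)
    do.call(rbind, lapply(sets, function(s) s$ligands))
  })
}

# many planted terms over one world, for permutation-null calibration
manyterm_pipeline <- function() {
  cached("manyterm", function() {
    params <- world_params(n_terms = 210L)
    world <- make_world(params, seed = 43L)
    coexp <- build_coexp_network(make_expression(world),
                                 genes = world$genes)
    ann <- make_annotations(world)
    A <- filter_terms(ann$annotations)
    list(world = world, coexp = coexp, A = A,
         folds = make_folds(A, 3L, seed = 50L))
  })
}

# hub-boosted interaction world for the degree-bias checks
hub_pipeline <- function() {
  cached("hub", function() {
    params <- world_params(n_terms = 60L, n_hubs = 40L,
                           hub_term_fraction = 0.25)
    world <- make_world(params, seed = 44L)
    extppi <- extend_ppi(make_ppi(world), genes = world$genes)
    ann <- make_annotations(world)
    A <- filter_terms(ann$annotations)
    list(world = world, extppi = extppi, truth = ann$truth, A = A,
         folds = make_folds(A, 3L, seed = 51L))
  })
}

# clique-signal world for sparsification / pruning checks.  Precision is
# carried by three planted cliques of tightly linked, heavily co-annotated
# core genes; a weak within-term nudge on top of heavy noise gives the
# dense network broad ranking signal (decent AUROC) whose per-gene
# precision is poor, so the dense MAP is low and carried by the cores.
clique_pipeline <- function() {
  cached("clique", function() {
    n <- 600L
    clique_size <- 8L
    n_periph <- 40L
    genes <- sprintf("g%03d", seq_len(n))
    cliques <- lapply(0:2, function(k) genes[k * clique_size + 1:clique_size])
    # three terms per clique: the clique cores plus peripheral genes
    terms <- with_local_seed(98L, {
      out <- list()
      for (k in 1:3) {
        for (r in 1:3) {
          periph <- sample(genes[-(1:(3L * clique_size))], n_periph)
          out[[length(out) + 1L]] <- c(cliques[[k]], periph)
        }
      }
      out
    })
    w <- with_local_seed(97L, {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- stats::runif(sum(upper.tri(m)), 0, 0.75)
      # weak broad signal: within-term pairs nudged up slightly
      for (tg in terms) {
        ti <- match(tg, genes)
        m[ti, ti] <- m[ti, ti] + 0.03
      }
      for (cl in cliques) {
        ci <- match(cl, genes)
        m[ci, ci] <- 0.95 + matrix(stats::runif(clique_size^2, 0, 0.05),
                                   clique_size)
      }
      m[lower.tri(m)] <- 0
      m <- m + t(m)
      diag(m) <- 0
      pmin(m, 1)
    })
    dense <- rank_standardize(w, genes = genes)
    values <- matrix(FALSE, n, length(terms),
                     dimnames = list(genes,
                                     sprintf("ct%02d", seq_along(terms))))
    for (j in seq_along(terms)) values[terms[[j]], j] <- TRUE
    A <- annotation_matrix(genes, colnames(values), values)
    folds <- make_folds(A, 3L, seed = 52L)
    list(genes = genes, cliques = cliques, dense = dense, A = A,
         folds = folds)
  })
}
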