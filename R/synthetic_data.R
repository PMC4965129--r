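#' Default parameters for a synthetic world
#'
#' A synthetic world emulates the statistical structure of the real data
#' modalities: chemotype families drive ligand-set similarity,
#' co-expression modules drive correlated expression, interaction blocks
#' drive a stochastic-block PPI graph, and planted functional terms align
#' with exactly one modality (or jointly with two), so the modalities
#' carry complementary information by construction.
#'
#' @param n_genes number of genes/targets (>= 50).
#' @param n_families,n_modules,n_blocks number of chemotype families,
#'   co-expression modules and PPI blocks (each >= 3); assignments are
#'   drawn independently of one another.
#' @param n_terms number of planted functional terms.
#' @param term_size inclusive range of planted term sizes.
#' @param modality_fractions fractions of terms encoded only chemically,
#'   only by co-expression, only by PPI, or jointly (chemistry +
#'   co-expression); must sum to 1.
#' @param label_noise fraction of each term's members swapped for random
#'   genes when annotations are materialized.
#' @param n_bits fingerprint length (feature universe size).
#' @param prototype_bits set bits in each family prototype fingerprint.
#' @param bit_flip per-bit perturbation rate applied to the prototype for
#'   each ligand.
#' @param set_size inclusive range of per-target ligand-set sizes (floor 5
#'   honours the target inclusion rule).
#' @param n_experiments,n_samples,noise_sd expression defaults: number of
#'   experiments, samples per experiment (>= 10) and Gaussian noise SD
#'   around the module latent factor.
#' @param p_within,p_between PPI edge probabilities inside / between
#'   blocks.
#' @param n_hubs number of hub genes with boosted degree (0 disables).
#' @param p_hub edge probability from a hub to any other gene.
#' @param hub_term_fraction fraction of terms planted on hub genes (only
#'   meaningful when `n_hubs > 0`; carved out of the PPI fraction).
#' @param evidence_proportions sampling weights of evidence tags assigned
#'   to positives.
#' @return named list of parameters.
#' @export
world_params <- function(n_genes = 300L, n_families = 6L, n_modules = 6L,
                         n_blocks = 6L, n_terms = 40L,
                         term_size = c(20L, 30L),
                         modality_fractions = c(chem = 0.3, coexp = 0.3,
                                                ppi = 0.3, joint = 0.1),
                         label_noise = 0.05,
                         n_bits = 1024L, prototype_bits = 60L,
                         bit_flip = 0.10, set_size = c(5L, 20L),
                         n_experiments = 5L, n_samples = 20L,
                         noise_sd = 0.5,
                         p_within = 0.30, p_between = 0.02,
                         n_hubs = 0L, p_hub = 0.5,
                         hub_term_fraction = 0,
                         evidence_proportions = c(TAS = 0.4, ISS = 0.3,
                                                  IEA = 0.3)) {
  as.list(environment())
}

# named substream seeds derived from the world seed, kept below 2^31
substream_seed <- function(seed, name) {
  offset <- c(world = 1L, ligands = 2L, expression = 3L, ppi = 4L,
              annotations = 5L)[[name]]
  (abs(as.integer(seed)) %% 214748363L) * 10L + offset
}

#' Build a synthetic world
#'
#' Draws the family/module/block assignments and the planted term
#' definitions.  Regeneration from the same `(params, seed)` is
#' bit-identical; each downstream generator uses its own named substream
#' of the world seed so the stages can be regenerated independently.
#'
#' @param params list from [world_params()].
#' @param seed integer seed.
#' @return object of class `"synthetic_world"`.
#' @export
make_world <- function(params = world_params(), seed = 1L) {
  p <- params
  stopifnot(p$n_genes >= 50L, p$n_families >= 3L, p$n_modules >= 3L,
            p$n_blocks >= 3L,
            abs(sum(p$modality_fractions) - 1) < 1e-8)
  if (p$term_size[2] > floor(p$n_genes / max(p$n_families, p$n_modules,
                                             p$n_blocks))) {
    stop("term sizes exceed group sizes; enlarge n_genes or shrink groups")
  }
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  world <- with_local_seed(substream_seed(seed, "world"), {
    assign_groups <- function(k) {
      a <- sample(rep_len(seq_len(k), p$n_genes))
      names(a) <- genes
      a
    }
    families <- assign_groups(p$n_families)
    modules <- assign_groups(p$n_modules)
    blocks <- assign_groups(p$n_blocks)
    hubs <- if (p$n_hubs > 0L) sample(genes, p$n_hubs) else character(0)

    fr <- p$modality_fractions
    n_hub_terms <- if (p$n_hubs > 0L) round(p$hub_term_fraction * p$n_terms)
      else 0L
    counts <- c(chem = round(fr[["chem"]] * p$n_terms),
                coexp = round(fr[["coexp"]] * p$n_terms),
                ppi = round(fr[["ppi"]] * p$n_terms) - n_hub_terms,
                joint = round(fr[["joint"]] * p$n_terms),
                hub = n_hub_terms)
    counts[["chem"]] <- counts[["chem"]] + (p$n_terms - sum(counts))
    if (any(counts < 0)) stop("infeasible modality term counts")

    modality <- rep(names(counts), counts)
    terms <- vector("list", p$n_terms)
    group_of <- list(chem = families, coexp = modules, ppi = blocks)
    cyc <- c(chem = 0L, coexp = 0L, ppi = 0L, joint = 0L, hub = 0L)
    for (i in seq_len(p$n_terms)) {
      mo <- modality[i]
      size <- sample(p$term_size[1]:p$term_size[2], 1L)
      cyc[mo] <- cyc[mo] + 1L
      members <- if (mo == "joint") {
        f <- (cyc[mo] - 1L) %% p$n_families + 1L
        m <- (cyc[mo] - 1L) %% p$n_modules + 1L
        half <- ceiling(size / 2)
        c(sample(genes[families == f], half),
          sample(genes[modules == m], size - half))
      } else if (mo == "hub") {
        n_h <- min(size, length(hubs))
        c(sample(hubs, n_h), sample(setdiff(genes, hubs), size - n_h))
      } else {
        grp <- group_of[[mo]]
        g <- (cyc[mo] - 1L) %% max(grp) + 1L
        sample(genes[grp == g], size)
      }
      terms[[i]] <- list(term_id = sprintf("t%03d_%s", i, mo),
                         modality = mo, genes = unique(members))
    }
    list(families = families, modules = modules, blocks = blocks,
         hubs = hubs, terms = terms)
  })
  structure(c(world, list(genes = genes, seed = as.integer(seed),
                          params = p)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  mo <- table(vapply(x$terms, `[[`, character(1), "modality"))
  cat("synthetic_world: ", length(x$genes), " genes, ",
      length(x$terms), " planted terms (",
      paste(names(mo), mo, sep = "=", collapse = ", "), "), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate ligand sets for a synthetic world
#'
#' Each chemotype family gets a random prototype fingerprint; each
#' target's ligands perturb its family prototype (each prototype bit
#' dropped with probability `bit_flip` and replaced by a random feature),
#' so within-family Tanimoto similarity exceeds between-family similarity.
#' Property fields are drawn inside the filter bounds.
#'
#' @param world a [make_world()] object.
#' @return named list of [ligand_set()] objects, one per gene.
#' @export
make_ligands <- function(world) {
  p <- world$params
  with_local_seed(substream_seed(world$seed, "ligands"), {
    protos <- lapply(seq_len(p$n_families), function(f) {
      sort(sample.int(p$n_bits, p$prototype_bits))
    })
    sets <- lapply(world$genes, function(g) {
      proto <- protos[[world$families[[g]]]]
      n_lig <- sample(p$set_size[1]:p$set_size[2], 1L)
      fps <- lapply(seq_len(n_lig), function(i) {
        keep <- stats::runif(length(proto)) >= p$bit_flip
        extra <- if (any(!keep)) sample.int(p$n_bits, sum(!keep)) else
          integer(0)
        sort(unique(c(proto[keep], extra)))
      })
      lig <- ligand_frame(sprintf("%s_l%03d", g, seq_len(n_lig)), fps,
                          mol_weight = stats::runif(n_lig, 150, 500),
                          n_oxygen = sample(0:10, n_lig, replace = TRUE),
                          n_nitrogen = sample(0:10, n_lig, replace = TRUE))
      ligand_set(g, lig)
    })
    names(sets) <- world$genes
    sets
  })
}

#' Generate expression experiments for a synthetic world
#'
#' Each experiment draws one latent factor per co-expression module per
#' sample; a gene's expression is its module's factor plus Gaussian noise,
#' so module co-membership implies positive expected Spearman correlation.
#'
#' @param world a [make_world()] object.
#' @param n_experiments,n_samples,noise_sd override the world defaults.
#' @param seed override the derived substream seed.
#' @return list of gene-by-sample matrices with gene rownames.
#' @export
make_expression <- function(world, n_experiments = NULL, n_samples = NULL,
                            noise_sd = NULL, seed = NULL) {
  p <- world$params
  if (is.null(n_experiments)) n_experiments <- p$n_experiments
  if (is.null(n_samples)) n_samples <- p$n_samples
  if (is.null(noise_sd)) noise_sd <- p$noise_sd
  if (is.null(seed)) seed <- substream_seed(world$seed, "expression")
  stopifnot(n_samples >= 10L)
  ng <- length(world$genes)
  with_local_seed(seed, {
    lapply(seq_len(n_experiments), function(e) {
      fac <- matrix(stats::rnorm(p$n_modules * n_samples),
                    p$n_modules, n_samples)
      x <- fac[world$modules, , drop = FALSE] +
        noise_sd * matrix(stats::rnorm(ng * n_samples), ng, n_samples)
      dimnames(x) <- list(world$genes,
                          sprintf("e%02d_s%03d", e, seq_len(n_samples)))
      x
    })
  })
}

#' Generate a stochastic-block PPI edge list
#'
#' Independent Bernoulli edges with probability `p_within` inside a block
#' and `p_between` across blocks.  Hub genes (when the world has them)
#' additionally connect to every other gene with probability `p_hub`,
#' reproducing the degree bias of real interaction data.
#'
#' @param world a [make_world()] object.
#' @param p_within,p_between,p_hub override the world defaults.
#' @param seed override the derived substream seed.
#' @return data frame with columns `gene_a`, `gene_b`.
#' @export
make_ppi <- function(world, p_within = NULL, p_between = NULL,
                     p_hub = NULL, seed = NULL) {
  p <- world$params
  if (is.null(p_within)) p_within <- p$p_within
  if (is.null(p_between)) p_between <- p$p_between
  if (is.null(p_hub)) p_hub <- p$p_hub
  if (is.null(seed)) seed <- substream_seed(world$seed, "ppi")
  stopifnot(p_between >= 0, p_between < p_within, p_within <= 1)
  n <- length(world$genes)
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  same_block <- world$blocks[idx[, 1]] == world$blocks[idx[, 2]]
  prob <- ifelse(same_block, p_within, p_between)
  if (length(world$hubs) > 0L) {
    hub_pair <- world$genes[idx[, 1]] %in% world$hubs |
      world$genes[idx[, 2]] %in% world$hubs
    prob <- ifelse(hub_pair, 1 - (1 - prob) * (1 - p_hub), prob)
  }
  edge <- with_local_seed(seed, stats::runif(nrow(idx)) < prob)
  data.frame(gene_a = world$genes[idx[edge, 1]],
             gene_b = world$genes[idx[edge, 2]],
             stringsAsFactors = FALSE)
}

#' Materialize annotations for the planted terms
#'
#' Each planted term's gene set has a `label_noise` fraction of members
#' swapped for random non-members; every positive gets an evidence tag
#' sampled from the configured proportions.  Chemically encoded terms are
#' tagged molecular function (`MF`), the others biological process (`BP`).
#'
#' @param world a [make_world()] object.
#' @param label_noise override the world default.
#' @param seed override the derived substream seed.
#' @return list with `annotations` (an [annotation_matrix()]) and `truth`
#'   (data frame `term`, `modality`, `size` describing the planted sets).
#' @export
make_annotations <- function(world, label_noise = NULL, seed = NULL) {
  p <- world$params
  if (is.null(label_noise)) label_noise <- p$label_noise
  if (is.null(seed)) seed <- substream_seed(world$seed, "annotations")
  genes <- world$genes
  term_ids <- vapply(world$terms, `[[`, character(1), "term_id")
  modality <- vapply(world$terms, `[[`, character(1), "modality")
  values <- matrix(FALSE, length(genes), length(term_ids),
                   dimnames = list(genes, term_ids))
  evid <- matrix("", length(genes), length(term_ids),
                 dimnames = list(genes, term_ids))
  ev_codes <- names(p$evidence_proportions)
  with_local_seed(seed, {
    for (i in seq_along(world$terms)) {
      members <- world$terms[[i]]$genes
      n_swap <- round(label_noise * length(members))
      if (n_swap > 0L) {
        out <- sample(members, n_swap)
        replacement <- sample(setdiff(genes, members), n_swap)
        members <- c(setdiff(members, out), replacement)
      }
      values[members, i] <- TRUE
      evid[members, i] <- sample(ev_codes, length(members), replace = TRUE,
                                 prob = p$evidence_proportions)
    }
  })
  branch <- ifelse(modality == "chem", "MF",
                   ifelse(modality %in% c("coexp", "ppi"), "BP", "other"))
  names(branch) <- term_ids
  A <- annotation_matrix(genes, term_ids, values, evid, branch = branch)
  truth <- data.frame(term = term_ids, modality = modality,
                      size = vapply(world$terms,
                                    function(t) length(t$genes), integer(1)),
                      stringsAsFactors = FALSE)
  list(annotations = A, truth = truth)
}
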