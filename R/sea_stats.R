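#' Random background for ligand-set similarity scores
#'
#' Raw ligand-set scores grow with the number of cross-pair comparisons, so
#' they are calibrated against scores of randomly drawn ligand sets of
#' matched sizes.  [sample_background()] draws the random scores,
#' [fit_background()] fits power laws for their mean and standard deviation
#' as functions of the set-size product `m = nA * nB` and a Gumbel
#' (extreme-value) tail to the resulting Z-scores, [zscore()] and
#' [evalue()] convert observed raw scores to calibrated statistics, and
#' [score_all_pairs()] applies the machinery to every pair of targets.
#'
#' @name sea-background
NULL

#' Sample raw scores of random ligand sets
#'
#' For each `(nA, nB)` size pair, draws `n_samples` pairs of disjoint
#' random ligand sets (without replacement) from the universe and records
#' the raw score at `tc_cutoff`.
#'
#' @param universe ligand record data frame (the pool to draw from).
#' @param size_grid list of length-2 integer vectors, or a 2-column matrix
#'   of set sizes.
#' @param n_samples samples per grid point (>= 50 recommended).
#' @param seed integer seed; the sampling is fully reproducible from it.
#' @param tc_cutoff Tanimoto cutoff used for the raw scores.
#' @return data frame with columns `n_a`, `n_b`, `m`, `raw` and attribute
#'   `tc_cutoff`.
#' @export
sample_background <- function(universe, size_grid, n_samples, seed,
                              tc_cutoff = 0.28) {
  universe <- as_ligand_frame(universe)
  if (is.matrix(size_grid)) {
    size_grid <- lapply(seq_len(nrow(size_grid)), function(i) size_grid[i, ])
  }
  sizes <- do.call(rbind, lapply(size_grid, as.integer))
  n_lig <- nrow(universe)
  if (n_lig < max(sizes[, 1] + sizes[, 2])) {
    stop("ligand universe too small for the requested set sizes")
  }
  fps <- universe$fingerprint
  bits <- sort(unique(unlist(fps)))
  bm <- fp_bit_matrix(fps, bits)
  fp_size <- lengths(fps)

  set.seed(seed)
  out <- vector("list", nrow(sizes))
  for (g in seq_len(nrow(sizes))) {
    na <- sizes[g, 1]; nb <- sizes[g, 2]
    raw <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      idx <- sample.int(n_lig, na + nb)
      ia <- idx[seq_len(na)]; ib <- idx[na + seq_len(nb)]
      inter <- as.matrix(Matrix::tcrossprod(bm[ia, , drop = FALSE],
                                            bm[ib, , drop = FALSE]))
      tc <- inter / (outer(fp_size[ia], fp_size[ib], `+`) - inter)
      raw[s] <- sum(tc[tc >= tc_cutoff])
    }
    out[[g]] <- data.frame(n_a = na, n_b = nb, m = na * nb, raw = raw)
  }
  structure(do.call(rbind, out), tc_cutoff = tc_cutoff, seed = seed)
}

#' Fit the random-score background model
#'
#' Fits `E[raw] = a * m^k` and `SD[raw] = b * m^j` by least squares in
#' log-log space over the per-grid-point sample means and standard
#' deviations, then fits a Gumbel distribution by maximum likelihood to the
#' Z-scores of a held-out subset of the random samples (every fourth
#' sample within each grid point, excluded from the power-law fits).
#'
#' @param samples output of [sample_background()].
#' @param holdout_every hold out every k-th sample per grid point for the
#'   extreme-value fit (default 4).
#' @return object of class `"sea_background"`: list with `tc_cutoff`,
#'   `mean_fit` (`a`, `k`), `sd_fit` (`b`, `j`), `evd_location`,
#'   `evd_scale`, `n_comparisons` (1 until a scoring run sets it), `seed`.
#' @export
fit_background <- function(samples, holdout_every = 4L) {
  stopifnot(all(c("m", "raw") %in% names(samples)))
  grp <- interaction(samples$n_a, samples$n_b, drop = TRUE)
  idx_in_grp <- stats::ave(seq_len(nrow(samples)), grp, FUN = seq_along)
  held <- idx_in_grp %% holdout_every == 0L
  train <- samples[!held, , drop = FALSE]

  if (all(train$raw == 0)) {
    stop("all background scores are zero; lower tc_cutoff or enlarge sets")
  }
  agg_m <- tapply(train$m, train$m, unique)
  if (length(agg_m) < 2L) {
    stop("background fit needs more than one distinct set-size product m")
  }
  if (length(agg_m) < 20L || max(train$m) / min(train$m) < 10) {
    warning("background grid is small (< 20 size products or < 1 decade); ",
            "fits may be unstable")
  }
  mu <- tapply(train$raw, train$m, mean)
  sg <- tapply(train$raw, train$m, stats::sd)
  mv <- as.numeric(names(mu))
  if (any(mu <= 0)) {
    stop("some grid points have zero mean background score; lower tc_cutoff")
  }
  mfit <- stats::lm(log(mu) ~ log(mv))
  mean_fit <- c(a = unname(exp(stats::coef(mfit)[1])),
                k = unname(stats::coef(mfit)[2]))
  ok <- is.finite(sg) & sg > 0
  if (sum(ok) < 2L) {
    stop("background standard deviations are degenerate; lower tc_cutoff")
  }
  sfit <- stats::lm(log(sg[ok]) ~ log(mv[ok]))
  sd_fit <- c(b = unname(exp(stats::coef(sfit)[1])),
              j = unname(stats::coef(sfit)[2]))

  model <- structure(list(tc_cutoff = attr(samples, "tc_cutoff"),
                          mean_fit = mean_fit, sd_fit = sd_fit,
                          evd_location = 0, evd_scale = 1,
                          n_comparisons = 1L,
                          seed = attr(samples, "seed")),
                     class = "sea_background")
  z_held <- zscore(samples$raw[held], samples$m[held], model)
  ev <- fit_gumbel(z_held)
  model$evd_location <- ev[["location"]]
  model$evd_scale <- ev[["scale"]]
  model
}

#' @export
print.sea_background <- function(x, ...) {
  cat("sea_background: Tc cutoff", x$tc_cutoff, "\n",
      sprintf("  mean = %.4g * m^%.4g, sd = %.4g * m^%.4g\n",
              x$mean_fit[["a"]], x$mean_fit[["k"]],
              x$sd_fit[["b"]], x$sd_fit[["j"]]),
      sprintf("  Gumbel(location = %.4g, scale = %.4g), n_comparisons = %d\n",
              x$evd_location, x$evd_scale, x$n_comparisons))
  invisible(x)
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location and scale of a Gumbel (type-I extreme value) distribution
#' by direct likelihood maximisation, started from moment estimates.
#'
#' @param x numeric sample.
#' @return named numeric vector `c(location, scale)`.
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10, stats::sd(x) > 0)
  s0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * s0
  nll <- function(p) {
    s <- exp(p[2])
    u <- (x - p[1]) / s
    length(x) * log(s) + sum(u) + sum(exp(-u))
  }
  opt <- stats::optim(c(mu0, log(s0)), nll, method = "BFGS")
  c(location = opt$par[1], scale = exp(opt$par[2]))
}

# expected background mean / sd at size product m
background_mean <- function(model, m) {
  model$mean_fit[["a"]] * m ^ model$mean_fit[["k"]]
}
background_sd <- function(model, m) {
  model$sd_fit[["b"]] * m ^ model$sd_fit[["j"]]
}

#' Z-score of a raw ligand-set score
#'
#' Centres and scales a raw score by the fitted random expectation for its
#' set-size product.
#'
#' @param raw raw score(s).
#' @param m set-size product(s) `nA * nB`, `>= 1`.
#' @param model a `"sea_background"` model.
#' @return numeric Z-score(s).
#' @export
zscore <- function(raw, m, model) {
  stopifnot(inherits(model, "sea_background"), all(m >= 1))
  s <- background_sd(model, m)
  if (any(s <= 0)) stop("fitted background SD is non-positive at some m")
  (raw - background_mean(model, m)) / s
}

#' Extreme-value E-value of a Z-score
#'
#' The expected number of random comparisons scoring at least as well:
#' `E = n_comparisons * P(Z > z)` under the fitted Gumbel tail
#' `P(Z > z) = 1 - exp(-exp(-(z - location)/scale))`.  Strictly decreasing
#' in `z`, mapping the real line onto `(0, n_comparisons)`.
#'
#' @param z Z-score(s).
#' @param model a `"sea_background"` model.
#' @return positive E-value(s).
#' @export
evalue <- function(z, model) {
  stopifnot(inherits(model, "sea_background"), model$evd_scale > 0)
  u <- (z - model$evd_location) / model$evd_scale
  model$n_comparisons * (-expm1(-exp(-u)))
}

#' Score every pair of targets
#'
#' Computes the raw ligand-set score, Z-score and E-value for each
#' unordered pair of targets.  Sets smaller than `min_ligands` are dropped
#' with a warning (the inclusion rule for targets).  The model's
#' comparison count is set to the number of pairs actually scored.
#'
#' @param sets named list of [ligand_set()] objects, already filtered.
#' @param model a `"sea_background"` model.
#' @param min_ligands minimum ligand-set size for inclusion (default 5).
#' @return data frame with columns `target_a`, `target_b`, `raw`, `z`,
#'   `e_value`; attribute `n_comparisons` holds the pair count used.
#' @export
score_all_pairs <- function(sets, model, min_ligands = 5L) {
  stopifnot(inherits(model, "sea_background"))
  sizes <- vapply(sets, function(s) nrow(s$ligands), integer(1))
  small <- sizes < min_ligands
  if (any(small)) {
    warning(sum(small), " target(s) with fewer than ", min_ligands,
            " ligands excluded")
    sets <- sets[!small]
  }
  nt <- length(sets)
  if (nt < 2L) stop("need at least two targets to score pairs")
  targets <- vapply(sets, `[[`, character(1), "target_id")

  fps <- unlist(lapply(sets, function(s) s$ligands$fingerprint),
                recursive = FALSE)
  grp <- rep.int(seq_len(nt), vapply(sets, function(s) nrow(s$ligands),
                                     integer(1)))
  n_lig <- length(fps)
  fp_size <- lengths(fps)
  bits <- sort(unique(unlist(fps)))
  bm <- fp_bit_matrix(fps, bits)
  gm <- Matrix::sparseMatrix(i = seq_len(n_lig), j = grp, x = 1,
                             dims = c(n_lig, nt))

  # accumulate target-by-target raw-score sums in ligand row chunks to keep
  # the dense Tanimoto block small
  S <- matrix(0, nt, nt)
  chunk <- max(1L, min(n_lig, as.integer(ceiling(2e6 / max(n_lig, 1)))))
  start <- 1L
  while (start <= n_lig) {
    r <- start:min(n_lig, start + chunk - 1L)
    inter <- as.matrix(Matrix::tcrossprod(bm[r, , drop = FALSE], bm))
    tc <- inter / (outer(fp_size[r], fp_size, `+`) - inter)
    tc[tc < model$tc_cutoff] <- 0
    S <- S + as.matrix(Matrix::crossprod(gm[r, , drop = FALSE], tc %*% gm))
    start <- start + chunk
  }

  ij <- which(upper.tri(S), arr.ind = TRUE)
  set_size <- vapply(sets, function(s) nrow(s$ligands), integer(1))
  m <- set_size[ij[, 1]] * set_size[ij[, 2]]
  raw <- S[ij]
  model$n_comparisons <- nrow(ij)
  z <- zscore(raw, m, model)
  res <- data.frame(target_a = targets[ij[, 1]],
                    target_b = targets[ij[, 2]],
                    raw = raw, z = z, e_value = evalue(z, model),
                    stringsAsFactors = FALSE)
  res <- res[order(res$target_a, res$target_b), ]
  rownames(res) <- NULL
  structure(res, n_comparisons = nrow(ij))
}

#' Write / read SEA pair scores
#'
#' TSV with columns `target_a`, `target_b`, `raw`, `z`, `e_value`;
#' E-values serialized in scientific notation with 7 significant digits so
#' values near the numerical floor survive a round trip.
#'
#' @param results data frame from [score_all_pairs()].
#' @param path file path.
#' @export
write_sea_results <- function(results, path) {
  out <- results
  out$e_value <- format(out$e_value, scientific = TRUE, digits = 7)
  out$raw <- format(out$raw, digits = 10)
  out$z <- format(out$z, digits = 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sea_results
#' @export
read_sea_results <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$raw <- as.numeric(tab$raw)
  tab$z <- as.numeric(tab$z)
  tab$e_value <- as.numeric(tab$e_value)
  tab
}

#' Serialize / restore a background model
#'
#' Stores the calibration (cutoff, power-law fits, extreme-value
#' parameters, comparison count, seed) as a small JSON file.
#'
#' @param model a `"sea_background"` model.
#' @param path file path.
#' @export
write_background_model <- function(model, path) {
  x <- unclass(model)
  x$mean_fit <- as.list(x$mean_fit)
  x$sd_fit <- as.list(x$sd_fit)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background_model
#' @export
read_background_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mean_fit <- unlist(x$mean_fit)
  x$sd_fit <- unlist(x$sd_fit)
  structure(x, class = "sea_background")
}
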