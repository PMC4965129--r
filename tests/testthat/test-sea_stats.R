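make_uniform_universe <- function(n = 80, n_bits = 64, n_on = 8, seed = 5) {
  with_local_seed(seed, {
    fps <- replicate(n, random_fp(n_bits, n_on), simplify = FALSE)
    ligand_frame(sprintf("u%03d", seq_len(n)), fps)
  })
}
test_that("background sampling is reproducible and respects set sizes", {
  uni <- make_uniform_universe()
  s1 <- sample_background(uni, list(c(5L, 5L)), n_samples = 100, seed = 9)
  s2 <- sample_background(uni, list(c(5L, 5L)), n_samples = 100, seed = 9)
  expect_equal(nrow(s1), 100L)
  expect_identical(s1, s2)
  expect_true(all(s1$m == 25))
  expect_error(sample_background(uni[1:8, ], list(c(5L, 5L)), 10, seed = 1),
               "too small")
})

test_that("identical fingerprints give raw score nA * nB; sparse random
           fingerprints give raw scores near zero", {
  same <- ligand_frame(sprintf("s%02d", 1:40),
                       replicate(40, c(1L, 2L, 3L), simplify = FALSE))
  s <- sample_background(same, list(c(4L, 7L)), n_samples = 20, seed = 2)
  expect_true(all(s$raw == 28))

  # expected pairwise Tc of disjoint-ish random 64-bit fingerprints is far
  # below the cutoff, so almost no pair contributes
  uni <- make_uniform_universe(n = 120, n_bits = 1024, n_on = 10)
  s0 <- sample_background(uni, list(c(10L, 10L)), n_samples = 50, seed = 3)
  expect_lt(mean(s0$raw), 1)
})

test_that("power-law background fit recovers an exact law", {
  m_grid <- round(exp(seq(log(20), log(400), length.out = 25)))
  m_grid <- unique(m_grid)
  # every 4th sample is held out for the tail fit, so only the first three
  # (mean exactly 0, constant spread) enter the power-law fits; the held
  # offset varies so the Gumbel fit sees a non-degenerate sample
  held_offsets <- seq(-1.5, 3, length.out = length(m_grid))
  samples <- do.call(rbind, lapply(seq_along(m_grid), function(i) {
    m <- m_grid[i]
    data.frame(n_a = m, n_b = 1L, m = m,
               raw = 2 * m + c(-1, 0, 1, held_offsets[i]))
  }))
  attr(samples, "tc_cutoff") <- 0.28
  model <- fit_background(samples)
  expect_equal(model$mean_fit[["a"]], 2, tolerance = 1e-6)
  expect_equal(model$mean_fit[["k"]], 1, tolerance = 1e-6)
})

test_that("background fit rejects degenerate inputs", {
  one_m <- data.frame(n_a = 5L, n_b = 5L, m = 25, raw = rnorm(40, 10))
  attr(one_m, "tc_cutoff") <- 0.28
  expect_error(fit_background(one_m), "more than one distinct")

  zeros <- data.frame(n_a = rep(c(5L, 10L), each = 20),
                      n_b = 5L, m = rep(c(25, 50), each = 20), raw = 0)
  attr(zeros, "tc_cutoff") <- 0.28
  expect_error(suppressWarnings(fit_background(zeros)), "cutoff")
})

test_that("gumbel maximum-likelihood fit recovers known parameters", {
  set.seed(21)
  # inverse-cdf samples from Gumbel(0, 1)
  z <- -log(-log(runif(10000)))
  fit <- fit_gumbel(z)
  expect_equal(fit[["location"]], 0, tolerance = 0.05)
  expect_equal(fit[["scale"]], 1, tolerance = 0.05)
})

test_that("zscore centres and scales by the fitted background", {
  model <- structure(list(tc_cutoff = 0.28,
                          mean_fit = c(a = 2, k = 1),
                          sd_fit = c(b = 0.5, j = 0.5),
                          evd_location = 1, evd_scale = 2,
                          n_comparisons = 100L, seed = 1L),
                     class = "sea_background")
  expect_equal(zscore(2 * 36, 36, model), 0)
  expect_equal(zscore(2 * 36 + 0.5 * 6, 36, model), 1)
})

test_that("evalue follows the Gumbel tail and is a bijection to
           (0, n_comparisons)", {
  model <- structure(list(tc_cutoff = 0.28,
                          mean_fit = c(a = 1, k = 1),
                          sd_fit = c(b = 1, j = 0.5),
                          evd_location = 0.5, evd_scale = 1.2,
                          n_comparisons = 1000L, seed = 1L),
                     class = "sea_background")
  expect_equal(evalue(model$evd_location, model),
               1000 * (1 - exp(-1)))
  # below z ~ -3 the tail probability rounds to 1 in double precision, so
  # probe the range where the mapping is numerically resolvable
  zg <- seq(-3, 30, by = 0.5)
  ev <- evalue(zg, model)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev > 0 & ev < 1000))
  expect_lt(evalue(80, model), 1e-25)
})

test_that("zscores of random pairs from the fitted background are centred", {
  uni <- make_structured_universe()
  grid <- background_size_grid()
  bg <- sample_background(uni, grid, n_samples = 50, seed = 13)
  model <- fit_background(bg)
  fresh <- sample_background(uni, grid, n_samples = 20, seed = 14)
  z <- zscore(fresh$raw, fresh$m, model)
  expect_lt(abs(mean(z)), 0.1)
})

test_that("score_all_pairs scores each unordered pair once,
           deterministically, and separates planted chemotype families", {
  pl <- default_pipeline()
  n <- length(pl$sets)
  expect_equal(nrow(pl$sea), n * (n - 1) / 2)
  expect_false(any(pl$sea$target_a == pl$sea$target_b))
  expect_equal(attr(pl$sea, "n_comparisons"), n * (n - 1) / 2)

  fam <- pl$world$families
  same <- fam[pl$sea$target_a] == fam[pl$sea$target_b]
  # every within-family pair scores better than every cross-family pair
  expect_lt(max(pl$sea$e_value[same]), min(pl$sea$e_value[!same]))

  res2 <- score_all_pairs(pl$sets, pl$model)
  expect_identical(res2$e_value, pl$sea$e_value)
})

test_that("E-values of random synthetic pairs are approximately
           uniform-rank calibrated in the tail", {
  uni <- make_structured_universe()
  grid <- background_size_grid()
  bg <- sample_background(uni, grid, n_samples = 50, seed = 13)
  model <- fit_background(bg)
  fresh <- sample_background(uni, grid, n_samples = 30, seed = 15)
  z <- zscore(fresh$raw, fresh$m, model)
  model$n_comparisons <- length(z)
  e <- evalue(z, model)
  for (c_frac in c(0.2, 0.4)) {
    frac <- mean(e < c_frac * length(z))
    expect_lt(abs(frac - c_frac), 0.1)
  }
})

test_that("SEA results and background model survive file round trips", {
  pl <- default_pipeline()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sea_results(pl$sea[1:50, ], path)
  back <- read_sea_results(path)
  expect_equal(back$e_value, pl$sea$e_value[1:50], tolerance = 1e-6)
  expect_identical(back$target_a, pl$sea$target_a[1:50])

  mpath <- withr::local_tempfile(fileext = ".json")
  write_background_model(pl$model, mpath)
  m2 <- read_background_model(mpath)
  expect_equal(m2$mean_fit, pl$model$mean_fit)
  expect_equal(m2$evd_location, pl$model$evd_location)
  expect_equal(zscore(10, 100, m2), zscore(10, 100, pl$model))
})
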