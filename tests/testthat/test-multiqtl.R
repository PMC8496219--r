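test_that("train/test split is disjoint, exhaustive and seeded", {
  pheno <- tibble::tibble(segregant_id = sprintf("s%03d", 1:255),
                          phenotype = rep_len(c(0L, 1L), 255))
  sp <- split_data(pheno, n_train = 150, seed = 9)
  expect_equal(sum(sp$split == "train"), 150)
  expect_equal(sum(sp$split == "test"), 105)
  expect_setequal(sp$segregant_id, pheno$segregant_id)
  expect_identical(sp, split_data(pheno, n_train = 150, seed = 9))
  expect_false(identical(sp$split, split_data(pheno, 150, seed = 10)$split))
  expect_error(split_data(pheno, n_train = 0), "positive")
  expect_error(split_data(pheno, n_train = 255), "smaller")
})

test_that("stepwise search returns the empty model under the null", {
  map <- small_map(40)
  cross <- sim_cross(cross_config(map, n_tetrads = 25), seed = 31)
  geno <- geno_from_calls(cross$genotypes, map)
  probs <- genotype_probs(geno, step_cM = 5)
  y_null <- withr::with_seed(32, sample(cross$segregants$phenotype))
  # phenotype shuffled against genotypes: no real signal
  m <- stepwise_search(probs, y_null, n_perm = 200, seed = 33)
  expect_equal(nrow(m$loci), 0)
  expect_equal(m$plod, 0)
  expect_error(
    stepwise_search(probs, y_null, chromosomes = "chrXIX", n_perm = 200),
    "no candidate positions")
})

test_that("stepwise search recovers planted loci", {
  map <- sim_genetic_map(120, c(chrI = 3e5, chrII = 3e5, chrIII = 3e5),
                         seed = 34)
  cfg <- cross_config(map, n_tetrads = 64)
  cross <- sim_cross(cfg, seed = 35)
  geno <- geno_from_calls(cross$genotypes, map)
  probs <- genotype_probs(geno, step_cM = 5)
  m <- stepwise_search(probs, cross$segregants, n_perm = 200, seed = 36)
  expect_equal(nrow(m$loci), 1)
  causal_chrom <- map$chrom[map$marker_id == cfg$causal_marker]
  expect_equal(m$loci$chrom, causal_chrom)

  # two strong additive loci on the two allowed chromosomes
  causal2 <- map$marker_id[map$chrom == "chrIII"][10]
  y2 <- withr::with_seed(37, {
    p <- 0.05 + 0.45 * (cross$genotypes[, cfg$causal_marker] == "B") +
      0.45 * (cross$genotypes[, causal2] == "B")
    rbinom(nrow(cross$genotypes), 1, p)
  })
  chrom2 <- map$chrom[map$marker_id == cfg$causal_marker]
  m2 <- stepwise_search(probs, y2, chromosomes = c(chrom2, "chrIII"),
                        n_perm = 200, seed = 38)
  expect_equal(nrow(m2$loci), 2)
  expect_setequal(m2$loci$chrom, c(chrom2, "chrIII"))
  expect_equal(length(m2$interactions), 0)

  # local-optimum certificate: no single deletion improves the penalized LOD
  Q <- probs$prob_B
  yv <- tetradqtl:::align_phenotype(probs, y2)
  full <- tetradqtl:::hk_model_fit(Q, yv, m2$loci$index)
  plod_full <- full$lod - 2 * m2$penalties$main
  for (k in seq_len(nrow(m2$loci))) {
    f <- tetradqtl:::hk_model_fit(Q, yv, m2$loci$index[-k])
    expect_lte(f$lod - m2$penalties$main, plod_full + 1e-9)
  }
  expect_gte(plod_full, 0)
})

test_that("held-out fitting reproduces the RSS arithmetic", {
  tab <- table22()
  probs <- probs_from_q(tab$q)
  model <- stepwise_search(probs, tab$y,
                           penalties = list(main = 0.1, interaction = 0.1),
                           max_qtl = 1)
  expect_equal(nrow(model$loci), 1)
  fitted <- fit_model(probs, tab$y, model)
  expect_equal(fitted$variance_explained, 0.25)        # 1 - 1.5/2
  # likelihood-ratio LOD of the 2x2 table
  expect_equal(fitted$model_lod,
               (6 * log(0.75) + 2 * log(0.25) - 8 * log(0.5)) / log(10),
               tolerance = 1e-6)

  # perfect association: all variance explained, LOD = n log10(2)
  perf_y <- c(rep(1, 4), rep(0, 4))
  fitted_perf <- fit_model(probs, perf_y, model)
  expect_equal(fitted_perf$variance_explained, 1, tolerance = 1e-9)
  expect_equal(fitted_perf$model_lod, 8 * log10(2), tolerance = 1e-3)

  # a locus with no effect in the held-out data explains nothing
  null_y <- c(1, 0, 1, 0, 1, 0, 1, 0)
  fitted_null <- fit_model(probs, null_y, model)
  expect_lt(fitted_null$variance_explained, 1e-9)
  expect_gt(fitted_null$p_chisq, 0.9)
  expect_gt(fitted_null$p_F, 0.9)

  expect_error(fit_model(probs, rep(1, 8), model), "both phenotype classes")
})

test_that("position refinement converges to the profile optimum", {
  map <- small_map(60, c(chrI = 2.5e5), seed = 41)
  cfg <- cross_config(map, n_tetrads = 60)
  cross <- sim_cross(cfg, seed = 42)
  geno <- geno_from_calls(cross$genotypes, map)
  probs <- genotype_probs(geno, step_cM = 2)
  scan <- scan_binary(probs, cross$segregants, method = "hk")
  argmax <- which.max(scan$lod)

  model <- stepwise_search(probs, cross$segregants,
                           penalties = list(main = 1), max_qtl = 1)
  # jitter the position away from the optimum, then refine back
  jittered <- model
  jitter_to <- max(1, argmax - 5)
  jittered$loci <- probs$grid[jitter_to, c("chrom", "pos_cM", "marker_id")]
  jittered$loci$index <- jitter_to
  before <- tetradqtl:::hk_model_fit(probs$prob_B,
                                     tetradqtl:::align_phenotype(
                                       probs, cross$segregants),
                                     jitter_to)$lod
  refined <- refine_positions(probs, cross$segregants, jittered)
  expect_equal(refined$loci$pos_cM, scan$pos_cM[argmax])
  expect_equal(refined$model_lod, max(scan$lod), tolerance = 1e-9)
  expect_gte(refined$model_lod, before)
})

test_that("allele effects are posterior-weighted penetrances", {
  tab <- table22()
  eff <- estimate_effects(probs_from_q(tab$q), tab$y, 1)
  expect_equal(eff$mean, c(0.75, 0.25))
  expect_equal(eff$se, rep(sqrt(0.75 * 0.25 / 4), 2), tolerance = 1e-9)
  expect_equal(eff$se, rep(0.2165, 2), tolerance = 1e-4)
  expect_equal(eff$n_eff, c(4, 4))

  all_dip <- estimate_effects(probs_from_q(tab$q), rep(1, 8), 1)
  expect_equal(all_dip$mean, c(1, 1))
  expect_equal(all_dip$se, c(0, 0))

  # an allele class with no carriers is undefined
  onesided <- estimate_effects(probs_from_q(matrix(1, 4, 1)),
                               c(1, 0, 1, 1), 1)
  expect_true(is.na(onesided$mean[onesided$allele == "W"]))

  # posterior weighting: uncertain genotypes contribute fractionally
  wts <- probs_from_q(matrix(c(1, 1, 0.5, 0), ncol = 1))
  eff_w <- estimate_effects(wts, c(1, 0, 1, 0), 1)
  expect_equal(eff_w$n_eff, c(2.5, 1.5))
  expect_equal(eff_w$mean[1], (1 + 0 + 0.5) / 2.5)
})
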