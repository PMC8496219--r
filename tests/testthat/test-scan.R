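test_that("pseudomarker probabilities obey the two-point closed forms", {
  map <- manual_map(c(0, 20))
  r10 <- haldane_r(10)

  # B then W flanking calls: the midpoint is exactly ambiguous
  geno_bw <- geno_from_calls(rbind(s1 = c("B", "W")), map)
  p_bw <- genotype_probs(geno_bw, step_cM = 10, error_rate = 0)
  mid <- which(p_bw$grid$pos_cM == 10)
  expect_equal(unname(p_bw$prob_B[1, mid]), 0.5)

  # two B calls: conditional two-point probability
  geno_bb <- geno_from_calls(rbind(s1 = c("B", "B")), map)
  p_bb <- genotype_probs(geno_bb, step_cM = 10, error_rate = 0)
  expected <- (1 - r10)^2 / ((1 - r10)^2 + r10^2)
  expect_equal(unname(p_bb$prob_B[1, mid]), expected, tolerance = 1e-12)
  expect_equal(expected, 0.9901, tolerance = 1e-4)

  # at called markers with concordant flanks the probability is ~0 or 1
  p_eps <- genotype_probs(geno_bb, step_cM = 10, error_rate = 0.005)
  expect_gt(p_eps$prob_B[1, 1], 0.99)
  expect_gt(p_eps$prob_B[1, ncol(p_eps$prob_B)], 0.99)
  geno_ww <- geno_from_calls(rbind(s1 = c("W", "W")), map)
  p_ww <- genotype_probs(geno_ww, step_cM = 10, error_rate = 0.005)
  expect_lt(p_ww$prob_B[1, 1], 0.01)
})

test_that("EM and Haley-Knott match their 2x2 closed forms", {
  tab <- table22()
  em <- scan_binary(probs_from_q(tab$q), tab$y, method = "em")
  em_expected <- (6 * log(0.75) + 2 * log(0.25) - 8 * log(0.5)) / log(10)
  expect_equal(em$lod, em_expected, tolerance = 1e-9)
  expect_equal(em$lod, 0.4545, tolerance = 1e-3)

  hk <- scan_binary(probs_from_q(tab$q), tab$y, method = "hk")
  expect_equal(hk$lod, 4 * log10(4 / 3), tolerance = 1e-9)   # RSS 2 vs 1.5
  expect_equal(hk$lod, 0.4998, tolerance = 1e-3)

  # perfect association, n = 8 balanced
  perf_y <- c(rep(1, 4), rep(0, 4))
  perf <- scan_binary(probs_from_q(tab$q), perf_y, method = "em")
  expect_equal(perf$lod, 8 * log10(2), tolerance = 1e-6)
})

test_that("degenerate scans give zero LOD", {
  tab <- table22()
  for (m in c("em", "hk")) {
    expect_equal(scan_binary(probs_from_q(tab$q), rep(1, 8), method = m)$lod, 0)
  }
  flat <- probs_from_q(matrix(0.7, 8, 3))
  expect_equal(scan_binary(flat, tab$y, method = "hk")$lod, rep(0, 3))
})

test_that("LOD curves are non-negative and label-swap invariant", {
  map <- small_map(40)
  cross <- sim_cross(cross_config(map, n_tetrads = 15), seed = 21)
  geno <- geno_from_calls(cross$genotypes, map)
  probs <- genotype_probs(geno, step_cM = 5)
  for (m in c("em", "hk")) {
    s <- scan_binary(probs, cross$segregants, method = m)
    expect_true(all(s$lod >= 0))
    swapped_calls <- ifelse(cross$genotypes == "B", "W", "B")
    probs_sw <- genotype_probs(geno_from_calls(swapped_calls, map), step_cM = 5)
    s_sw <- scan_binary(probs_sw, cross$segregants, method = m)
    expect_equal(s_sw$lod, s$lod, tolerance = 1e-6)
  }
})

test_that("the EM objective is non-decreasing over iterations", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      n <- 40
      q <- runif(n)
      y <- rbinom(n, 1, 0.4)
      fit <- tetradqtl:::em_mixture_ll(q, y, trace = TRUE)
      expect_true(all(diff(fit$trace) >= -1e-10))
    }
  })
})

test_that("permutation thresholds calibrate significance genome-wide", {
  map <- small_map(40)
  cross <- sim_cross(cross_config(map, n_tetrads = 30), seed = 23)
  geno <- geno_from_calls(cross$genotypes, map)
  probs <- genotype_probs(geno, step_cM = 5)
  res <- permutation_threshold(probs, cross$segregants, n_perm = 200,
                               seed = 24)
  expect_gt(attr(res, "threshold"), 0)
  p <- attr(res, "genomewide_p")
  expect_gte(p, 1 / 201)
  expect_lte(p, 1)
  # same seed reproduces the permutation null exactly
  res2 <- permutation_threshold(probs, cross$segregants, n_perm = 200,
                                seed = 24)
  expect_identical(attr(res, "perm_max"), attr(res2, "perm_max"))
  expect_error(permutation_threshold(probs, cross$segregants, n_perm = 50),
               "at least 100")
})

test_that("regressing out the lead QTL removes its own signal", {
  map <- small_map(50, c(chrI = 2e5, chrII = 2e5), seed = 25)
  cross <- sim_cross(cross_config(map, n_tetrads = 40), seed = 26)
  geno <- geno_from_calls(cross$genotypes, map)
  probs <- genotype_probs(geno, step_cM = 5)
  base <- scan_binary(probs, cross$segregants, method = "hk")
  peak <- which.max(base$lod)
  for (m in c("hk", "em")) {
    rs <- scan_regressout(probs, cross$segregants, peak, method = m)
    # the covariate explains its own position away
    expect_lt(rs$lod[peak], 0.05 * max(base$lod))
    expect_lt(max(rs$lod), max(base$lod))
  }
  # a constant covariate changes nothing (hk reduces to the plain scan)
  flat <- probs_from_q(cbind(probs$prob_B[, peak], 0.5))
  rs2 <- scan_regressout(flat, cross$segregants$phenotype, 2, method = "hk")
  s2 <- scan_binary(flat, cross$segregants$phenotype, method = "hk")
  expect_equal(rs2$lod, s2$lod, tolerance = 1e-9)
})
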