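test_that("haldane_r matches its closed form and limits", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(1e9), 0.5)
  expect_equal(haldane_r(10), 0.5 * (1 - exp(-0.2)), tolerance = 1e-12)
  expect_equal(haldane_r(10), 0.09063462, tolerance = 1e-7)
  expect_error(haldane_r(-1), "non-negative")
})

test_that("tetrads segregate 2:2 and respect the zero-recombination limit", {
  map <- small_map(30)
  tet <- simulate_tetrad(map, seed = 3)
  expect_true(all(colSums(tet == "B") == 2))
  expect_true(all(tet %in% c("B", "W")))

  # all markers at the same genetic position: fully parental spores, 2 B + 2 W
  flat <- manual_map(rep(0, 8))
  tet0 <- simulate_tetrad(flat, seed = 4)
  per_spore <- apply(tet0, 1, function(s) length(unique(s)))
  expect_equal(per_spore, rep(1, 4), ignore_attr = TRUE)
  expect_equal(sum(apply(tet0, 1, function(s) all(s == "B"))), 2)
})

test_that("recombinant fraction between two markers matches Haldane", {
  map <- manual_map(c(0, 10))
  cfg <- cross_config(map, causal_marker = "m01", n_tetrads = 10000)
  cross <- sim_cross(cfg, seed = 42)
  rec <- mean(cross$genotypes[, 1] != cross$genotypes[, 2])
  expect_lt(abs(rec - haldane_r(10)), 0.008)   # ~4 SE at 20,000 meioses
})

test_that("phenotypes follow the penetrance model", {
  map <- small_map(20)
  cfg0 <- cross_config(map, n_tetrads = 20, penetrance_B = 0,
                       penetrance_W = 0)
  expect_true(all(sim_cross(cfg0, seed = 1)$segregants$phenotype == 0))

  cfg1 <- cross_config(map, n_tetrads = 20, penetrance_B = 1,
                       penetrance_W = 0)
  cr1 <- sim_cross(cfg1, seed = 2)
  expect_equal(cr1$segregants$phenotype,
               as.integer(cr1$genotypes[, cfg1$causal_marker] == "B"))

  # expected population fraction is the penetrance average (2:2 segregation)
  cfg <- cross_config(map, n_tetrads = 1500)
  cr <- sim_cross(cfg, seed = 3)
  expect_equal(mean(cr$segregants$phenotype), (0.69 + 0.18) / 2,
               tolerance = 0.02)
})

test_that("count emission follows Poisson depth and binomial error", {
  map <- small_map(25)
  cfg <- cross_config(map, n_tetrads = 50)
  cross <- sim_cross(cfg, seed = 7)

  zero <- sim_counts(cross, mean_depth = 0, seed = 8)
  expect_true(all(zero$n_B == 0 & zero$n_W == 0))

  clean <- sim_counts(cross, error_rate = 0, seed = 9)
  is_B <- cross$genotypes == "B"
  expect_true(all(clean$n_W[is_B] == 0) && all(clean$n_B[!is_B] == 0))

  noisy <- sim_counts(cross, mean_depth = 5, error_rate = 0.005, seed = 10)
  wrong <- sum(noisy$n_W[is_B]) + sum(noisy$n_B[!is_B])
  expect_equal(wrong / sum(noisy$n_B + noisy$n_W), 0.005, tolerance = 0.2)
  expect_equal(mean(noisy$n_B + noisy$n_W), 5, tolerance = 0.05)
})

test_that("pool sequencing reflects pooled allele frequencies", {
  map <- small_map(10, seed = 21)
  cfg <- cross_config(map, n_tetrads = 30, penetrance_B = 1, penetrance_W = 0)
  cross <- sim_cross(cfg, seed = 11)
  pools <- sim_pools(cross, depth = 4000, error_rate = 0, seed = 12)

  # all diploids carry B at the causal marker: fraction exactly 1
  dip <- dplyr::filter(pools, phenotype == "diploid",
                       marker_id == cfg$causal_marker)
  expect_equal(dip$n_B / (dip$n_B + dip$n_W), 1)

  # markers unlinked to the phenotype stay near 0.5 in a balanced pool
  other_chrom <- setdiff(unique(map$chrom),
                         map$chrom[map$marker_id == cfg$causal_marker])
  far <- map$marker_id[map$chrom == other_chrom][1]
  frac <- dplyr::filter(pools, marker_id == far) |>
    dplyr::summarise(f = sum(n_B) / sum(n_B + n_W)) |> dplyr::pull(f)
  expect_equal(frac, 0.5, tolerance = 0.15)

  # empty pools are an error: no haploids exist when both penetrances are 1
  cfg_all <- cross_config(map, n_tetrads = 5, penetrance_B = 1,
                          penetrance_W = 1)
  expect_error(sim_pools(sim_cross(cfg_all, seed = 13), seed = 14),
               "empty pool")
})

test_that("the whole generative chain is deterministic under a seed", {
  map <- small_map(15)
  cfg <- cross_config(map, n_tetrads = 8)
  c1 <- sim_cross(cfg, seed = 99)
  c2 <- sim_cross(cfg, seed = 99)
  expect_identical(c1, c2)
  expect_identical(sim_counts(c1, seed = 5), sim_counts(c2, seed = 5))
  expect_identical(sim_pools(c1, seed = 6), sim_pools(c2, seed = 6))
  expect_false(identical(sim_cross(cfg, seed = 100)$genotypes, c1$genotypes))
})

test_that("tetrad spectrum concentrates at 2 for a strong causal locus", {
  map <- small_map(20)
  cfg <- cross_config(map, n_tetrads = 200, penetrance_B = 1,
                      penetrance_W = 0)
  spec <- tetrad_spectrum(sim_cross(cfg, seed = 17))
  expect_true(all(spec$n_diploid == 2))   # 2:2 segregation, deterministic map
})
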