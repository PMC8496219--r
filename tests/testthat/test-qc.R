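# Hand-built genotype matrices exercise each diagnostic's closed form.

test_that("segregation distortion reproduces the chi-square closed form", {
  map <- manual_map(c(0, 10, 20))
  calls <- cbind(
    c(rep("B", 128), rep("W", 127)),          # near-perfect 1:1
    c(rep("B", 200), rep("W", 55)),           # distorted
    rep(NA_character_, 255))                  # untestable
  geno <- geno_from_calls(calls, map)
  d <- segregation_distortion(geno)
  expect_equal(d$statistic[1], 1 / 255, tolerance = 1e-12)
  expect_equal(d$p_value[1], pchisq(1 / 255, 1, lower.tail = FALSE))
  expect_gt(d$p_value[1], 0.9)
  expect_equal(d$statistic[2], (200 - 55)^2 / 255)
  expect_false(d$testable[3])

  even <- geno_from_calls(cbind(rep(c("B", "W"), each = 100)), manual_map(0))
  de <- segregation_distortion(even)
  expect_equal(de$statistic, 0)
  expect_equal(de$p_value, 1)

  mono <- geno_from_calls(cbind(rep("B", 200)), manual_map(0))
  dm <- segregation_distortion(mono)
  expect_equal(dm$statistic, 200)
  expect_lt(dm$p_value, 1e-15)
})

test_that("genotype similarity flags clones, not tetrad complements", {
  map <- manual_map(seq(0, 90, by = 10))
  s <- rep(c("B", "W"), 5)
  calls <- rbind(dup1 = s, dup2 = s,
                 comp = ifelse(s == "B", "W", "B"),
                 other = c(rep("B", 5), rep("W", 5)))
  sim <- genotype_similarity(geno_from_calls(calls, map))
  pair <- function(a, b) sim[sim$id1 %in% c(a, b) & sim$id2 %in% c(a, b), ]
  expect_equal(pair("dup1", "dup2")$similarity, 1)
  expect_true(pair("dup1", "dup2")$flagged)
  expect_equal(pair("dup1", "comp")$similarity, 0)
  expect_false(pair("dup1", "comp")$flagged)

  # independent spores share about half their genome
  cross <- sim_cross(cross_config(small_map(60), n_tetrads = 0,
                                  n_selected = 60), seed = 2)
  simi <- genotype_similarity(geno_from_calls(cross$genotypes, small_map(60)))
  expect_equal(mean(simi$similarity), 0.5, tolerance = 0.03)
})

test_that("crossover counts switches between non-missing calls", {
  map <- manual_map(seq(0, 40, by = 10), chrom = "chrI")
  calls <- rbind(parental = rep("B", 5),
                 one_switch = c("B", "B", "W", "W", "W"),
                 with_gap = c("B", NA, "W", NA, "W"))
  xo <- crossover_counts(geno_from_calls(calls, map))
  expect_equal(xo$n_crossovers, c(0L, 1L, 1L), ignore_attr = TRUE)

  # mean crossovers per gamete equals the map length in Morgans
  big <- sim_genetic_map(200, c(chrI = 8e5, chrII = 8e5), seed = 3)
  cross <- sim_cross(cross_config(big, n_tetrads = 0, n_selected = 300),
                     seed = 4)
  xo2 <- crossover_counts(geno_from_calls(cross$genotypes, big))
  morgans <- sum(tapply(big$pos_cM, big$chrom, function(p) diff(range(p)))) / 100
  expect_equal(mean(xo2$n_crossovers), morgans, tolerance = 0.1)
})

test_that("apply_qc removes planted anomalies and records reasons", {
  map <- manual_map(seq(0, 190, by = 10), chrom = "chrI")
  cross <- sim_cross(cross_config(map, n_tetrads = 0, n_selected = 255),
                     seed = 5)
  calls <- cross$genotypes
  # plant a distorted marker (10:90) and a duplicated segregant
  calls[, 3] <- c(rep("B", 26), rep("W", 229))
  calls[2, ] <- calls[1, ]
  calls[2, 5] <- NA   # the copy with more missing data should be dropped
  geno <- geno_from_calls(calls, map)
  res <- apply_qc(geno)
  expect_false(map$marker_id[3] %in% res$genotypes$map$marker_id)
  expect_true("S0002" %in% res$report$id[res$report$entity == "segregant"])
  expect_true("S0001" %in% rownames(res$genotypes$call))
  expect_true(all(c("entity", "id", "statistic", "threshold", "action",
                    "reason") %in% names(res$report)))

  # disabled thresholds leave the data untouched
  off <- apply_qc(geno, qc_thresholds(NA, NA, NA))
  expect_identical(off$genotypes$call, geno$call)
  expect_equal(nrow(off$report), 0)
})

test_that("qc is calibrated and idempotent on clean simulated data", {
  # a genome-scale map: with 16 chromosomes and ~48 crossovers per spore,
  # chance near-clones are vanishingly rare, as in the real cross
  map <- sim_genetic_map(400, seed = 6)
  cross <- sim_cross(cross_config(map, n_tetrads = 60), seed = 7)
  geno <- infer_genotypes(sim_counts(cross, seed = 8))
  res1 <- apply_qc(geno)
  expect_lte(sum(res1$report$entity == "marker"), ceiling(0.01 * nrow(map)))
  expect_equal(sum(res1$report$entity == "segregant"), 0)
  res2 <- apply_qc(res1$genotypes)
  expect_identical(res2$genotypes$call, res1$genotypes$call)
  expect_equal(nrow(res2$report), 0)
})
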