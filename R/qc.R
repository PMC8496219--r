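#' Test markers for segregation distortion
#'
#' In a haploid biallelic cross every marker should segregate 1 B : 1 W among
#' segregants. Each marker's called genotypes are tested against 1:1 by a
#' chi-square goodness-of-fit test with 1 df, excluding missing calls. Markers
#' with fewer than two calls are flagged and left untested.
#'
#' @param geno A `genotype_matrix` from [infer_genotypes()].
#' @return Tibble: `marker_id`, `chrom`, `pos_cM`, `n_B`, `n_W`, `statistic`,
#'   `p_value`, `testable`.
#' @export
segregation_distortion <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n_B <- colSums(geno$call == "B", na.rm = TRUE)
  n_W <- colSums(geno$call == "W", na.rm = TRUE)
  n <- n_B + n_W
  stat <- unname(ifelse(n >= 2, (n_B - n_W)^2 / n, NA_real_))
  tibble(marker_id = geno$map$marker_id, chrom = geno$map$chrom,
         pos_cM = geno$map$pos_cM, n_B = as.integer(n_B),
         n_W = as.integer(n_W), statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         testable = n >= 2)
}

#' Pairwise genotype similarity between segregants
#'
#' For every pair of segregants, the fraction of markers called in both at
#' which the calls agree. Unrelated haploid segregants of a 1:1 cross share
#' about half their genome; near-1 similarity indicates duplicated clones and
#' near-0 a tetrad complement. Pairs with similarity above `threshold`, or
#' with no co-called markers at all, are flagged.
#'
#' @param geno A `genotype_matrix`.
#' @param threshold Similarity above which a pair is flagged. Default 0.90.
#' @return Tibble: `id1`, `id2`, `n_shared`, `similarity`, `flagged`.
#' @export
genotype_similarity <- function(geno, threshold = 0.90) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$call)
  if (n < 2) abort("need at least two segregants")
  # +1 = B, -1 = W, 0 = missing: cross-products count agreements/disagreements
  g <- matrix(0, n, ncol(geno$call))
  g[!is.na(geno$call) & geno$call == "B"] <- 1
  g[!is.na(geno$call) & geno$call == "W"] <- -1
  shared <- abs(g) %*% t(abs(g))      # co-called markers
  agree_minus_disagree <- g %*% t(g)
  sim <- (shared + agree_minus_disagree) / (2 * shared)
  ut <- which(upper.tri(shared), arr.ind = TRUE)
  ids <- rownames(geno$call)
  tibble(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
         n_shared = as.integer(shared[ut]),
         similarity = sim[ut],
         flagged = is.na(sim[ut]) | sim[ut] > threshold)
}

#' Crossover counts per segregant
#'
#' Counts, per segregant, the number of genotype switches between consecutive
#' non-missing calls within each chromosome, summed over chromosomes. Outliers
#' are flagged when the count exceeds both `median + k_mad * MAD` and twice
#' the map expectation (total map length in Morgans, the expected crossover
#' number per gamete under Haldane); taking the larger of the two cutoffs
#' keeps the rule stable on short maps where one heuristic alone is noisy.
#'
#' @param geno A `genotype_matrix`.
#' @param k_mad MAD multiplier for the outlier rule. Default 5.
#' @return Tibble: `segregant_id`, `n_crossovers`, `flagged`.
#' @export
crossover_counts <- function(geno, k_mad = 5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  chrom_idx <- map_chrom_index(geno$map)
  counts <- integer(nrow(geno$call))
  for (idx in chrom_idx) {
    sub <- geno$call[, idx, drop = FALSE]
    counts <- counts + apply(sub, 1, function(calls) {
      calls <- calls[!is.na(calls)]
      if (length(calls) < 2) 0L else sum(calls[-1] != calls[-length(calls)])
    })
  }
  expected <- sum(vapply(chrom_idx, function(idx) {
    diff(range(geno$map$pos_cM[idx]))
  }, numeric(1))) / 100
  cutoff <- max(median(counts) + k_mad * mad(counts), 2 * expected)
  tibble(segregant_id = rownames(geno$call), n_crossovers = counts,
         flagged = counts > cutoff)
}

#' QC thresholds for [apply_qc()]
#'
#' @param distortion_alpha Family-wise significance level for the segregation
#'   distortion filter; each marker is tested at `distortion_alpha / n_markers`
#'   (Bonferroni). `NA` disables. Default 0.05.
#' @param similarity_threshold Genotype identity above which one of a pair of
#'   segregants is dropped. `NA` disables. Default 0.90.
#' @param crossover_k_mad MAD multiplier for the crossover outlier rule. `NA`
#'   disables. Default 5.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(distortion_alpha = 0.05, similarity_threshold = 0.90,
                          crossover_k_mad = 5) {
  structure(list(distortion_alpha = distortion_alpha,
                 similarity_threshold = similarity_threshold,
                 crossover_k_mad = crossover_k_mad),
            class = "qc_thresholds")
}

#' Apply pre-mapping quality control
#'
#' Runs the three diagnostics -- segregation distortion, anomalous genotype
#' similarity, crossover-count outliers -- and removes flagged markers and
#' segregants, producing the clean analysis set. Within a flagged similar
#' pair, the segregant with more missing calls is dropped (ties broken by
#' lexicographic id). All statistics are computed on the input, so the
#' procedure is deterministic and removal-only; every removal is recorded with
#' its reason.
#'
#' @param geno A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_result`: `genotypes` (the cleaned
#'   `genotype_matrix`) and `report` (tibble: `entity`, `id`, `statistic`,
#'   `threshold`, `action`, `reason` -- one row per removal).
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  report <- tibble(entity = character(), id = character(),
                   statistic = numeric(), threshold = numeric(),
                   action = character(), reason = character())
  drop_markers <- character(0)
  drop_segregants <- character(0)

  if (!is.na(thresholds$distortion_alpha)) {
    dist <- segregation_distortion(geno)
    cut <- thresholds$distortion_alpha / sum(dist$testable)
    bad <- dist[dist$testable & !is.na(dist$p_value) & dist$p_value < cut, ]
    drop_markers <- c(drop_markers, bad$marker_id)
    if (nrow(bad) > 0) {
      report <- bind_rows(report, tibble(
        entity = "marker", id = bad$marker_id, statistic = bad$p_value,
        threshold = cut, action = "drop",
        reason = "segregation distortion (Bonferroni chi-square)"))
    }
    untestable <- dist$marker_id[!dist$testable]
    drop_markers <- c(drop_markers, untestable)
    if (length(untestable) > 0) {
      report <- bind_rows(report, tibble(
        entity = "marker", id = untestable, statistic = NA_real_,
        threshold = NA_real_, action = "drop",
        reason = "fewer than two genotype calls"))
    }
  }

  if (!is.na(thresholds$similarity_threshold) && nrow(geno$call) >= 2) {
    sim <- genotype_similarity(geno, thresholds$similarity_threshold)
    miss <- rowSums(is.na(geno$call))
    names(miss) <- rownames(geno$call)
    flagged <- sim[sim$flagged & !is.na(sim$similarity), ]
    if (nrow(flagged) > 0) {
      for (k in seq_len(nrow(flagged))) {
        pair <- c(flagged$id1[k], flagged$id2[k])
        if (any(pair %in% drop_segregants)) next
        loser <- if (miss[pair[1]] != miss[pair[2]]) {
          pair[which.max(miss[pair])]
        } else sort(pair)[2]
        drop_segregants <- c(drop_segregants, loser)
        report <- bind_rows(report, tibble(
          entity = "segregant", id = loser, statistic = flagged$similarity[k],
          threshold = thresholds$similarity_threshold, action = "drop",
          reason = paste0("genotype similarity with ", setdiff(pair, loser))))
      }
    }
  }

  if (!is.na(thresholds$crossover_k_mad)) {
    xo <- crossover_counts(geno, thresholds$crossover_k_mad)
    bad <- xo[xo$flagged, ]
    new <- setdiff(bad$segregant_id, drop_segregants)
    drop_segregants <- c(drop_segregants, new)
    if (length(new) > 0) {
      keep <- bad[bad$segregant_id %in% new, ]
      report <- bind_rows(report, tibble(
        entity = "segregant", id = keep$segregant_id,
        statistic = as.numeric(keep$n_crossovers),
        threshold = NA_real_, action = "drop",
        reason = "crossover count outlier"))
    }
  }

  keep_m <- !geno$map$marker_id %in% drop_markers
  keep_s <- !rownames(geno$call) %in% drop_segregants
  if (!any(keep_m) || !any(keep_s)) {
    abort("QC removed all markers or all segregants; relax the thresholds")
  }
  clean_map <- geno$map[keep_m, ]
  class(clean_map) <- class(geno$map)
  clean <- structure(list(
    call = geno$call[keep_s, keep_m, drop = FALSE],
    posterior_B = geno$posterior_B[keep_s, keep_m, drop = FALSE],
    map = clean_map,
    segregants = geno$segregants[
      geno$segregants$segregant_id %in% rownames(geno$call)[keep_s], ],
    error_rate = geno$error_rate, call_threshold = geno$call_threshold),
    class = "genotype_matrix")
  structure(list(genotypes = clean, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> kept ", nrow(x$genotypes$call), " segregants x ",
      ncol(x$genotypes$call), " markers; removed ",
      sum(x$report$entity == "segregant"), " segregants, ",
      sum(x$report$entity == "marker"), " markers\n", sep = "")
  invisible(x)
}
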