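#' B-allele fraction in sequencing pools
#'
#' For each pool (optionally at a single marker), the proportion of reads
#' matching the B parental allele, with an exact (Clopper-Pearson) binomial
#' confidence interval and the total read count. Zero-depth pool/marker
#' combinations are flagged and get `NA` estimates.
#'
#' @param pools Tibble of pooled counts: `pool_id`, `phenotype`, optional
#'   `stratum`, `marker_id`, `n_B`, `n_W` (as from [sim_pools()] or
#'   [read_pools()]).
#' @param marker Optional `marker_id` to restrict to (e.g. the causal SNP).
#' @param conf_level Confidence level. Default 0.95.
#' @return Tibble: pool columns plus `n`, `fraction_B`, `conf_low`,
#'   `conf_high`, `flagged`.
#' @export
pool_allele_fraction <- function(pools, marker = NULL, conf_level = 0.95) {
  pools <- as_tibble(pools)
  if (!is.null(marker)) {
    pools <- filter(pools, .data$marker_id %in% marker)
    if (nrow(pools) == 0) abort("marker not present in the pool counts")
  }
  ci <- purrr::map2(pools$n_B, pools$n_B + pools$n_W, function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    stats::binom.test(x, n, conf.level = conf_level)$conf.int
  })
  pools |>
    mutate(n = .data$n_B + .data$n_W,
           fraction_B = ifelse(.data$n > 0, .data$n_B / .data$n, NA_real_),
           conf_low = vapply(ci, `[`, numeric(1), 1),
           conf_high = vapply(ci, `[`, numeric(1), 2),
           flagged = .data$n == 0)
}

#' Contrast B-allele enrichment between phenotype-sorted pools
#'
#' Aggregates read counts at a marker within the haploid-derived and the
#' diploid-derived pools and tests equality of the two B-allele proportions by
#' a two-proportion chi-square test (1 df, no continuity correction by
#' default). `direction` is the sign of `fraction_diploid - fraction_haploid`:
#' +1 means the diploid pools are enriched for the B allele. With `by`, the
#' contrast is computed separately per covariate stratum (e.g. auxotrophy
#' class) in addition to the headline all-strata contrast.
#'
#' @param pools Pool counts tibble (see [pool_allele_fraction()]).
#' @param marker `marker_id` at which to test.
#' @param by Optional column name (e.g. `"stratum"`) for a stratified
#'   contrast.
#' @param correct Apply Yates continuity correction. Default `FALSE`.
#' @return Tibble with one row per contrast: `stratum` (`"all"` for the
#'   pooled contrast), fractions, `statistic`, `p_value`, `direction`.
#' @export
compare_pools <- function(pools, marker, by = NULL, correct = FALSE) {
  pools <- filter(as_tibble(pools), .data$marker_id == marker)
  if (nrow(pools) == 0) abort("marker not present in the pool counts")
  one_test <- function(d, label) {
    agg <- d |>
      group_by(.data$phenotype) |>
      summarise(n_B = sum(.data$n_B), n_W = sum(.data$n_W))
    if (!all(c("haploid", "diploid") %in% agg$phenotype) ||
        any(agg$n_B + agg$n_W == 0)) {
      abort("both haploid and diploid pools must have reads at the marker")
    }
    hap <- agg[agg$phenotype == "haploid", ]
    dip <- agg[agg$phenotype == "diploid", ]
    f_h <- hap$n_B / (hap$n_B + hap$n_W)
    f_d <- dip$n_B / (dip$n_B + dip$n_W)
    if (f_h == f_d) {
      stat <- 0; p <- 1
    } else {
      tst <- stats::prop.test(c(dip$n_B, hap$n_B),
                              c(dip$n_B + dip$n_W, hap$n_B + hap$n_W),
                              correct = correct)
      stat <- unname(tst$statistic); p <- tst$p.value
    }
    tibble(stratum = label, fraction_haploid = f_h, fraction_diploid = f_d,
           statistic = stat, p_value = p, direction = sign(f_d - f_h))
  }
  out <- one_test(pools, "all")
  if (!is.null(by)) {
    if (!by %in% names(pools)) abort(paste0("no column '", by, "' in pools"))
    strata <- split(pools, pools[[by]])
    out <- bind_rows(out, purrr::imap(strata, one_test) |> bind_rows())
  }
  out
}
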