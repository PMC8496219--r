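#' Build a genetic map of biallelic markers
#'
#' A genetic map is a tibble of ordered biallelic markers, one row per marker,
#' with physical (`pos_bp`) and genetic (`pos_cM`) coordinates and the two
#' parental alleles. It underlies every stage of the pipeline: the Haldane map
#' function converts inter-marker genetic distances into recombination
#' fractions for both the cross simulator and the genotype HMM.
#'
#' If `pos_cM` is absent it is derived from physical positions at a constant
#' rate (default 0.4 cM/kb, i.e. 1 cM per 2.5 kb, the yeast genome-wide
#' average), measured from the first marker of each chromosome.
#'
#' @param markers Data frame with columns `marker_id`, `chrom`, `pos_bp`, the
#'   parental alleles `allele_B` and `allele_W` (single nucleotides), and
#'   optionally `pos_cM`.
#' @param cM_per_kb Physical-to-genetic conversion rate used when `pos_cM` is
#'   missing. Default 0.4 cM/kb.
#' @return A tibble of class `genetic_map`, ordered by (chromosome, `pos_bp`).
#'   Chromosomes keep their order of first appearance.
#' @examples
#' genetic_map(data.frame(
#'   marker_id = c("m1", "m2"), chrom = "chrI", pos_bp = c(1000, 26000),
#'   allele_B = c("A", "G"), allele_W = c("T", "C")
#' ))
#' @export
genetic_map <- function(markers, cM_per_kb = 0.4) {
  markers <- as_tibble(markers)
  need <- c("marker_id", "chrom", "pos_bp", "allele_B", "allele_W")
  missing_cols <- setdiff(need, names(markers))
  if (length(missing_cols) > 0) {
    abort(paste0("genetic map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(markers) == 0) abort("genetic map has no markers")
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  chrom_order <- unique(markers$chrom)
  markers <- markers[order(match(markers$chrom, chrom_order), markers$pos_bp), ]
  if (!"pos_cM" %in% names(markers) || all(is.na(markers$pos_cM))) {
    markers <- markers |>
      group_by(.data$chrom) |>
      mutate(pos_cM = (.data$pos_bp - min(.data$pos_bp)) / 1000 * cM_per_kb) |>
      ungroup()
  }
  markers <- markers[, c("marker_id", "chrom", "pos_bp", "pos_cM",
                         "allele_B", "allele_W")]
  validate_genetic_map(markers)
  class(markers) <- c("genetic_map", class(tibble()))
  markers
}

validate_genetic_map <- function(map) {
  if (nrow(map) == 0) abort("genetic map has no markers")
  if (anyDuplicated(map$marker_id) > 0) abort("marker_ids must be unique")
  if (any(map$pos_bp < 1)) abort("pos_bp must be >= 1")
  if (any(map$pos_cM < 0)) abort("pos_cM must be >= 0")
  if (any(map$allele_B == map$allele_W)) {
    abort("allele_B and allele_W must differ at every marker")
  }
  bad <- map |>
    group_by(.data$chrom) |>
    summarise(ok = !is.unsorted(.data$pos_cM) && !is.unsorted(.data$pos_bp)) |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("markers not ordered by position on chromosome(s): ",
                 paste(bad$chrom, collapse = ", ")))
  }
  invisible(map)
}

is_genetic_map <- function(x) inherits(x, "genetic_map")

assert_genetic_map <- function(map) {
  if (!is_genetic_map(map)) map <- genetic_map(map)
  map
}

#' Chromosome sizes of the S. cerevisiae (S288C) nuclear genome
#'
#' @return Named numeric vector of chromosome lengths in bp, chrI-chrXVI.
#' @export
yeast_chromosomes <- function() {
  c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
    chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
    chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
    chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)
}

#' Simulate a biallelic marker map
#'
#' Draws marker positions uniformly along each chromosome, allocating markers
#' to chromosomes in proportion to physical size, and assigns distinct parental
#' alleles at random. The default emulates a dense map of a laboratory yeast
#' cross: 8505 SNP markers over the sixteen nuclear chromosomes, with genetic
#' positions at 0.4 cM/kb.
#'
#' @param n_markers Total number of markers. Default 8505.
#' @param chromosomes Named numeric vector of chromosome sizes in bp. Default
#'   [yeast_chromosomes()].
#' @param cM_per_kb Physical-to-genetic conversion rate. Default 0.4.
#' @param seed Optional integer seed for reproducibility.
#' @return A [genetic_map()] tibble.
#' @examples
#' sim_genetic_map(n_markers = 50, chromosomes = c(chrI = 2e5, chrII = 3e5),
#'                 seed = 1)
#' @export
sim_genetic_map <- function(n_markers = 8505, chromosomes = yeast_chromosomes(),
                            cM_per_kb = 0.4, seed = NULL) {
  stopifnot(n_markers >= length(chromosomes), all(chromosomes > 0))
  with_seed_(seed, {
    alloc <- pmax(1, round(n_markers * chromosomes / sum(chromosomes)))
    # fix rounding drift so totals match exactly
    while (sum(alloc) != n_markers) {
      i <- if (sum(alloc) > n_markers) which.max(alloc) else which.min(alloc)
      alloc[i] <- alloc[i] + sign(n_markers - sum(alloc))
    }
    nt <- c("A", "C", "G", "T")
    markers <- purrr::map2(names(chromosomes), alloc, function(chr, k) {
      pos <- sort(sample.int(chromosomes[[chr]], k))
      a_B <- sample(nt, k, replace = TRUE)
      a_W <- vapply(a_B, function(a) sample(setdiff(nt, a), 1), character(1))
      tibble(marker_id = sprintf("%s_%05d", chr, seq_len(k)), chrom = chr,
             pos_bp = pos, allele_B = a_B, allele_W = unname(a_W))
    }) |> bind_rows()
    genetic_map(markers, cM_per_kb = cM_per_kb)
  })
}

# Split row indices of a map by chromosome, preserving map order.
map_chrom_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}
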