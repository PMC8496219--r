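#' Haldane map function
#'
#' Converts a genetic distance in centimorgans into a recombination fraction
#' under the Haldane (no-interference) model, r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM Genetic distance(s) in cM, non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 10, 1e6))
#' @export
haldane_r <- function(d_cM) {
  if (any(is.na(d_cM)) || any(d_cM < 0)) {
    abort("genetic distances must be non-negative")
  }
  0.5 * (1 - exp(-d_cM / 50))
}

#' Configure a synthetic F1 cross
#'
#' Bundles the parameters of the generative model: a tetrad-structured cross of
#' two haploid parents (B and W), a single causal biallelic locus acting on a
#' binary phenotype through allele-specific penetrances, and a sparse
#' sequencing-count emission. Defaults mirror the mapping experiment the model
#' emulates: 65 dissected tetrads (260 spores), penetrances 0.69 (B allele)
#' versus 0.18 (W allele), ~5X mean coverage, and a 0.5% per-read error rate.
#'
#' @param map A [genetic_map()].
#' @param causal_marker `marker_id` of the causal locus. Default: the marker
#'   nearest chrIV:1,044,000 (the SSD1 coding region) when the map has a
#'   chromosome named `chrIV`, otherwise the marker in the middle of the map.
#' @param n_tetrads Number of dissected tetrads (4 spores each). Default 65.
#' @param n_selected Number of additional bulk-selected spores simulated as
#'   independent gametes without tetrad structure. Default 0.
#' @param penetrance_B,penetrance_W Probability that a population founded by a
#'   carrier of the B (resp. W) allele at the causal locus expresses the
#'   phenotype (diploidizes). Defaults 0.69 and 0.18.
#' @param mean_depth Expected sequencing reads per marker per segregant
#'   (Poisson mean). Default 5.
#' @param error_rate Per-read probability of reporting the wrong parental
#'   allele, symmetric between alleles. Default 0.005.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(map, causal_marker = NULL, n_tetrads = 65,
                         n_selected = 0, penetrance_B = 0.69,
                         penetrance_W = 0.18, mean_depth = 5,
                         error_rate = 0.005) {
  map <- assert_genetic_map(map)
  if (is.null(causal_marker)) causal_marker <- default_causal_marker(map)
  if (!causal_marker %in% map$marker_id) {
    abort(paste0("causal_marker '", causal_marker, "' is not in the map"))
  }
  stopifnot(n_tetrads >= 0, n_selected >= 0, n_tetrads + n_selected > 0,
            penetrance_B >= 0, penetrance_B <= 1,
            penetrance_W >= 0, penetrance_W <= 1,
            mean_depth >= 0, error_rate >= 0, error_rate < 0.5)
  structure(list(map = map, causal_marker = causal_marker,
                 n_tetrads = as.integer(n_tetrads),
                 n_selected = as.integer(n_selected),
                 penetrance_B = penetrance_B, penetrance_W = penetrance_W,
                 mean_depth = mean_depth, error_rate = error_rate),
            class = "cross_config")
}

default_causal_marker <- function(map) {
  if ("chrIV" %in% map$chrom) {
    on_iv <- map[map$chrom == "chrIV", ]
    on_iv$marker_id[which.min(abs(on_iv$pos_bp - 1044000))]
  } else {
    map$marker_id[ceiling(nrow(map) / 2)]
  }
}

# n independent gametes as an n x m logical matrix (TRUE = B allele), built
# per chromosome as a two-state Markov chain with Haldane switch probabilities.
sim_gametes <- function(map, n) {
  m <- nrow(map)
  geno <- matrix(NA, n, m)
  for (idx in map_chrom_index(map)) {
    L <- length(idx)
    r <- haldane_r(diff(map$pos_cM[idx]))
    s <- matrix(NA, n, L)
    s[, 1] <- runif(n) < 0.5
    if (L > 1) {
      for (j in 2:L) {
        s[, j] <- xor(s[, j - 1], runif(n) < r[j - 1])
      }
    }
    geno[, idx] <- s
  }
  geno
}

#' Simulate one tetrad of four spores
#'
#' A tetrad is generated as \{s1, complement(s1), s2, complement(s2)\} from two
#' independent Haldane-process gametes s1 and s2. This guarantees exact 2:2
#' segregation of every marker within the tetrad and gives each single spore
#' the correct marginal recombination process; chromatid interference is not
#' modeled.
#'
#' @param map A [genetic_map()].
#' @param seed Optional integer seed.
#' @return A 4 x n_markers character matrix over `{"B", "W"}`, with marker ids
#'   as column names.
#' @examples
#' simulate_tetrad(sim_genetic_map(20, c(chrI = 1e5), seed = 1), seed = 2)
#' @export
simulate_tetrad <- function(map, seed = NULL) {
  map <- assert_genetic_map(map)
  with_seed_(seed, {
    g <- sim_gametes(map, 2)
    out <- rbind(g[1, ], !g[1, ], g[2, ], !g[2, ])
    geno_chr <- ifelse(out, "B", "W")
    dimnames(geno_chr) <- list(paste0("spore", 1:4), map$marker_id)
    geno_chr
  })
}

#' Simulate a tetrad-structured F1 cross with a binary phenotype
#'
#' Generates `n_tetrads` tetrads (plus optional bulk-selected independent
#' spores), then assigns each segregant a binary phenotype by the single-locus
#' penetrance model of the [cross_config()]: carriers of the B allele at the
#' causal marker express the phenotype with probability `penetrance_B`, W
#' carriers with `penetrance_W`, independently across segregants.
#'
#' @param config A [cross_config()].
#' @param seed Optional integer seed; the same seed reproduces the cross
#'   bit-identically.
#' @return A list of class `sim_cross` with elements `config`, `map`,
#'   `genotypes` (segregant x marker character matrix over `{"B","W"}`), and
#'   `segregants` (tibble with `segregant_id`, `tetrad` -- `NA` for
#'   bulk-selected spores -- and `phenotype` in \{0 haploid, 1 diploid\}).
#' @export
sim_cross <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cross_config"))
  map <- config$map
  with_seed_(seed, {
    nt <- config$n_tetrads
    rows <- list()
    tetrad <- integer(0)
    if (nt > 0) {
      g1 <- sim_gametes(map, nt)
      g2 <- sim_gametes(map, nt)
      tet <- matrix(NA, 4 * nt, nrow(map))
      tet[seq(1, 4 * nt, by = 4), ] <- g1
      tet[seq(2, 4 * nt, by = 4), ] <- !g1
      tet[seq(3, 4 * nt, by = 4), ] <- g2
      tet[seq(4, 4 * nt, by = 4), ] <- !g2
      rows <- c(rows, list(tet))
      tetrad <- rep(seq_len(nt), each = 4)
    }
    if (config$n_selected > 0) {
      rows <- c(rows, list(sim_gametes(map, config$n_selected)))
      tetrad <- c(tetrad, rep(NA_integer_, config$n_selected))
    }
    geno <- do.call(rbind, rows)
    ids <- character(nrow(geno))
    if (nt > 0) {
      ids[seq_len(4 * nt)] <- paste0("T", sprintf("%03d", rep(seq_len(nt), each = 4)),
                                     "_s", rep(1:4, nt))
    }
    if (config$n_selected > 0) {
      ids[4 * nt + seq_len(config$n_selected)] <-
        sprintf("S%04d", seq_len(config$n_selected))
    }
    geno_chr <- ifelse(geno, "B", "W")
    dimnames(geno_chr) <- list(ids, map$marker_id)
    cross <- structure(
      list(config = config, map = map, genotypes = geno_chr,
           segregants = tibble(segregant_id = ids, tetrad = tetrad,
                               phenotype = NA_integer_)),
      class = "sim_cross")
    cross$segregants$phenotype <- assign_phenotypes(cross, config)
    cross
  })
}

#' Draw binary phenotypes under the single-locus penetrance model
#'
#' @param cross A `sim_cross` object (or a segregant x marker genotype matrix
#'   over `{"B","W"}` with marker ids as column names).
#' @param config A [cross_config()] supplying `causal_marker`, `penetrance_B`
#'   and `penetrance_W`.
#' @param seed Optional integer seed. Defaults to `NULL` so that
#'   [sim_cross()] can draw phenotypes inside its own seeded stream.
#' @return Integer vector of phenotypes (0 = haploid, 1 = diploid), one per
#'   segregant.
#' @export
assign_phenotypes <- function(cross, config, seed = NULL) {
  geno <- if (inherits(cross, "sim_cross")) cross$genotypes else cross
  if (!config$causal_marker %in% colnames(geno)) {
    abort("causal marker not genotyped in this cross")
  }
  with_seed_(seed, {
    carrier_B <- geno[, config$causal_marker] == "B"
    p <- ifelse(carrier_B, config$penetrance_B, config$penetrance_W)
    rbinom(length(p), 1, p)
  })
}

#' Simulate sparse per-marker allele read counts
#'
#' The forward model of the genotyping data: per segregant and marker, total
#' depth is Poisson(`mean_depth`); reads matching the segregant's true parental
#' allele are Binomial(depth, 1 - `error_rate`), the remainder are attributed
#' to the other allele (symmetric error).
#'
#' @param cross A `sim_cross` object.
#' @param mean_depth,error_rate Override the values in the cross's config.
#' @param seed Optional integer seed.
#' @return A list of class `allele_counts` with elements `map`, `segregants`,
#'   and integer matrices `n_B`, `n_W` (segregant x marker).
#' @export
sim_counts <- function(cross, mean_depth = NULL, error_rate = NULL,
                       seed = NULL) {
  stopifnot(inherits(cross, "sim_cross"))
  mean_depth <- mean_depth %||% cross$config$mean_depth
  error_rate <- error_rate %||% cross$config$error_rate
  geno <- cross$genotypes
  with_seed_(seed, {
    nm <- length(geno)
    depth <- rpois(nm, mean_depth)
    n_true <- rbinom(nm, depth, 1 - error_rate)
    is_B <- geno == "B"
    n_B <- matrix(ifelse(is_B, n_true, depth - n_true), nrow(geno))
    n_W <- matrix(depth, nrow(geno)) - n_B
    dimnames(n_B) <- dimnames(n_W) <- dimnames(geno)
    structure(list(map = cross$map, segregants = cross$segregants,
                   n_B = n_B, n_W = n_W),
              class = "allele_counts")
  })
}

#' Simulate phenotype-sorted pooled sequencing
#'
#' Segregants are grouped into pools by phenotype (haploid vs diploid),
#' optionally crossed with user-supplied strata (e.g. auxotrophy classes, as
#' when eight Lys x Trp x ploidy pools are sequenced). For each pool and
#' marker, `depth` reads are drawn with the B-matching probability
#' `f(1 - error_rate) + (1 - f)error_rate`, where `f` is the B-allele
#' frequency among the pooled segregants.
#'
#' @param cross A `sim_cross` object.
#' @param depth Reads per marker per pool. Default 1000.
#' @param strata Optional factor/character vector (one per segregant) of
#'   covariate classes; pools are formed per phenotype x stratum combination.
#' @param error_rate Per-read error; defaults to the cross config's value.
#' @param seed Optional integer seed.
#' @return Long tibble of class `pool_counts`: `pool_id`, `phenotype`
#'   (`"haploid"`/`"diploid"`), `stratum`, `marker_id`, `n_B`, `n_W`.
#' @export
sim_pools <- function(cross, depth = 1000, strata = NULL, error_rate = NULL,
                      seed = NULL) {
  stopifnot(inherits(cross, "sim_cross"), depth >= 1)
  error_rate <- error_rate %||% cross$config$error_rate
  pheno <- ifelse(cross$segregants$phenotype == 1, "diploid", "haploid")
  strata <- if (is.null(strata)) rep("all", nrow(cross$genotypes))
            else as.character(strata)
  stopifnot(length(strata) == nrow(cross$genotypes))
  groups <- split(seq_len(nrow(cross$genotypes)),
                  list(pheno = pheno, stratum = strata), sep = "|", drop = TRUE)
  if (!all(c("haploid", "diploid") %in% pheno)) {
    abort("cannot sequence an empty pool: need both phenotype classes")
  }
  with_seed_(seed, {
    purrr::imap(groups, function(rows, key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      f <- colMeans(cross$genotypes[rows, , drop = FALSE] == "B")
      p <- f * (1 - error_rate) + (1 - f) * error_rate
      n_B <- rbinom(length(p), depth, p)
      tibble(pool_id = paste0(parts[1],
                              ifelse(parts[2] == "all", "", paste0("_", parts[2]))),
             phenotype = parts[1], stratum = parts[2],
             marker_id = cross$map$marker_id,
             n_B = n_B, n_W = depth - n_B)
    }) |>
      bind_rows() |>
      structure(class = c("pool_counts", class(tibble())))
  })
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("<sim_cross> ", nrow(x$genotypes), " segregants (",
      x$config$n_tetrads, " tetrads + ", x$config$n_selected,
      " selected) x ", ncol(x$genotypes), " markers\n",
      "  causal locus ", x$config$causal_marker,
      ", penetrances B=", x$config$penetrance_B,
      " W=", x$config$penetrance_W, "\n",
      "  diploidized: ", sum(x$segregants$phenotype), "/",
      nrow(x$segregants), "\n", sep = "")
  invisible(x)
}

#' Diploid spores per tetrad
#'
#' Tabulates, for each dissected tetrad, how many of its four spore-derived
#' populations expressed the phenotype -- the tetrad spectrum that a 2:2
#' segregating causal locus shapes.
#'
#' @param cross A `sim_cross` object with tetrad spores.
#' @return Tibble with `tetrad` and `n_diploid` (0-4).
#' @export
tetrad_spectrum <- function(cross) {
  stopifnot(inherits(cross, "sim_cross"))
  cross$segregants |>
    filter(!is.na(.data$tetrad)) |>
    group_by(.data$tetrad) |>
    summarise(n_diploid = sum(.data$phenotype))
}
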