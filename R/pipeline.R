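# Orchestration: configuration, seeding, logging, and the end-to-end run
# binding simulate -> genotype -> qc -> scan -> stepwise -> effects -> pools.

config_schema <- list(
  seed = NULL,
  files = c("map", "counts", "phenotypes", "pools"),
  simulate = c("n_markers", "n_tetrads", "n_selected", "penetrance_B",
               "penetrance_W", "mean_depth", "error_rate", "causal_marker",
               "pool_depth"),
  genotype = c("error_rate", "call_threshold"),
  qc = c("distortion_alpha", "similarity_threshold", "crossover_k_mad"),
  scan = c("method", "step_cM", "n_perm", "alpha"),
  stepwise = c("n_train", "max_qtl", "chromosomes", "n_perm"),
  pools = c("marker", "by")
)

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file) with optional sections
#' `files` (paths to `map`, `counts`, `phenotypes`, `pools` TSVs),
#' `simulate` (synthetic-cross parameters used when no input files are given),
#' and per-stage parameter sections `genotype`, `qc`, `scan`, `stepwise`,
#' `pools`, plus a global `seed`. Unknown keys are rejected; numeric
#' parameters are range-checked before any work starts.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad) > 0) {
    abort(paste0("unknown config section(s): ", paste(bad, collapse = ", ")))
  }
  for (section in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[section]]), config_schema[[section]])
    if (length(bad) > 0) {
      abort(paste0("unknown key(s) in config section '", section, "': ",
                   paste(bad, collapse = ", ")))
    }
  }
  np <- config$scan$n_perm
  if (!is.null(np) && np < 100) abort("scan.n_perm must be at least 100")
  np <- config$stepwise$n_perm
  if (!is.null(np) && np < 100) abort("stepwise.n_perm must be at least 100")
  for (key in c("error_rate")) {
    v <- config$genotype[[key]]
    if (!is.null(v) && (v < 0 || v >= 0.5)) {
      abort("genotype.error_rate must be in [0, 0.5)")
    }
  }
  structure(config, class = "pipeline_config")
}

# Per-stage seeds derived from one global seed: independent reruns of a stage
# reproduce it without replaying earlier stages. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 1, counts = 2, phenotype = 3, pools = 4,
               permutation = 5, split = 6, stepwise = 7)
  (as.integer(seed) + 10007L * offsets[[stage]]) %% 2147483647L
}

pipeline_log <- function(log_path) {
  function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (reading the configured map / counts /
#' phenotype / pool files, or generating them with the cross simulator), HMM
#' genotype inference, quality control, the single-QTL genome scan with a
#' permutation threshold, a regress-out rescan at the peak, the stepwise
#' multi-QTL search on a training split with held-out fitting, position
#' refinement and allele-effect estimation, and the pooled-sample enrichment
#' contrast. Every intermediate artifact is written under `outdir`, along with
#' a manifest (package version, seed, full parameter set) sufficient to
#' reproduce the run bit-identically.
#'
#' @param config A [pipeline_config()] (or list / YAML path accepted by it).
#' @param outdir Output directory (created if needed).
#' @param seed Global integer seed; expanded into fixed per-stage seeds.
#' @return Invisibly, a list: `genotypes`, `qc`, `scan`, `rescan`, `model`,
#'   `effects`, `pool_tests` (when pools exist), and `manifest`.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  config <- pipeline_config(config)
  seed <- seed %||% config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- pipeline_log(file.path(outdir, "pipeline.log"))
  log("pipeline start (seed ", seed %||% "none", ")")

  # --- inputs -----------------------------------------------------------
  sim <- config$simulate %||% list()
  cross <- NULL
  if (!is.null(config$files$map)) {
    map <- read_genetic_map(config$files$map)
    log("read map: ", nrow(map), " markers")
  } else {
    map <- sim_genetic_map(n_markers = sim$n_markers %||% 8505,
                           seed = stage_seed(seed, "simulate"))
    log("simulated map: ", nrow(map), " markers")
  }
  if (!is.null(config$files$counts)) {
    counts <- read_counts(config$files$counts, map)
    phenotypes <- read_phenotypes(config$files$phenotypes)
    log("read counts for ", nrow(counts$n_B), " segregants")
  } else {
    cfg <- cross_config(map,
                        causal_marker = sim$causal_marker,
                        n_tetrads = sim$n_tetrads %||% 65,
                        n_selected = sim$n_selected %||% 0,
                        penetrance_B = sim$penetrance_B %||% 0.69,
                        penetrance_W = sim$penetrance_W %||% 0.18,
                        mean_depth = sim$mean_depth %||% 5,
                        error_rate = sim$error_rate %||% 0.005)
    cross <- sim_cross(cfg, seed = stage_seed(seed, "simulate"))
    counts <- sim_counts(cross, seed = stage_seed(seed, "counts"))
    phenotypes <- cross$segregants
    write_phenotypes(phenotypes, file.path(outdir, "phenotypes.tsv"))
    write_counts(counts, file.path(outdir, "counts.tsv"))
    log("simulated cross: ", nrow(cross$genotypes), " segregants, causal ",
        cfg$causal_marker)
  }
  write_genetic_map(map, file.path(outdir, "map.tsv"))

  # --- genotype + qc ----------------------------------------------------
  geno <- infer_genotypes(counts,
                          error_rate = config$genotype$error_rate %||% 0.005,
                          call_threshold = config$genotype$call_threshold %||% 0.95)
  geno$segregants <- phenotypes
  write_genotypes(geno, file.path(outdir, "genotypes.tsv"))
  log("genotyped: ", round(100 * mean(is.na(geno$call)), 2), "% missing calls")
  qc <- apply_qc(geno, qc_thresholds(
    distortion_alpha = config$qc$distortion_alpha %||% 0.05,
    similarity_threshold = config$qc$similarity_threshold %||% 0.90,
    crossover_k_mad = config$qc$crossover_k_mad %||% 5))
  readr::write_tsv(qc$report, file.path(outdir, "qc_report.tsv"))
  log("qc: kept ", nrow(qc$genotypes$call), " segregants x ",
      ncol(qc$genotypes$call), " markers")

  # --- single-QTL scan --------------------------------------------------
  probs <- genotype_probs(qc$genotypes,
                          step_cM = config$scan$step_cM %||% 1,
                          error_rate = config$genotype$error_rate %||% 0.005)
  scan <- permutation_threshold(
    probs, phenotypes, n_perm = config$scan$n_perm %||% 1000,
    alpha = config$scan$alpha %||% 0.05,
    seed = stage_seed(seed, "permutation"),
    method = config$scan$method %||% "hk")
  write_scan(scan, file.path(outdir, "scan.tsv"))
  peak <- which.max(scan$lod)
  log("scan peak LOD ", round(max(scan$lod), 2), " at ", scan$chrom[peak],
      ":", round(scan$pos_cM[peak], 1), " (threshold ",
      round(attr(scan, "threshold"), 2), ")")
  rescan <- scan_regressout(probs, phenotypes, peak,
                            method = config$scan$method %||% "hk")
  write_scan(rescan, file.path(outdir, "scan_regressout.tsv"))
  log("regress-out rescan max LOD ", round(max(rescan$lod), 2))

  # --- multi-QTL model --------------------------------------------------
  pheno_split <- split_data(
    phenotypes[phenotypes$segregant_id %in% rownames(probs$prob_B), ],
    n_train = min(config$stepwise$n_train %||% 150,
                  nrow(probs$prob_B) - 2L),
    seed = stage_seed(seed, "split"))
  train_ids <- pheno_split$segregant_id[pheno_split$split == "train"]
  test_ids <- pheno_split$segregant_id[pheno_split$split == "test"]
  model <- stepwise_search(
    subset_probs(probs, train_ids),
    pheno_split[pheno_split$split == "train", ],
    max_qtl = config$stepwise$max_qtl %||% 4,
    chromosomes = config$stepwise$chromosomes,
    n_perm = config$stepwise$n_perm %||% 1000,
    seed = stage_seed(seed, "stepwise"))
  log("stepwise model: ", nrow(model$loci), " loci, ",
      length(model$interactions), " interactions, train LOD ",
      round(model$model_lod, 2))
  effects <- NULL
  if (nrow(model$loci) > 0) {
    test_probs <- subset_probs(probs, test_ids)
    test_pheno <- pheno_split[pheno_split$split == "test", ]
    model <- fit_model(test_probs, test_pheno, model)
    model <- refine_positions(test_probs, test_pheno, model)
    model <- fit_model(test_probs, test_pheno, model)
    effects <- model$effects
    readr::write_tsv(effects, file.path(outdir, "effects.tsv"))
    log("held-out fit: LOD ", round(model$model_lod, 2), ", variance explained ",
        round(100 * model$variance_explained, 1), "%")
  }
  write_model(model, file.path(outdir, "model.json"))

  # --- pools ------------------------------------------------------------
  pool_tests <- NULL
  pools <- NULL
  if (!is.null(config$files$pools)) {
    pools <- read_pools(config$files$pools)
  } else if (!is.null(cross)) {
    pools <- sim_pools(cross, depth = sim$pool_depth %||% 1000,
                       seed = stage_seed(seed, "pools"))
    write_pools(pools, file.path(outdir, "pools.tsv"))
  }
  if (!is.null(pools)) {
    target <- config$pools$marker %||% {
      # nearest genotyped marker to the scan peak
      on_chrom <- map[map$chrom == scan$chrom[peak], ]
      on_chrom$marker_id[which.min(abs(on_chrom$pos_cM - scan$pos_cM[peak]))]
    }
    pool_tests <- compare_pools(pools, target, by = config$pools$by)
    readr::write_tsv(pool_tests, file.path(outdir, "pool_tests.tsv"))
    log("pool contrast at ", target, ": diploid B fraction ",
        round(pool_tests$fraction_diploid[1], 3), " vs haploid ",
        round(pool_tests$fraction_haploid[1], 3),
        " (p ", signif(pool_tests$p_value[1], 3), ")")
  }

  manifest <- list(
    package = "tetradqtl",
    version = as.character(packageVersion("tetradqtl")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log("pipeline done")
  invisible(list(genotypes = geno, qc = qc, scan = scan, rescan = rescan,
                 model = model, effects = effects, pool_tests = pool_tests,
                 manifest = manifest))
}
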