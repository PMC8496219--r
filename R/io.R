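# Readers and writers for the pipeline's plain-text interchange formats.
# All tables are tab-separated with a header row; bp positions are 1-based.

read_tsv_ <- function(path, col_types) {
  out <- readr::read_tsv(path, col_types = col_types, progress = FALSE)
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(paste0("malformed row(s) in ", path, ": line ",
                 paste(unique(prob$row), collapse = ", ")))
  }
  out
}

#' Read / write a marker map TSV
#'
#' Columns: `marker_id`, `chrom`, `pos_bp`, `pos_cM` (optional on read),
#' `allele_B`, `allele_W`.
#'
#' @param path File path.
#' @param cM_per_kb Conversion used when `pos_cM` is absent (see
#'   [genetic_map()]).
#' @return `read_genetic_map()`: a [genetic_map()] tibble.
#' @export
read_genetic_map <- function(path, cM_per_kb = 0.4) {
  tbl <- read_tsv_(path, readr::cols(
    marker_id = "c", chrom = "c", pos_bp = "i",
    allele_B = "c", allele_W = "c", .default = "d"))
  genetic_map(tbl, cM_per_kb = cM_per_kb)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Read / write allele counts (long TSV)
#'
#' Columns: `segregant_id`, `marker_id`, `n_B`, `n_W`. Rows may omit
#' zero-coverage markers; missing cells are zero-coverage.
#'
#' @param path File path.
#' @param map A [genetic_map()] the counts refer to.
#' @return `read_counts()`: an `allele_counts` object.
#' @export
read_counts <- function(path, map) {
  tbl <- read_tsv_(path, readr::cols(segregant_id = "c", marker_id = "c",
                                     n_B = "i", n_W = "i"))
  as_allele_counts(tbl, map)
}

#' @rdname read_counts
#' @param counts An `allele_counts` object.
#' @param drop_zero Omit zero-coverage cells from the file. Default `TRUE`.
#' @export
write_counts <- function(counts, path, drop_zero = TRUE) {
  tbl <- tibble(
    segregant_id = rep(rownames(counts$n_B), ncol(counts$n_B)),
    marker_id = rep(colnames(counts$n_B), each = nrow(counts$n_B)),
    n_B = as.vector(counts$n_B), n_W = as.vector(counts$n_W)) |>
    arrange(match(.data$segregant_id, rownames(counts$n_B)),
            match(.data$marker_id, colnames(counts$n_B)))
  if (drop_zero) tbl <- filter(tbl, .data$n_B + .data$n_W > 0)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read / write a genotype matrix
#'
#' The call matrix is a segregants x markers TSV with cells in
#' `{B, W, NA}` and a `segregant_id` first column; a companion
#' `<path>.posterior.tsv` holds the posterior P(B) matrix.
#'
#' @param path File path of the call matrix.
#' @param map A [genetic_map()].
#' @return `read_genotypes()`: a `genotype_matrix`.
#' @export
read_genotypes <- function(path, map) {
  map <- assert_genetic_map(map)
  tbl <- read_tsv_(path, readr::cols(segregant_id = "c", .default = "c"))
  if (!identical(setdiff(names(tbl), "segregant_id"), map$marker_id)) {
    abort("genotype matrix columns do not match the map's markers")
  }
  call <- as.matrix(tbl[, -1])
  rownames(call) <- tbl$segregant_id
  geno <- as_genotype_matrix(call, map)
  ppath <- paste0(path, ".posterior.tsv")
  if (file.exists(ppath)) {
    ptbl <- read_tsv_(ppath, readr::cols(segregant_id = "c", .default = "d"))
    post <- as.matrix(ptbl[, -1])
    rownames(post) <- ptbl$segregant_id
    geno$posterior_B <- post[rownames(call), map$marker_id]
  }
  geno
}

#' @rdname read_genotypes
#' @param geno A `genotype_matrix`.
#' @export
write_genotypes <- function(geno, path) {
  tbl <- as_tibble(geno$call, rownames = "segregant_id")
  readr::write_tsv(tbl, path, na = "NA")
  ptbl <- as_tibble(geno$posterior_B, rownames = "segregant_id")
  readr::write_tsv(ptbl, paste0(path, ".posterior.tsv"))
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Columns: `segregant_id`, `tetrad` (integer or NA for bulk-selected spores),
#' `phenotype` (0 = haploid, 1 = diploid).
#'
#' @param path File path.
#' @return `read_phenotypes()`: a tibble.
#' @export
read_phenotypes <- function(path) {
  tbl <- read_tsv_(path, readr::cols(segregant_id = "c", tetrad = "i",
                                     phenotype = "i"))
  if (!all(tbl$phenotype %in% c(0L, 1L))) {
    abort("phenotype must be 0 (haploid) or 1 (diploid)")
  }
  tbl
}

#' @rdname read_phenotypes
#' @param phenotypes Tibble with `segregant_id`, `tetrad`, `phenotype`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(as_tibble(phenotypes), path)
  invisible(path)
}

#' Read / write pooled counts
#'
#' Columns: `pool_id`, `phenotype` (`haploid`/`diploid`), `stratum`,
#' `marker_id`, `n_B`, `n_W`.
#'
#' @param path File path.
#' @return `read_pools()`: a tibble of pool counts.
#' @export
read_pools <- function(path) {
  tbl <- read_tsv_(path, readr::cols(pool_id = "c", phenotype = "c",
                                     stratum = "c", marker_id = "c",
                                     n_B = "i", n_W = "i"))
  bad <- setdiff(unique(tbl$phenotype), c("haploid", "diploid"))
  if (length(bad) > 0) {
    abort(paste0("unknown pool phenotype label(s): ", paste(bad, collapse = ", ")))
  }
  tbl
}

#' @rdname read_pools
#' @param pools Pool counts tibble.
#' @export
write_pools <- function(pools, path) {
  readr::write_tsv(as_tibble(pools), path)
  invisible(path)
}

#' Import biallelic SNP markers from a parent-vs-parent VCF
#'
#' Reads a VCF 4.x of variants between the two parental genomes and keeps
#' biallelic SNP records (single-nucleotide REF and ALT); multi-allelic or
#' indel records are skipped with a warning. REF is taken as the B-parent
#' allele and ALT as the W-parent allele; only CHROM/POS/REF/ALT are consumed.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param cM_per_kb Physical-to-genetic conversion (see [genetic_map()]).
#' @return A [genetic_map()].
#' @export
markers_from_vcf <- function(path, cM_per_kb = 0.4) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package 'vcfR' is required for VCF import")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warn(paste0("skipped ", sum(!snp),
                " non-biallelic-SNP record(s) in ", basename(path)))
  }
  fix <- fix[snp, , drop = FALSE]
  if (nrow(fix) == 0) abort("no biallelic SNPs in the VCF")
  genetic_map(tibble(
    marker_id = paste0(fix$CHROM, "_", fix$POS),
    chrom = fix$CHROM, pos_bp = as.integer(fix$POS),
    allele_B = fix$REF, allele_W = fix$ALT), cM_per_kb = cM_per_kb)
}

#' Write a scan result TSV
#'
#' Body columns `chrom`, `pos_cM`, `marker_id`, `lod`; when a permutation
#' threshold is attached, a `# threshold` / `# genomewide_p` footer block of
#' comment lines is appended.
#'
#' @param scan A `scan_result`.
#' @param path File path.
#' @export
write_scan <- function(scan, path) {
  readr::write_tsv(tidy(scan), path)
  if (!is.null(attr(scan, "threshold"))) {
    cat(sprintf("# threshold\t%.6g\n# genomewide_p\t%.6g\n# n_perm\t%d\n",
                attr(scan, "threshold"), attr(scan, "genomewide_p"),
                attr(scan, "n_perm")),
        file = path, append = TRUE)
  }
  invisible(path)
}

#' Write a fitted QTL model as JSON
#'
#' @param model A `qtl_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  out <- list(loci = model$loci, interactions = model$interactions,
              model_lod = model$model_lod, plod = model$plod,
              penalties = model$penalties,
              variance_explained = model$variance_explained,
              variance_explained_deviance = model$variance_explained_deviance,
              p_chisq = model$p_chisq, p_F = model$p_F, n = model$n,
              effects = model$effects)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
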