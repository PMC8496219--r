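# Shared fixtures: all synthetic, built in code at test time.

# A small random map for generic checks.
small_map <- function(n = 40, chroms = c(chrI = 1e5, chrII = 1.5e5),
                      seed = 11) {
  sim_genetic_map(n, chroms, seed = seed)
}

# A map with explicit genetic positions on one chromosome.
manual_map <- function(pos_cM, chrom = "chrI") {
  n <- length(pos_cM)
  genetic_map(tibble::tibble(
    marker_id = sprintf("m%02d", seq_len(n)), chrom = chrom,
    pos_bp = seq_len(n) * 1000, pos_cM = pos_cM,
    allele_B = rep("A", n), allele_W = rep("T", n)))
}

# genotype_matrix from a hard-call matrix (rows = segregants).
geno_from_calls <- function(call, map) {
  rownames(call) <- rownames(call) %||% sprintf("S%03d", seq_len(nrow(call)))
  tetradqtl:::as_genotype_matrix(call, map)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# genotype_probs built directly from a P(B) matrix: a fully informative
# fixture for scan closed-form checks.
probs_from_q <- function(Q, chrom = "chrI", pos_cM = seq_len(ncol(Q))) {
  rownames(Q) <- rownames(Q) %||% sprintf("S%03d", seq_len(nrow(Q)))
  structure(list(
    grid = tibble::tibble(chrom = chrom, pos_cM = pos_cM,
                          marker_id = NA_character_),
    prob_B = Q,
    segregants = tibble::tibble(segregant_id = rownames(Q))),
    class = "genotype_probs")
}

# The worked 2x2 example: a fully informative locus with B carriers 3 diploid
# / 1 haploid and W carriers 1 diploid / 3 haploid.
table22 <- function() {
  list(q = matrix(c(rep(1, 4), rep(0, 4)), ncol = 1),
       y = c(1, 1, 1, 0, 1, 0, 0, 0))
}

# Independent brute-force posterior oracle for a two-state chain over L
# markers: enumerates all 2^L state paths with uniform start, Haldane
# transitions and binomial emissions. Deliberately path-enumeration, not
# forward-backward.
brute_posterior_B <- function(n_B, n_W, r, eps) {
  L <- length(n_B)
  paths <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), L)))
  logp <- apply(paths, 1, function(is_B) {
    lp <- log(0.5)
    if (L > 1) {
      switches <- xor(is_B[-1], is_B[-L])
      lp <- lp + sum(log(ifelse(switches, r, 1 - r)))
    }
    n_match <- ifelse(is_B, n_B, n_W)
    lp + sum(dbinom(n_match, n_B + n_W, 1 - eps, log = TRUE))
  })
  p <- exp(logp - max(logp))
  vapply(seq_len(L), function(j) sum(p[paths[, j]]) / sum(p), numeric(1))
}
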