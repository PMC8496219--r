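#' Emission log-likelihood of allele read counts
#'
#' Log-probability of observing `n_B` B-matching and `n_W` W-matching reads at
#' a marker, given the segregant's true parental state. Reads are modeled as
#' Binomial(n_B + n_W, 1 - error_rate) draws of the matching allele, with a
#' symmetric per-read error. Zero-coverage markers carry no information: both
#' states get log-likelihood 0.
#'
#' @param n_B,n_W Non-negative read counts (vectorized).
#' @param state `"B"` or `"W"`, the hypothesized parental origin.
#' @param error_rate Per-read error probability in `[0, 0.5)`.
#' @return Log-likelihood(s).
#' @examples
#' emission_loglik(3, 0, "B", 0.01)  # 3 * log(0.99)
#' @export
emission_loglik <- function(n_B, n_W, state, error_rate) {
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("error_rate must be in [0, 0.5)")
  }
  if (any(n_B < 0) || any(n_W < 0)) abort("read counts must be non-negative")
  state <- match.arg(state, c("B", "W"))
  n_match <- if (state == "B") n_B else n_W
  dbinom(n_match, n_B + n_W, 1 - error_rate, log = TRUE)
}

# Coerce a long counts tibble (segregant_id, marker_id, n_B, n_W) into the
# matrix-backed allele_counts container used internally.
as_allele_counts <- function(x, map, segregants = NULL) {
  if (inherits(x, "allele_counts")) return(x)
  map <- assert_genetic_map(map)
  x <- as_tibble(x)
  need <- c("segregant_id", "marker_id", "n_B", "n_W")
  if (!all(need %in% names(x))) {
    abort(paste("counts need columns:", paste(need, collapse = ", ")))
  }
  unknown <- setdiff(unique(x$marker_id), map$marker_id)
  if (length(unknown) > 0) {
    abort(paste0("counts reference marker(s) absent from the map: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  ids <- unique(x$segregant_id)
  n_B <- matrix(0L, length(ids), nrow(map), dimnames = list(ids, map$marker_id))
  n_W <- n_B
  i <- match(x$segregant_id, ids)
  j <- match(x$marker_id, map$marker_id)
  n_B[cbind(i, j)] <- as.integer(x$n_B)
  n_W[cbind(i, j)] <- as.integer(x$n_W)
  structure(list(map = map,
                 segregants = segregants %||% tibble(segregant_id = ids),
                 n_B = n_B, n_W = n_W),
            class = "allele_counts")
}

# Forward-backward posterior P(state = B) for one chromosome, vectorized over
# segregants. log_eB/log_eW are n x L emission log-likelihoods; r is the
# vector of L-1 inter-marker recombination fractions.
forward_backward <- function(log_eB, log_eW, r) {
  n <- nrow(log_eB); L <- ncol(log_eB)
  mx <- pmax(log_eB, log_eW)
  if (any(!is.finite(mx))) {
    abort("emission impossible under both states; use error_rate > 0")
  }
  wB <- exp(log_eB - mx); wW <- exp(log_eW - mx)
  aB <- matrix(0, n, L); aW <- matrix(0, n, L)
  fB <- 0.5 * wB[, 1]; fW <- 0.5 * wW[, 1]
  z <- fB + fW
  aB[, 1] <- fB / z; aW[, 1] <- fW / z
  if (L > 1) {
    for (t in 2:L) {
      pB <- (1 - r[t - 1]) * aB[, t - 1] + r[t - 1] * aW[, t - 1]
      pW <- 1 - pB
      fB <- pB * wB[, t]; fW <- pW * wW[, t]
      z <- fB + fW
      aB[, t] <- fB / z; aW[, t] <- fW / z
    }
  }
  bB <- matrix(1, n, L); bW <- matrix(1, n, L)
  if (L > 1) {
    for (t in (L - 1):1) {
      xB <- wB[, t + 1] * bB[, t + 1]
      xW <- wW[, t + 1] * bW[, t + 1]
      gB <- (1 - r[t]) * xB + r[t] * xW
      gW <- r[t] * xB + (1 - r[t]) * xW
      z <- gB + gW
      bB[, t] <- gB / z; bW[, t] <- gW / z
    }
  }
  num <- aB * bB
  num / (num + aW * bW)
}

#' Infer parental-origin genotypes by a two-state HMM
#'
#' Posterior (forward-backward) decoding of each segregant's parental origin
#' along the genome from sparse allele read counts. The hidden chain has
#' states \{B, W\}, a uniform (1/2, 1/2) start at the first marker of each
#' chromosome, and transition probability `haldane_r(d)` of switching between
#' adjacent markers separated by `d` cM; chromosomes are independent.
#' Emissions are binomial read counts with symmetric error
#' ([emission_loglik()]). A marker is called B (or W) when its posterior
#' exceeds `call_threshold`, and left missing otherwise.
#'
#' @param counts An `allele_counts` object from [sim_counts()], or a long
#'   tibble with columns `segregant_id`, `marker_id`, `n_B`, `n_W` (then `map`
#'   is required).
#' @param map A [genetic_map()]; taken from `counts` when absent.
#' @param error_rate Per-read error used in the emission model. Default 0.005.
#' @param call_threshold Posterior needed to call a genotype, in (0.5, 1].
#'   Default 0.95.
#' @return A list of class `genotype_matrix`: `call` (segregant x marker
#'   character matrix over `{"B","W",NA}`), `posterior_B` (matching numeric
#'   matrix), `map`, `segregants`, and the parameters used.
#' @export
infer_genotypes <- function(counts, map = NULL, error_rate = 0.005,
                            call_threshold = 0.95) {
  if (call_threshold <= 0.5 || call_threshold > 1) {
    abort("call_threshold must be in (0.5, 1]")
  }
  counts <- as_allele_counts(counts, map %||% counts$map)
  map <- counts$map
  post <- matrix(NA_real_, nrow(counts$n_B), ncol(counts$n_B),
                 dimnames = dimnames(counts$n_B))
  for (idx in map_chrom_index(map)) {
    r <- haldane_r(diff(map$pos_cM[idx]))
    log_eB <- emission_loglik(counts$n_B[, idx, drop = FALSE],
                              counts$n_W[, idx, drop = FALSE], "B", error_rate)
    log_eW <- emission_loglik(counts$n_B[, idx, drop = FALSE],
                              counts$n_W[, idx, drop = FALSE], "W", error_rate)
    dim(log_eB) <- dim(log_eW) <- c(nrow(post), length(idx))
    post[, idx] <- forward_backward(log_eB, log_eW, r)
  }
  call <- matrix(NA_character_, nrow(post), ncol(post), dimnames = dimnames(post))
  call[post >= call_threshold] <- "B"
  call[1 - post >= call_threshold] <- "W"
  structure(list(call = call, posterior_B = post, map = map,
                 segregants = counts$segregants, error_rate = error_rate,
                 call_threshold = call_threshold),
            class = "genotype_matrix")
}

# Build a genotype_matrix directly from hard calls (e.g. simulator truth or a
# genotype TSV), with posteriors 0/1 and NA where calls are missing.
as_genotype_matrix <- function(call, map, segregants = NULL,
                               error_rate = 0.005, call_threshold = 0.95) {
  if (inherits(call, "genotype_matrix")) return(call)
  map <- assert_genetic_map(map)
  stopifnot(is.matrix(call), ncol(call) == nrow(map))
  colnames(call) <- map$marker_id
  post <- matrix(0.5, nrow(call), ncol(call), dimnames = dimnames(call))
  post[!is.na(call) & call == "B"] <- 1
  post[!is.na(call) & call == "W"] <- 0
  structure(list(call = call, posterior_B = post, map = map,
                 segregants = segregants %||%
                   tibble(segregant_id = rownames(call) %||%
                            sprintf("S%04d", seq_len(nrow(call)))),
                 error_rate = error_rate, call_threshold = call_threshold),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$call), " segregants x ", ncol(x$call),
      " markers; ", round(100 * mean(is.na(x$call)), 2), "% missing calls\n",
      sep = "")
  invisible(x)
}

#' @describeIn infer_genotypes Long-format view: one row per segregant x
#'   marker with the call and posterior.
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(segregant_id = rep(rownames(x$call), ncol(x$call)),
         marker_id = rep(colnames(x$call), each = nrow(x$call)),
         call = as.vector(x$call),
         posterior_B = as.vector(x$posterior_B)) |>
    left_join(x$map[, c("marker_id", "chrom", "pos_cM")], by = "marker_id") |>
    arrange(match(.data$marker_id, x$map$marker_id),
            match(.data$segregant_id, rownames(x$call)))
}
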