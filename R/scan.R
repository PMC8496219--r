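#' Genotype probabilities on a pseudomarker grid
#'
#' Computes each segregant's probability of carrying the B allele at every
#' position of an evaluation grid: all marker positions plus pseudomarkers
#' every `step_cM` along each chromosome. Probabilities come from the same
#' two-state forward-backward machinery as [infer_genotypes()], here with
#' genotype *calls* as observations: a called marker reports the true state
#' with probability `1 - error_rate`, a missing marker (or pseudomarker)
#' carries no information. `error_rate = 0` treats calls as exact.
#'
#' @param geno A `genotype_matrix`.
#' @param step_cM Grid spacing in cM (> 0). Default 1.
#' @param error_rate Per-call error for the observation model. Default 0.005.
#' @return A list of class `genotype_probs`: `grid` (tibble `chrom`, `pos_cM`,
#'   `marker_id` -- `NA` at pseudomarkers), `prob_B` (segregant x position
#'   matrix), `segregants`.
#' @export
genotype_probs <- function(geno, step_cM = 1, error_rate = 0.005) {
  stopifnot(inherits(geno, "genotype_matrix"), step_cM > 0,
            error_rate >= 0, error_rate < 0.5)
  map <- geno$map
  n <- nrow(geno$call)
  grids <- list(); probs <- list()
  for (idx in map_chrom_index(map)) {
    pos_m <- map$pos_cM[idx]
    pseudo <- setdiff(seq(min(pos_m), max(pos_m), by = step_cM), pos_m)
    pos <- sort(c(pos_m, pseudo))
    marker_at <- map$marker_id[idx][match(pos, pos_m)]
    L <- length(pos)
    # observation log-likelihoods: called markers only, else uninformative
    log_eB <- matrix(0, n, L); log_eW <- matrix(0, n, L)
    obs_j <- which(!is.na(marker_at))
    calls <- geno$call[, idx, drop = FALSE]
    pB_given_B <- log(1 - error_rate); pW_given_B <- log(error_rate)
    for (k in seq_along(obs_j)) {
      cl <- calls[, k]
      j <- obs_j[k]
      log_eB[, j] <- ifelse(is.na(cl), 0,
                            ifelse(cl == "B", pB_given_B, pW_given_B))
      log_eW[, j] <- ifelse(is.na(cl), 0,
                            ifelse(cl == "W", pB_given_B, pW_given_B))
    }
    r <- haldane_r(diff(pos))
    probs[[length(probs) + 1]] <- forward_backward(log_eB, log_eW, r)
    grids[[length(grids) + 1]] <- tibble(chrom = map$chrom[idx[1]],
                                         pos_cM = pos, marker_id = marker_at)
  }
  grid <- bind_rows(grids)
  prob_B <- do.call(cbind, probs)
  rownames(prob_B) <- rownames(geno$call)
  structure(list(grid = grid, prob_B = prob_B, segregants = geno$segregants),
            class = "genotype_probs")
}

# Align a phenotype table (segregant_id, phenotype in {0,1}) with the rows of
# a genotype_probs object; returns the 0/1 vector in row order.
align_phenotype <- function(probs, phenotypes) {
  if (is.data.frame(phenotypes)) {
    i <- match(rownames(probs$prob_B), phenotypes$segregant_id)
    if (anyNA(i)) abort("phenotype table is missing some segregants")
    y <- phenotypes$phenotype[i]
  } else {
    y <- phenotypes
    stopifnot(length(y) == nrow(probs$prob_B))
  }
  if (!all(y %in% c(0, 1))) abort("phenotype must be binary 0/1")
  as.numeric(y)
}

# Binomial log-likelihood of y under probability p (vectorized, safe at 0/1).
bern_ll <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# EM fit of the two-penetrance binomial mixture at one position.
# q = P(B) per segregant. Returns the maximized log-likelihood; with
# trace = TRUE, a list also carrying the per-iteration log-likelihoods and
# the fitted penetrances.
em_mixture_ll <- function(q, y, tol = 1e-8, max_iter = 1000, trace = FALSE) {
  ybar <- mean(y)
  p_B <- min(max(ybar + 0.1, 1e-6), 1 - 1e-6)
  p_W <- min(max(ybar - 0.1, 1e-6), 1 - 1e-6)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    f_B <- p_B^y * (1 - p_B)^(1 - y)
    f_W <- p_W^y * (1 - p_W)^(1 - y)
    mix <- q * f_B + (1 - q) * f_W
    ll <- sum(log(mix))
    if (trace) ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol) break
    ll_old <- ll
    w <- q * f_B / mix
    sw <- sum(w)
    p_B <- if (sw > 0) sum(w * y) / sw else ybar
    p_W <- if (sw < length(y)) sum((1 - w) * y) / (length(y) - sw) else ybar
    p_B <- min(max(p_B, 1e-12), 1 - 1e-12)
    p_W <- min(max(p_W, 1e-12), 1 - 1e-12)
  }
  if (trace) list(ll = ll, trace = ll_trace, p_B = p_B, p_W = p_W) else ll
}

new_scan_result <- function(grid, lod, method, n, threshold = NULL,
                            genomewide_p = NULL, n_perm = NULL) {
  out <- grid
  out$lod <- pmax(lod, 0)
  structure(out, class = c("scan_result", class(tibble())),
            method = method, n = n, threshold = threshold,
            genomewide_p = genomewide_p, n_perm = n_perm)
}

#' Single-QTL genome scan for a binary phenotype
#'
#' Computes a LOD curve over the evaluation grid by one of two methods.
#' `"em"` is interval mapping on the binomial mixture likelihood: at each
#' position the likelihood `prod_i [q_i p_B^y_i (1-p_B)^(1-y_i) +
#' (1-q_i) p_W^y_i (1-p_W)^(1-y_i)]` is maximized over the two penetrances by
#' EM (q_i the segregant's P(B) there), and compared with the phenotype-only
#' binomial null. `"hk"` is Haley-Knott regression: ordinary least squares of
#' the 0/1 phenotype on P(B), with `LOD = (n/2) log10(RSS0/RSS1)`.
#'
#' @param probs A [genotype_probs()] object.
#' @param phenotypes Tibble (`segregant_id`, `phenotype` 0/1) or a 0/1 vector
#'   in row order of `probs`.
#' @param method `"em"` or `"hk"`.
#' @return A `scan_result` tibble: `chrom`, `pos_cM`, `marker_id`, `lod`, with
#'   the method and sample size as attributes.
#' @export
scan_binary <- function(probs, phenotypes, method = c("em", "hk")) {
  method <- match.arg(method)
  stopifnot(inherits(probs, "genotype_probs"))
  y <- align_phenotype(probs, phenotypes)
  n <- length(y)
  Q <- probs$prob_B
  if (length(unique(y)) < 2) {
    return(new_scan_result(probs$grid, rep(0, ncol(Q)), method, n))
  }
  lod <- if (method == "hk") {
    hk_lod(Q, y)
  } else {
    ll0 <- bern_ll(y, rep(mean(y), n))
    apply(Q, 2, function(q) (em_mixture_ll(q, y) - ll0) / log(10))
  }
  new_scan_result(probs$grid, lod, method, n)
}

# Vectorized Haley-Knott LOD over all grid columns of Q for one phenotype y.
hk_lod <- function(Q, y) {
  n <- length(y)
  yc <- y - mean(y)
  Xc <- sweep(Q, 2, colMeans(Q))
  sxx <- colSums(Xc^2)
  sxy <- as.vector(crossprod(Xc, yc))
  rss0 <- sum(yc^2)
  rss1 <- rss0 - ifelse(sxx > 0, sxy^2 / sxx, 0)
  (n / 2) * log10(rss0 / pmax(rss1, 1e-300))
}

#' Genome-wide permutation threshold and p-value
#'
#' Permutes phenotype labels against whole genotype rows `n_perm` times,
#' recording the genome-wide maximum LOD of each permuted scan. The
#' significance threshold is the `1 - alpha` quantile of that null; the
#' genome-wide p-value of the observed maximum uses the add-one rule
#' `(k + 1) / (n_perm + 1)`, so 10,000 permutations with no exceedances report
#' p < 1e-4 rather than zero.
#'
#' @inheritParams scan_binary
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param alpha Genome-wide significance level. Default 0.05.
#' @param seed Optional integer seed for the permutations.
#' @param method Scan method; `"hk"` (default) permutes by closed-form linear
#'   algebra, `"em"` refits the mixture per permutation and is much slower.
#' @return The observed `scan_result` with attributes `threshold`,
#'   `genomewide_p` and `n_perm` filled in; the permutation null maxima are
#'   attached as attribute `perm_max`.
#' @export
permutation_threshold <- function(probs, phenotypes, n_perm = 1000,
                                  alpha = 0.05, seed = NULL,
                                  method = c("hk", "em")) {
  method <- match.arg(method)
  if (n_perm < 100) abort("n_perm must be at least 100")
  y <- align_phenotype(probs, phenotypes)
  obs <- scan_binary(probs, phenotypes, method = method)
  perm_max <- with_seed_(seed, {
    if (method == "hk") {
      perm_max_hk(probs$prob_B, y, n_perm)
    } else {
      vapply(seq_len(n_perm), function(i) {
        max(scan_binary(probs, sample(y), method = "em")$lod)
      }, numeric(1))
    }
  })
  k <- sum(perm_max >= max(obs$lod))
  attr(obs, "threshold") <- as.numeric(quantile(perm_max, 1 - alpha, type = 7))
  attr(obs, "genomewide_p") <- (k + 1) / (n_perm + 1)
  attr(obs, "n_perm") <- n_perm
  attr(obs, "perm_max") <- perm_max
  obs
}

# Max HK LOD per permutation, vectorized over permutations in blocks.
perm_max_hk <- function(Q, y, n_perm, block = 250) {
  n <- length(y)
  Xc <- sweep(Q, 2, colMeans(Q))
  sxx <- colSums(Xc^2)
  rss0 <- sum((y - mean(y))^2)
  out <- numeric(n_perm)
  done <- 0
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Yp <- vapply(seq_len(b), function(i) sample(y), numeric(n))
    Yc <- sweep(Yp, 2, colMeans(Yp))
    num <- crossprod(Xc, Yc)^2            # positions x perms
    rss1 <- pmax(rss0 - num / ifelse(sxx > 0, sxx, Inf), 1e-300)
    out[done + seq_len(b)] <- (n / 2) * log10(rss0 / apply(rss1, 2, min))
    done <- done + b
  }
  out
}

#' Rescan with a known QTL regressed out
#'
#' Repeats the single-QTL scan with the genotype probability at a given
#' position included as an additive covariate, to ask whether any signal
#' remains once the lead QTL is accounted for. Under `"hk"` the covariate is
#' an extra regressor in both the null and full regressions. Under `"em"`
#' segregants are stratified by their covariate posterior (B-like vs W-like at
#' the QTL) and stratum-specific penetrances are fitted in both the null and
#' the mixture alternative. The LOD at the covariate's own position is ~0.
#'
#' @inheritParams scan_binary
#' @param qtl_position Grid row index, or a list/tibble row with `chrom` and
#'   `pos_cM` matching a grid position.
#' @return A `scan_result`.
#' @export
scan_regressout <- function(probs, phenotypes, qtl_position,
                            method = c("em", "hk")) {
  method <- match.arg(method)
  j <- grid_position_index(probs$grid, qtl_position)
  y <- align_phenotype(probs, phenotypes)
  n <- length(y)
  Q <- probs$prob_B
  covar <- Q[, j]
  if (method == "hk") {
    if (sd(covar) == 0) return(scan_binary(probs, phenotypes, method = "hk"))
    C <- cbind(1, covar)
    resid_on <- function(v) v - C %*% qr.solve(crossprod(C), crossprod(C, v))
    yr <- as.vector(resid_on(y))
    Xr <- apply(Q, 2, function(x) as.vector(resid_on(x)))
    rss0 <- sum(yr^2)
    sxx <- colSums(Xr^2)
    sxy <- as.vector(crossprod(Xr, yr))
    rss1 <- pmax(rss0 - ifelse(sxx > 0, sxy^2 / sxx, 0), 1e-300)
    lod <- (n / 2) * log10(rss0 / rss1)
  } else {
    stratum <- covar > 0.5
    if (length(unique(stratum)) < 2) {
      return(scan_binary(probs, phenotypes, method = "em"))
    }
    ll0 <- sum(vapply(split(seq_len(n), stratum), function(i) {
      bern_ll(y[i], rep(mean(y[i]), length(i)))
    }, numeric(1)))
    lod <- apply(Q, 2, function(q) {
      ll1 <- sum(vapply(split(seq_len(n), stratum), function(i) {
        em_mixture_ll(q[i], y[i])
      }, numeric(1)))
      (ll1 - ll0) / log(10)
    })
  }
  new_scan_result(probs$grid, lod, paste0(method, "+covariate"), n)
}

# Resolve a (chrom, pos_cM) pair -- or a bare index -- to a grid row index.
grid_position_index <- function(grid, position) {
  if (is.numeric(position) && length(position) == 1 && is.null(names(position))) {
    stopifnot(position >= 1, position <= nrow(grid))
    return(as.integer(position))
  }
  pos <- as.list(position)
  j <- which(grid$chrom == pos$chrom &
               abs(grid$pos_cM - pos$pos_cM) < 1e-8)
  if (length(j) != 1) abort("position does not match a unique grid point")
  j
}

#' @export
print.scan_result <- function(x, ...) {
  peak <- x[which.max(x$lod), ]
  cat("<scan_result> method=", attr(x, "method"), ", n=", attr(x, "n"),
      ", ", nrow(x), " positions\n  max LOD ", round(peak$lod, 3), " at ",
      peak$chrom, ":", round(peak$pos_cM, 1), " cM", sep = "")
  if (!is.null(attr(x, "threshold"))) {
    cat("; threshold ", round(attr(x, "threshold"), 3),
        " (", attr(x, "n_perm"), " permutations, genome-wide p ",
        signif(attr(x, "genomewide_p"), 3), ")", sep = "")
  }
  cat("\n")
  invisible(NextMethod())
}

#' @describeIn scan_binary Tibble of the LOD curve (drops the subclass).
#' @param x A `scan_result`.
#' @param ... Unused.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  as_tibble(x)[, c("chrom", "pos_cM", "marker_id", "lod")]
}

#' @describeIn scan_binary One-row summary: peak position and LOD, threshold
#'   and genome-wide p-value when permutations were run.
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  peak <- which.max(x$lod)
  tibble(method = attr(x, "method"), n = attr(x, "n"),
         max_lod = x$lod[peak], chrom = x$chrom[peak],
         pos_cM = x$pos_cM[peak],
         threshold = attr(x, "threshold") %||% NA_real_,
         genomewide_p = attr(x, "genomewide_p") %||% NA_real_,
         n_perm = attr(x, "n_perm") %||% NA_integer_)
}
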