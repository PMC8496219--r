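#' Split segregants into predictor and test sets
#'
#' Seeded random partition of the segregants, mirroring the design in which
#' 150 of 255 segregants form a predictor (training) set for model search and
#' the remaining 105 are held out for model fitting.
#'
#' @param phenotypes Tibble with `segregant_id` (and any other columns).
#' @param n_train Number of training segregants (0 < n_train < n). Default 150.
#' @param seed Optional integer seed.
#' @return The input tibble with an added `split` column (`"train"`/`"test"`).
#' @export
split_data <- function(phenotypes, n_train = 150, seed = NULL) {
  phenotypes <- as_tibble(phenotypes)
  n <- nrow(phenotypes)
  if (n_train <= 0) abort("n_train must be positive")
  if (n_train >= n) abort("n_train must be smaller than the number of segregants")
  with_seed_(seed, {
    idx <- sample.int(n, n_train)
    phenotypes$split <- ifelse(seq_len(n) %in% idx, "train", "test")
    phenotypes
  })
}

# Keep only the named segregants of a genotype_probs object.
subset_probs <- function(probs, segregant_ids) {
  keep <- rownames(probs$prob_B) %in% segregant_ids
  structure(list(grid = probs$grid,
                 prob_B = probs$prob_B[keep, , drop = FALSE],
                 segregants = probs$segregants[
                   probs$segregants$segregant_id %in% segregant_ids, ]),
            class = "genotype_probs")
}

# Haley-Knott fit of a multi-locus model: loci are grid column indices,
# interactions pairs of positions *within* loci. Returns RSS and LOD.
hk_model_fit <- function(Q, y, loci, interactions = list()) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (length(loci) == 0) {
    return(list(rss = rss0, lod = 0, df = 0))
  }
  X <- Q[, loci, drop = FALSE]
  for (pr in interactions) X <- cbind(X, X[, pr[1]] * X[, pr[2]])
  C <- cbind(1, X)
  fit <- qr(C)
  res <- qr.resid(fit, y)
  rss <- sum(res^2)
  list(rss = rss, lod = (n / 2) * log10(rss0 / max(rss, 1e-300)),
       df = fit$rank - 1)
}

new_qtl_model <- function(grid, loci_idx, interactions, lod, plod, penalties,
                          n) {
  structure(list(
    loci = tibble(chrom = grid$chrom[loci_idx], pos_cM = grid$pos_cM[loci_idx],
                  marker_id = grid$marker_id[loci_idx], index = loci_idx),
    interactions = interactions, model_lod = lod, plod = plod,
    penalties = penalties, n = n,
    variance_explained = NA_real_, variance_explained_deviance = NA_real_,
    p_chisq = NA_real_, p_F = NA_real_, effects = NULL),
    class = "qtl_model")
}

#' Forward/backward stepwise multi-QTL search
#'
#' Greedy model search over the evaluation grid, maximizing the penalized LOD
#' `pLOD = model_LOD - T_main * (#loci) - T_int * (#interactions)`. Forward
#' steps propose adding a locus (up to `max_qtl`) or an interaction between
#' included loci; after each accepted addition, backward deletion removes any
#' term whose deletion raises the penalized LOD. The best model visited is
#' returned. The main-effect penalty `T_main` defaults to the genome-wide
#' permutation threshold on the supplied (training) data; the interaction
#' penalty `T_int` defaults to `T_main`. The search can be restricted to a
#' subset of chromosomes, as when prior single-QTL scans justify searching
#' only chromosomes IV and XIV.
#'
#' @inheritParams scan_binary
#' @param penalties Optional list with elements `main` and `interaction`;
#'   derived from `n_perm` permutations at level `alpha` when `NULL`.
#' @param max_qtl Maximum number of loci in the model. Default 4.
#' @param chromosomes Optional character vector restricting candidate
#'   positions; `NULL` means all chromosomes.
#' @param n_perm,alpha,seed Permutation settings used when `penalties` is
#'   `NULL` (1000 permutations by default, matching stepwise-search practice).
#' @return A `qtl_model`.
#' @export
stepwise_search <- function(probs, phenotypes, penalties = NULL, max_qtl = 4,
                            chromosomes = NULL, n_perm = 1000, alpha = 0.05,
                            seed = NULL) {
  stopifnot(inherits(probs, "genotype_probs"))
  y <- align_phenotype(probs, phenotypes)
  n <- length(y)
  if (is.null(penalties)) {
    perm <- permutation_threshold(probs, y, n_perm = n_perm, alpha = alpha,
                                  seed = seed, method = "hk")
    penalties <- list(main = attr(perm, "threshold"),
                      interaction = attr(perm, "threshold"))
  }
  T_main <- penalties$main; T_int <- penalties$interaction %||% penalties$main
  candidates <- if (is.null(chromosomes)) seq_len(nrow(probs$grid)) else {
    which(probs$grid$chrom %in% chromosomes)
  }
  if (length(candidates) == 0) {
    abort("chromosome restriction leaves no candidate positions")
  }
  Q <- probs$prob_B
  plod_of <- function(lod, k, ni) lod - T_main * k - T_int * ni

  loci <- integer(0); inter <- list()
  cur <- hk_model_fit(Q, y, loci, inter)
  cur_plod <- 0
  best <- list(loci = loci, inter = inter, lod = 0, plod = 0)

  repeat {
    prop <- NULL
    # propose adding each candidate locus (vectorized residual regression)
    if (length(loci) < max_qtl) {
      X <- if (length(loci) > 0) Q[, loci, drop = FALSE] else NULL
      for (pr in inter) X <- cbind(X, Q[, loci[pr[1]]] * Q[, loci[pr[2]]])
      C <- cbind(rep(1, n), X)
      qrC <- qr(C)
      yr <- qr.resid(qrC, y)
      cand <- setdiff(candidates, loci)
      Xr <- qr.resid(qrC, Q[, cand, drop = FALSE])
      sxx <- colSums(Xr^2)
      sxy <- as.vector(crossprod(Xr, yr))
      rss_cur <- sum(yr^2)
      rss_new <- pmax(rss_cur - ifelse(sxx > 1e-12, sxy^2 / sxx, 0), 1e-300)
      rss0 <- sum((y - mean(y))^2)
      lod_new <- (n / 2) * log10(rss0 / rss_new)
      j <- which.max(lod_new)
      add_plod <- plod_of(lod_new[j], length(loci) + 1, length(inter))
      prop <- list(kind = "add_locus", locus = cand[j], plod = add_plod)
    }
    # propose each new interaction among current loci
    if (length(loci) >= 2) {
      pairs <- utils::combn(seq_along(loci), 2, simplify = FALSE)
      pairs <- Filter(function(p) !any(vapply(inter, identical, TRUE, p)), pairs)
      for (p in pairs) {
        f <- hk_model_fit(Q, y, loci, c(inter, list(p)))
        pl <- plod_of(f$lod, length(loci), length(inter) + 1)
        if (is.null(prop) || pl > prop$plod) {
          prop <- list(kind = "add_inter", pair = p, plod = pl)
        }
      }
    }
    if (is.null(prop) || prop$plod <= cur_plod + 1e-9) break
    if (prop$kind == "add_locus") {
      loci <- c(loci, prop$locus)
    } else {
      inter <- c(inter, list(prop$pair))
    }
    cur <- hk_model_fit(Q, y, loci, inter)
    cur_plod <- plod_of(cur$lod, length(loci), length(inter))

    # backward deletion while it helps
    repeat {
      best_drop <- NULL
      for (k in seq_along(inter)) {
        f <- hk_model_fit(Q, y, loci, inter[-k])
        pl <- plod_of(f$lod, length(loci), length(inter) - 1)
        if (pl > cur_plod + 1e-9 &&
            (is.null(best_drop) || pl > best_drop$plod)) {
          best_drop <- list(kind = "inter", k = k, plod = pl)
        }
      }
      for (k in seq_along(loci)) {
        keep_inter <- Filter(function(p) !(k %in% p), inter)
        keep_inter <- lapply(keep_inter, function(p) ifelse(p > k, p - 1L, p))
        f <- hk_model_fit(Q, y, loci[-k], keep_inter)
        pl <- plod_of(f$lod, length(loci) - 1, length(keep_inter))
        if (pl > cur_plod + 1e-9 &&
            (is.null(best_drop) || pl > best_drop$plod)) {
          best_drop <- list(kind = "locus", k = k, plod = pl,
                            inter = keep_inter)
        }
      }
      if (is.null(best_drop)) break
      if (best_drop$kind == "inter") {
        inter <- inter[-best_drop$k]
      } else {
        loci <- loci[-best_drop$k]
        inter <- best_drop$inter
      }
      cur <- hk_model_fit(Q, y, loci, inter)
      cur_plod <- plod_of(cur$lod, length(loci), length(inter))
    }
    if (cur_plod > best$plod) {
      best <- list(loci = loci, inter = inter, lod = cur$lod, plod = cur_plod)
    }
  }
  new_qtl_model(probs$grid, best$loci, best$inter, best$lod, best$plod,
                list(main = T_main, interaction = T_int), n)
}

#' Fit a QTL model on held-out data
#'
#' Fits the selected model to a (typically held-out) set of segregants and
#' reports a full-versus-null comparison: the model LOD from the binomial
#' likelihood ratio, variance explained `1 - RSS_full / RSS_null` on the 0/1
#' phenotype scale (with a deviance-based alternative from the matching
#' logistic fit), a chi-square likelihood-ratio test, and an F test.
#'
#' @inheritParams scan_binary
#' @param model A `qtl_model` from [stepwise_search()].
#' @return The `qtl_model` updated with `model_lod`, `variance_explained`,
#'   `variance_explained_deviance`, `p_chisq`, `p_F`, `n`, and per-locus
#'   `effects` ([estimate_effects()]).
#' @export
fit_model <- function(probs, phenotypes, model) {
  stopifnot(inherits(model, "qtl_model"))
  if (nrow(model$loci) == 0) abort("cannot fit an empty model")
  y <- align_phenotype(probs, phenotypes)
  if (length(unique(y)) < 2) {
    abort("test data must contain both phenotype classes")
  }
  n <- length(y)
  loci_idx <- vapply(seq_len(nrow(model$loci)), function(k) {
    grid_position_index(probs$grid, model$loci[k, c("chrom", "pos_cM")])
  }, integer(1))
  Q <- probs$prob_B
  X <- Q[, loci_idx, drop = FALSE]
  for (pr in model$interactions) X <- cbind(X, X[, pr[1]] * X[, pr[2]])
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- as.data.frame(X); dat$y <- y
  lfit <- lm(y ~ ., data = dat)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(lfit$residuals^2)
  fs <- suppressWarnings(summary(lfit))$fstatistic  # warns on a perfect fit
  p_F <- if (is.null(fs)) NA_real_ else {
    pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]], lower.tail = FALSE)
  }
  gfit <- suppressWarnings(glm(y ~ ., family = binomial(), data = dat))
  gnull <- glm(y ~ 1, family = binomial(), data = dat)
  dev_drop <- gnull$deviance - gfit$deviance
  p_chisq <- pchisq(dev_drop, df = gnull$df.residual - gfit$df.residual,
                    lower.tail = FALSE)
  # model LOD on the likelihood-ratio scale: deviance drop / (2 ln 10)
  model$model_lod <- dev_drop / (2 * log(10))
  model$variance_explained <- 1 - rss1 / rss0
  model$variance_explained_deviance <- 1 - gfit$deviance / gnull$deviance
  model$p_chisq <- p_chisq
  model$p_F <- p_F
  model$n <- n
  model$loci$index <- loci_idx
  model$effects <- purrr::map2(loci_idx, seq_along(loci_idx), function(j, k) {
    estimate_effects(probs, y, j) |>
      mutate(locus = paste0(model$loci$chrom[k], ":",
                            round(model$loci$pos_cM[k], 2)), .before = 1)
  }) |> bind_rows()
  model
}

#' Refine QTL positions by iterative profiling
#'
#' Re-profiles each locus of a fitted model along its chromosome with the
#' other loci held fixed, moving it to the position maximizing the model LOD,
#' and iterates until no position changes. The model LOD is non-decreasing.
#'
#' @inheritParams fit_model
#' @param max_iter Safety cap on refinement sweeps. Default 10.
#' @return The `qtl_model` with updated positions and `model_lod`.
#' @export
refine_positions <- function(probs, phenotypes, model, max_iter = 10) {
  stopifnot(inherits(model, "qtl_model"))
  if (nrow(model$loci) == 0) abort("cannot refine an empty model")
  y <- align_phenotype(probs, phenotypes)
  Q <- probs$prob_B
  loci_idx <- vapply(seq_len(nrow(model$loci)), function(k) {
    grid_position_index(probs$grid, model$loci[k, c("chrom", "pos_cM")])
  }, integer(1))
  for (sweep in seq_len(max_iter)) {
    moved <- FALSE
    for (k in seq_along(loci_idx)) {
      chrom_pos <- which(probs$grid$chrom == probs$grid$chrom[loci_idx[k]])
      lods <- vapply(chrom_pos, function(j) {
        trial <- loci_idx; trial[k] <- j
        hk_model_fit(Q, y, trial, model$interactions)$lod
      }, numeric(1))
      jbest <- chrom_pos[which.max(lods)]
      if (jbest != loci_idx[k]) {
        loci_idx[k] <- jbest
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  fit <- hk_model_fit(Q, y, loci_idx, model$interactions)
  model$loci <- tibble(chrom = probs$grid$chrom[loci_idx],
                       pos_cM = probs$grid$pos_cM[loci_idx],
                       marker_id = probs$grid$marker_id[loci_idx],
                       index = loci_idx)
  model$model_lod <- fit$lod
  model$plod <- fit$lod - model$penalties$main * length(loci_idx) -
    (model$penalties$interaction %||% model$penalties$main) *
    length(model$interactions)
  model
}

#' Allele effects at a locus
#'
#' Phenotype mean among carriers of each parental allele at a locus,
#' posterior-weighted when genotypes are uncertain: carriers of B contribute
#' with weight P(B), of W with weight 1 - P(B); the effective sample size of
#' each class is the sum of its weights, and the standard error is binomial,
#' `sqrt(p(1-p) / n_eff)`. For the phenotype studied here these means are the
#' estimated penetrances of the two alleles.
#'
#' @inheritParams scan_binary
#' @param locus Grid row index, or a list/tibble row with `chrom`, `pos_cM`.
#' @return Tibble: `allele` (`"B"`/`"W"`), `mean`, `se`, `n_eff`. A class
#'   with no (weighted) carriers gets `NA` mean and se.
#' @export
estimate_effects <- function(probs, phenotypes, locus) {
  j <- grid_position_index(probs$grid, locus)
  y <- align_phenotype(probs, phenotypes)
  w <- probs$prob_B[, j]
  one <- function(wt) {
    n_eff <- sum(wt)
    if (n_eff < 1e-9) return(c(mean = NA_real_, se = NA_real_, n_eff = 0))
    m <- sum(wt * y) / n_eff
    c(mean = m, se = sqrt(m * (1 - m) / n_eff), n_eff = n_eff)
  }
  eb <- one(w); ew <- one(1 - w)
  tibble(allele = c("B", "W"),
         mean = unname(c(eb["mean"], ew["mean"])),
         se = unname(c(eb["se"], ew["se"])),
         n_eff = unname(c(eb["n_eff"], ew["n_eff"])))
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("<qtl_model> ", nrow(x$loci), " loci, ", length(x$interactions),
      " interactions; LOD ", round(x$model_lod, 3), ", penalized LOD ",
      round(x$plod, 3), "\n", sep = "")
  if (nrow(x$loci) > 0) {
    print(x$loci)
  }
  if (!is.na(x$variance_explained)) {
    cat("  variance explained ", round(100 * x$variance_explained, 1),
        "% (deviance scale ",
        round(100 * x$variance_explained_deviance, 1), "%); chi-square p ",
        signif(x$p_chisq, 3), ", F p ", signif(x$p_F, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn stepwise_search One row per model locus (with effect estimates
#'   when the model has been fitted).
#' @param x A `qtl_model`.
#' @param ... Unused.
#' @method tidy qtl_model
#' @export
tidy.qtl_model <- function(x, ...) {
  out <- x$loci
  if (!is.null(x$effects)) {
    wide <- x$effects |>
      tidyr::pivot_wider(names_from = "allele",
                         values_from = c("mean", "se", "n_eff"))
    out <- dplyr::bind_cols(out, wide[, setdiff(names(wide), "locus")])
  }
  out
}

#' @describeIn stepwise_search One-row model summary (LODs, penalties,
#'   variance explained, tests).
#' @method glance qtl_model
#' @export
glance.qtl_model <- function(x, ...) {
  tibble(n_loci = nrow(x$loci), n_interactions = length(x$interactions),
         model_lod = x$model_lod, plod = x$plod,
         penalty_main = x$penalties$main,
         penalty_interaction = x$penalties$interaction %||% NA_real_,
         variance_explained = x$variance_explained,
         variance_explained_deviance = x$variance_explained_deviance,
         p_chisq = x$p_chisq, p_F = x$p_F, n = x$n)
}
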