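#' Between-trait CNV burden correlations
#'
#' The burden correlation between two traits is a rare-variant analogue of a
#' genetic correlation: the covariance of their shrinkage-adjusted gene-set
#' effect-size profiles, scaled by each trait's variance explained by the
#' same gene-set burdens,
#' `rg = Cov(profile1, profile2) / sqrt(h1^2 * h2^2)`.
#' Before profiles are estimated, redundant gene sets are removed by a
#' two-criterion filter (high Jaccard-overlap percentile AND frequent LASSO
#' removal across traits), and covariates are regressed out of each trait.
#'
#' @name burden_correlation
NULL

#' LASSO variable selection over gene-set burdens
#'
#' Fits, per trait, a cross-validated LASSO of the covariate-residualized
#' trait on the standardized gene-set burden matrix, and records which sets
#' retain a nonzero coefficient at the one-standard-error rule. The removal
#' frequency of a set is the fraction of traits in which LASSO zeroes it out.
#'
#' @param residuals_mat Samples x traits matrix of covariate residuals.
#' @param burden_x1 Samples x sets matrix of in-set disrupted gene counts.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed RNG seed fixing the fold assignment.
#' @param lambda Optional fixed penalty path passed to glmnet (overrides CV;
#'   mainly for limit checks).
#' @return List with `selected` (sets x traits logical matrix) and
#'   `removal_freq` (per-set fraction of traits where the set is dropped).
#' @export
lasso_selection <- function(residuals_mat, burden_x1, nfolds = 10,
                            seed = NULL, lambda = NULL) {
  residuals_mat <- as.matrix(residuals_mat)
  burden_x1 <- as.matrix(burden_x1)
  if (ncol(burden_x1) < 2L) stop("need at least two gene-set burden columns")
  if (nrow(burden_x1) != nrow(residuals_mat))
    stop("sample dimensions differ between residuals and burden")
  if (!is.null(seed)) set.seed(seed)
  sel <- matrix(FALSE, ncol(burden_x1), ncol(residuals_mat),
                dimnames = list(colnames(burden_x1), colnames(residuals_mat)))
  for (j in seq_len(ncol(residuals_mat))) {
    y <- residuals_mat[, j]
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(burden_x1, y, alpha = 1, nfolds = nfolds,
                              standardize = TRUE)
      cf <- stats::coef(cv, s = "lambda.1se")
    } else {
      fit <- glmnet::glmnet(burden_x1, y, alpha = 1, lambda = lambda,
                            standardize = TRUE)
      cf <- stats::coef(fit, s = min(lambda))
    }
    sel[, j] <- as.vector(cf[-1] != 0)
  }
  list(selected = sel, removal_freq = rowMeans(!sel))
}

#' Redundancy filter for gene sets
#'
#' Excludes gene sets that are both highly overlapping and dispensable: a set
#' is dropped when its Jaccard-similarity percentile exceeds `pct_threshold`
#' AND LASSO removes it in at least `freq_threshold` of traits. The overlap
#' percentile of a set is the rank percentile, across all sets, of its
#' maximum off-diagonal Jaccard similarity (redundancy against its best
#' partner).
#'
#' @param jaccard Pairwise Jaccard similarity matrix ([jaccard_matrix()]).
#' @param removal_freq Per-set LASSO removal frequency
#'   ([lasso_selection()]).
#' @param pct_threshold Overlap-percentile cutoff (default 0.2).
#' @param freq_threshold Removal-frequency cutoff (default 0.8).
#' @return Character vector of retained set names.
#' @export
filter_genesets <- function(jaccard, removal_freq, pct_threshold = 0.2,
                            freq_threshold = 0.8) {
  stopifnot(nrow(jaccard) == length(removal_freq))
  diag(jaccard) <- NA
  max_sim <- apply(jaccard, 1, max, na.rm = TRUE)
  pct <- rank(max_sim, ties.method = "average") / length(max_sim)
  drop <- pct > pct_threshold & removal_freq >= freq_threshold
  rownames(jaccard)[!drop]
}

#' Shrinkage-adjusted effect-size profile
#'
#' Joint ridge regression of a covariate-residualized trait on all retained
#' gene-set burdens; the coefficient vector is the trait's effect-size
#' profile. Ridge shrinkage spreads signal across overlapping sets instead of
#' arbitrarily picking one, which is what makes profiles comparable across
#' traits. The penalty is chosen by 10-fold cross-validation unless `lambda`
#' is supplied.
#'
#' @param residuals Covariate residuals for one trait.
#' @param burden_retained Samples x retained-sets burden matrix.
#' @param nfolds Cross-validation folds.
#' @param seed RNG seed fixing fold assignment.
#' @param lambda Optional fixed ridge penalty (glmnet scale).
#' @return Named numeric vector of per-set coefficients (original count
#'   scale).
#' @export
shrinkage_profile <- function(residuals, burden_retained, nfolds = 10,
                              seed = NULL, lambda = NULL) {
  burden_retained <- as.matrix(burden_retained)
  if (ncol(burden_retained) < 2L) stop("need at least two gene-set burden columns")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(burden_retained, residuals, alpha = 0,
                            nfolds = nfolds, standardize = TRUE)
    cf <- stats::coef(cv, s = "lambda.min")
  } else {
    fit <- glmnet::glmnet(burden_retained, residuals, alpha = 0,
                          lambda = lambda, standardize = TRUE)
    cf <- stats::coef(fit, s = min(lambda))
  }
  stats::setNames(as.vector(cf[-1]), colnames(burden_retained))
}

#' Variance explained by gene-set burdens
#'
#' R-squared of the multiple regression of the covariate-residualized trait
#' on all retained gene-set burdens — the proxy for the trait's variance
#' explained (burden heritability) used in the burden-correlation
#' denominator.
#'
#' @inheritParams shrinkage_profile
#' @return Single R-squared value in `[0, 1]`.
#' @export
variance_explained <- function(residuals, burden_retained) {
  burden_retained <- as.matrix(burden_retained)
  if (nrow(burden_retained) <= ncol(burden_retained))
    stop("variance explained undefined: need more samples than gene sets")
  fit <- stats::lm.fit(cbind(1, burden_retained), residuals)
  1 - sum(fit$residuals^2) / sum((residuals - mean(residuals))^2)
}

#' Burden genetic correlation between two traits
#'
#' `rg = Cov(profile1, profile2) / sqrt(h1_sq * h2_sq)`, with the covariance
#' taken across retained gene sets. The value is reported as-is (it can
#' exceed 1 in magnitude when the heritability proxies are small); the
#' `out_of_range` attribute flags such cells.
#'
#' @param profile1,profile2 Aligned effect-size profiles (same sets, same
#'   order; liability scale for binary traits).
#' @param h1_sq,h2_sq Variance-explained proxies for the two traits (> 0).
#' @return The burden correlation, with attribute `out_of_range`.
#' @export
burden_rg <- function(profile1, profile2, h1_sq, h2_sq) {
  stopifnot(length(profile1) == length(profile2))
  if (h1_sq <= 0 || h2_sq <= 0) stop("heritability proxies must be positive")
  rg <- stats::cov(profile1, profile2) / sqrt(h1_sq * h2_sq)
  attr(rg, "out_of_range") <- abs(rg) > 1
  rg
}

#' Sign concordance between two correlation matrices
#'
#' Percentage of upper-triangle trait pairs whose correlations agree in sign
#' between two matrices (pairs with a zero in either matrix are excluded).
#'
#' @param matrixA,matrixB Square matrices over the same trait pairs.
#' @return Percentage in `[0, 100]`.
#' @export
sign_concordance <- function(matrixA, matrixB) {
  stopifnot(all(dim(matrixA) == dim(matrixB)))
  a <- matrixA[upper.tri(matrixA)]
  b <- matrixB[upper.tri(matrixB)]
  keep <- a != 0 & b != 0 & !is.na(a) & !is.na(b)
  100 * mean(sign(a[keep]) == sign(b[keep]))
}

#' Ratio of mean absolute correlations
#'
#' Mean absolute off-diagonal correlation of `matrixA` divided by that of
#' `matrixB` — e.g. how many fold larger deletion burden correlations are
#' than duplication burden correlations.
#'
#' @inheritParams sign_concordance
#' @return Positive scalar.
#' @export
fold_ratio <- function(matrixA, matrixB) {
  stopifnot(all(dim(matrixA) == dim(matrixB)))
  a <- mean(abs(matrixA[upper.tri(matrixA)]), na.rm = TRUE)
  b <- mean(abs(matrixB[upper.tri(matrixB)]), na.rm = TRUE)
  if (b == 0) stop("denominator matrix has zero mean absolute correlation")
  a / b
}

#' Full between-trait burden correlation analysis for one dosage type
#'
#' Residualizes each trait on covariates, LASSO-filters redundant gene sets
#' (jointly with the Jaccard-percentile criterion), estimates ridge effect
#' profiles and variance-explained proxies over the retained sets, and
#' assembles the trait x trait burden correlation matrix. Binary-trait
#' profiles are converted to the liability scale before covariances are
#' taken. Optional P-Jaccard p-values (see Details) and BH-FDR across trait
#' pairs.
#'
#' P-Jaccard for a regression-derived profile: the trait-2 profile is mapped
#' to gene-level scores (mean coefficient of the sets containing each gene),
#' the scores are permuted over the universe, re-aggregated through the fixed
#' memberships, and the profile covariance with trait 1 recomputed.
#'
#' @param phenotypes,traits As in [funburd()].
#' @param burden A `burden_table`.
#' @param dosage_type `"DEL"` or `"DUP"`.
#' @param collection The [gene_set_collection()] the burden was computed
#'   from; required when `n_perm > 0`.
#' @param retained_sets Optional fixed list of retained set names; when
#'   `NULL` the LASSO + Jaccard filter chooses them.
#' @param n_perm Permutations per trait pair for P-Jaccard p-values (0 = skip).
#' @param seed RNG seed (folds and permutations).
#' @param q_threshold FDR threshold stored in the result.
#' @return List of class `burden_correlation`: `rg`, `p`, `q` (trait x trait
#'   matrices), `h2` (per-trait variance explained), `profiles` (sets x
#'   traits), `retained_sets`, `removal_freq`.
#' @export
burden_correlations <- function(phenotypes, traits, burden,
                                dosage_type = c("DEL", "DUP"),
                                collection = NULL, retained_sets = NULL,
                                n_perm = 0, seed = NULL, q_threshold = 0.05) {
  dosage_type <- match.arg(dosage_type)
  if (!is.null(seed)) set.seed(seed)
  common <- intersect(as.character(phenotypes$sample_id), burden$samples)
  ph <- phenotypes[match(common, as.character(phenotypes$sample_id)), , drop = FALSE]
  X <- burden$x1[[dosage_type]][match(common, burden$samples), , drop = FALSE]
  pc_cols <- grep("^PC[0-9]+$", names(ph), value = TRUE)
  covars <- ph[, c("age", "sex", pc_cols), drop = FALSE]

  n_traits <- nrow(traits)
  resid_mat <- matrix(NA_real_, length(common), n_traits,
                      dimnames = list(common, traits$trait))
  for (i in seq_len(n_traits)) {
    y <- ph[[traits$trait[i]]]
    if (traits$type[i] == "continuous") {
      keep <- outlier_filter(y)
      y[!keep] <- NA
      y <- irnt(y)
      y[is.na(y)] <- 0 # residual of excluded sample carries no signal
      resid_mat[, i] <- residualize(y, covars, "continuous")
    } else {
      resid_mat[, i] <- residualize(y, covars, "binary")
    }
  }

  removal_freq <- NULL
  if (is.null(retained_sets)) {
    lasso <- lasso_selection(resid_mat, X, seed = seed)
    removal_freq <- lasso$removal_freq
    jac <- jaccard_matrix(collection %||% stop("collection needed for filtering"))
    retained_sets <- filter_genesets(jac, removal_freq)
    if (length(retained_sets) < 2L) {
      warning("redundancy filter left fewer than two sets; retaining all")
      retained_sets <- colnames(X)
    }
  }
  Xr <- X[, retained_sets, drop = FALSE]

  profiles <- matrix(NA_real_, length(retained_sets), n_traits,
                     dimnames = list(retained_sets, traits$trait))
  h2 <- stats::setNames(numeric(n_traits), traits$trait)
  for (i in seq_len(n_traits)) {
    prof <- shrinkage_profile(resid_mat[, i], Xr, seed = seed)
    if (traits$type[i] == "binary")
      prof <- liability_transform(prof, traits$prevalence[i])
    profiles[, i] <- prof
    h2[i] <- variance_explained(resid_mat[, i], Xr)
  }

  rg <- p <- matrix(NA_real_, n_traits, n_traits,
                    dimnames = list(traits$trait, traits$trait))
  for (i in seq_len(n_traits - 1)) {
    for (j in seq(i + 1, n_traits)) {
      val <- burden_rg(profiles[, i], profiles[, j], h2[i], h2[j])
      rg[i, j] <- rg[j, i] <- as.numeric(val)
      if (n_perm > 0) {
        sub <- .subset_collection(collection, retained_sets)
        scores_j <- .gene_scores_from_profile(profiles[, j], sub)
        prof_i <- profiles[, i]
        stat_fn <- function(coll, attribute)
          stats::cov(prof_i, .set_attribute_stat(coll, attribute))
        pn <- pjaccard_generic(stat_fn, sub, scores_j, n_perm = n_perm,
                               seed = if (is.null(seed)) NULL else seed + i * 1000L + j)
        p[i, j] <- p[j, i] <- pn$p
      }
    }
  }
  q <- p
  if (n_perm > 0) {
    ut <- upper.tri(p)
    q[ut] <- fdr_correct(p[ut])
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  }
  structure(list(rg = rg, p = p, q = q, h2 = h2, profiles = profiles,
                 retained_sets = retained_sets, removal_freq = removal_freq,
                 dosage_type = dosage_type, q_threshold = q_threshold),
            class = "burden_correlation")
}

#' @export
print.burden_correlation <- function(x, ...) {
  cat("burden correlations (", x$dosage_type, "): ",
      ncol(x$rg), " traits, ", length(x$retained_sets),
      " retained gene sets\n", sep = "")
  cat("  mean |rg| =", signif(mean(abs(x$rg[upper.tri(x$rg)]), na.rm = TRUE), 3), "\n")
  invisible(x)
}

.subset_collection <- function(collection, set_names) {
  gene_set_collection(collection$sets[set_names], universe = collection$universe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
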