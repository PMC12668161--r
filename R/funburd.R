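#' Fit one functional burden association cell
#'
#' Regresses a trait on the gene-set burden predictors and covariates:
#' `trait = b0 + b1*x1 + b2*x2 + b3*age + b4*sex + sum(PC_i) + e`, where `x1`
#' counts set-member genes disrupted by the sample's CNVs of one dosage type
#' and `x2` counts non-member genes disrupted alongside (the multigenic-CNV
#' adjustment). Continuous traits (IRNT-scaled) are fitted by ordinary least
#' squares; binary traits by logistic regression on the raw 0/1 outcome, so
#' `beta` is then on the log-odds scale.
#'
#' Cells with no burden variation (no carriers) are non-estimable and are
#' returned flagged with `beta = 0`, `se = NA`, `p = 1` so the association
#' grid stays rectangular for joint FDR correction.
#'
#' @param y Trait vector (continuous, already IRNT-scaled; or 0/1).
#' @param x1 In-set disrupted gene counts per sample.
#' @param x2 Out-of-set disrupted gene counts per sample.
#' @param covariates Data frame of covariates (age, sex, PC columns).
#' @param trait_type `"continuous"` or `"binary"`.
#' @return List with `beta`, `se`, `p`, `n_carriers`, `estimable`.
#' @export
fit_funburd <- function(y, x1, x2, covariates,
                        trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(length(y) == length(x1), length(x1) == length(x2),
            nrow(covariates) == length(y))
  use <- !is.na(y)
  y <- y[use]; x1 <- x1[use]; x2 <- x2[use]
  covariates <- covariates[use, , drop = FALSE]
  n_carriers <- sum(x1 > 0)
  non_estimable <- list(beta = 0, se = NA_real_, p = 1,
                        n_carriers = n_carriers, estimable = FALSE)
  if (stats::var(x1) == 0) return(non_estimable)
  dat <- data.frame(y = y, x1 = x1, x2 = x2, covariates)
  fit <- if (trait_type == "continuous") {
    stats::lm(y ~ ., data = dat)
  } else {
    if (!all(y %in% c(0, 1))) stop("binary trait must be coded 0/1")
    suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  }
  cf <- summary(fit)$coefficients
  if (!"x1" %in% rownames(cf) || is.na(stats::coef(fit)["x1"])) {
    warning("x1 aliased in design; cell flagged non-estimable")
    return(non_estimable)
  }
  list(beta = unname(cf["x1", 1]), se = unname(cf["x1", 2]),
       p = unname(cf["x1", 4]), n_carriers = n_carriers, estimable = TRUE)
}

# Complete (set x trait x type) rectangle underlying an association grid.
.grid_template <- function(set_names, trait_names, types = c("DEL", "DUP")) {
  expand.grid(gene_set = set_names, trait = trait_names, dosage_type = types,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Functional burden association grid (FunBurd)
#'
#' Fits the functional burden regression for every (gene set, trait, dosage
#' type) cell and corrects the full rectangular grid jointly by
#' Benjamini-Hochberg FDR. Continuous traits are preprocessed by the standard
#' biobank pipeline — outlier removal beyond `outlier_k` SD, then IRNT —
#' unless `preprocess = FALSE` (in which case they are assumed already
#' scaled). Binary traits enter as raw 0/1 outcomes via logistic regression.
#'
#' @param phenotypes Data frame with `sample_id`, `age`, `sex`, `PC1`...`PCk`
#'   columns and one column per trait.
#' @param traits Data frame describing the traits: columns `trait`, `type`
#'   (`"continuous"`/`"binary"`), optional `category` (`"brain"`/
#'   `"non-brain"`) and `prevalence` (binary traits).
#' @param burden A `burden_table` from [aggregate_burden()].
#' @param q_threshold FDR significance threshold carried in the object;
#'   default 0.05.
#' @param preprocess Apply outlier filter + IRNT to continuous traits.
#' @param outlier_k SD multiple for the outlier filter.
#' @return An object of class `funburd` with a `results` data frame holding
#'   one row per grid cell: `gene_set`, `trait`, `dosage_type`, `beta`, `se`,
#'   `p`, `q`, `n_carriers`, `estimable`.
#' @seealso [pleiotropy()], [classify_responses()], [fit_funburd()]
#' @export
funburd <- function(phenotypes, traits, burden, q_threshold = 0.05,
                    preprocess = TRUE, outlier_k = 6) {
  stopifnot(inherits(burden, "burden_table"), is.data.frame(traits),
            all(c("trait", "type") %in% names(traits)),
            "sample_id" %in% names(phenotypes))
  common <- intersect(as.character(phenotypes$sample_id), burden$samples)
  if (length(common) < 10L) stop("fewer than 10 samples shared between phenotypes and burden")
  ph <- phenotypes[match(common, as.character(phenotypes$sample_id)), , drop = FALSE]
  bidx <- match(common, burden$samples)
  pc_cols <- grep("^PC[0-9]+$", names(ph), value = TRUE)
  covars <- ph[, c("age", "sex", pc_cols), drop = FALSE]

  ys <- list()
  for (i in seq_len(nrow(traits))) {
    tr <- traits$trait[i]
    y <- ph[[tr]]
    if (is.null(y)) stop("trait column missing from phenotypes: ", tr)
    if (traits$type[i] == "continuous" && preprocess) {
      keep <- outlier_filter(y, k = outlier_k)
      y[!keep] <- NA
      y <- irnt(y)
    }
    ys[[tr]] <- y
  }

  grid <- .grid_template(burden$sets, traits$trait)
  n <- nrow(grid)
  beta <- se <- p <- numeric(n)
  ncar <- integer(n)
  est <- logical(n)
  for (r in seq_len(n)) {
    type <- grid$dosage_type[r]
    x1 <- burden$x1[[type]][bidx, grid$gene_set[r]]
    x2 <- burden$x2[[type]][bidx, grid$gene_set[r]]
    ttype <- traits$type[match(grid$trait[r], traits$trait)]
    cell <- fit_funburd(ys[[grid$trait[r]]], x1, x2, covars, ttype)
    beta[r] <- cell$beta; se[r] <- cell$se; p[r] <- cell$p
    ncar[r] <- cell$n_carriers; est[r] <- cell$estimable
  }
  results <- cbind(grid, beta = beta, se = se, p = p,
                   q = fdr_correct(p), n_carriers = ncar, estimable = est)
  structure(list(results = results, sets = burden$sets, traits = traits,
                 n_samples = length(common), q_threshold = q_threshold,
                 x2_scope = burden$x2_scope, call = match.call()),
            class = "funburd")
}

#' Benjamini-Hochberg FDR correction
#'
#' Joint step-up FDR over a vector of p-values — applied over the entire
#' association grid (all gene sets, traits and both dosage types at once).
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, monotone non-decreasing in `p`.
#' @export
fdr_correct <- function(p) stats::p.adjust(p, method = "BH")

#' Functional pleiotropy per gene set
#'
#' Functional pleiotropy is the number of traits significantly associated
#' with a gene set (at the grid-wide FDR threshold), reported per dosage type
#' with the percentage over all analyzed traits.
#'
#' @param object A `funburd` fit (or its `results` data frame).
#' @param q_threshold FDR threshold; defaults to the fit's own.
#' @return Data frame with `gene_set`, `dosage_type`, `n_sig`, `pct_sig`.
#' @export
pleiotropy <- function(object, q_threshold = NULL) {
  res <- if (inherits(object, "funburd")) object$results else object
  if (is.null(q_threshold))
    q_threshold <- if (inherits(object, "funburd")) object$q_threshold else 0.05
  n_traits <- length(unique(res$trait))
  sig <- res$q < q_threshold
  agg <- stats::aggregate(sig, by = list(gene_set = res$gene_set,
                                         dosage_type = res$dosage_type), FUN = sum)
  names(agg)[3] <- "n_sig"
  agg$pct_sig <- 100 * agg$n_sig / n_traits
  agg[order(agg$dosage_type, agg$gene_set), , drop = FALSE]
}

#' Two-proportion comparison
#'
#' Two-sided two-proportion z test (chi-squared without continuity
#' correction), used to compare fractions of significant associations between
#' groups, e.g. deletions versus duplications.
#'
#' @param countA,nA Successes and total in group A.
#' @param countB,nB Successes and total in group B.
#' @return Two-sided p-value.
#' @export
proportion_compare <- function(countA, nA, countB, nB) {
  if (nA <= 0 || nB <= 0) stop("group totals must be positive")
  if (countA > nA || countB > nB) stop("counts cannot exceed totals")
  phat <- (countA + countB) / (nA + nB)
  if (phat == 0 || phat == 1) return(1)
  suppressWarnings(
    stats::prop.test(c(countA, countB), c(nA, nB), correct = FALSE)$p.value)
}

#' Liability-scale conversion of logistic effect sizes
#'
#' Rescales a logistic regression coefficient for a binary trait with
#' population prevalence `K` onto the liability scale:
#' `beta_liability = beta_logistic * dnorm(t) / (K * (1 - K))` with
#' `t = qnorm(1 - K)`. This puts binary-trait effects on a scale comparable
#' with continuous-trait effects for cross-trait covariance analyses.
#'
#' @param beta_logistic Numeric vector of log-odds effect sizes.
#' @param K Population prevalence in (0, 1) (scalar or vector).
#' @return Liability-scale effect sizes.
#' @export
liability_transform <- function(beta_logistic, K) {
  if (any(!is.finite(K)) || any(K <= 0) || any(K >= 1))
    stop("prevalence K must lie in (0, 1)")
  t <- stats::qnorm(1 - K)
  beta_logistic * stats::dnorm(t) / (K * (1 - K))
}

#' @export
print.funburd <- function(x, ...) {
  res <- x$results
  cat("FunBurd association grid\n")
  cat("  ", length(x$sets), " gene sets x ", nrow(x$traits),
      " traits x 2 dosage types = ", nrow(res), " cells\n", sep = "")
  cat("  samples:", x$n_samples, "  x2 scope:", x$x2_scope, "\n")
  cat("  FDR-significant cells (q < ", x$q_threshold, "): ",
      sum(res$q < x$q_threshold), "\n", sep = "")
  invisible(x)
}

#' @export
summary.funburd <- function(object, ...) {
  res <- object$results
  sig <- res$q < object$q_threshold
  by_type <- tapply(sig, res$dosage_type, sum)
  out <- list(
    n_cells = nrow(res),
    n_sets = length(object$sets),
    n_traits = nrow(object$traits),
    n_samples = object$n_samples,
    q_threshold = object$q_threshold,
    sig_by_type = by_type,
    sig_fraction_by_type = by_type / (nrow(res) / 2),
    prop_test_del_vs_dup = proportion_compare(by_type[["DEL"]], nrow(res) / 2,
                                              by_type[["DUP"]], nrow(res) / 2),
    top = utils::head(res[order(res$p), ], 10))
  class(out) <- "summary.funburd"
  out
}

#' @export
print.summary.funburd <- function(x, ...) {
  cat("FunBurd grid:", x$n_sets, "sets x", x$n_traits, "traits x 2 types =",
      x$n_cells, "cells;", x$n_samples, "samples\n")
  cat(sprintf("  significant at q < %g: DEL %d (%.1f%%), DUP %d (%.1f%%); del-vs-dup proportion p = %.3g\n",
              x$q_threshold, x$sig_by_type[["DEL"]],
              100 * x$sig_fraction_by_type[["DEL"]], x$sig_by_type[["DUP"]],
              100 * x$sig_fraction_by_type[["DUP"]], x$prop_test_del_vs_dup))
  cat("  strongest associations:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Effect-size matrices from a FunBurd fit
#'
#' @param object A `funburd` fit.
#' @param dosage_type `"DEL"`, `"DUP"`, or `NULL` for both.
#' @param ... Unused.
#' @return A sets x traits matrix of `beta`, or a named list of two such
#'   matrices.
#' @export
coef.funburd <- function(object, dosage_type = NULL, ...) {
  one <- function(type) {
    res <- object$results[object$results$dosage_type == type, ]
    m <- matrix(NA_real_, length(object$sets), nrow(object$traits),
                dimnames = list(object$sets, object$traits$trait))
    m[cbind(res$gene_set, res$trait)] <- res$beta
    m
  }
  if (is.null(dosage_type)) list(DEL = one("DEL"), DUP = one("DUP"))
  else one(match.arg(dosage_type, c("DEL", "DUP")))
}

#' Heatmap of FunBurd effect sizes
#'
#' Base-graphics heatmap of the effect-size matrix for one dosage type, with
#' FDR-significant cells marked by asterisks.
#'
#' @param x A `funburd` fit.
#' @param dosage_type `"DEL"` or `"DUP"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.funburd <- function(x, dosage_type = "DEL", ...) {
  b <- coef(x, dosage_type)
  lim <- max(abs(b), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(51)
  graphics::image(seq_len(nrow(b)), seq_len(ncol(b)), b,
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = paste("FunBurd effect sizes,", dosage_type), ...)
  graphics::axis(1, seq_len(nrow(b)), rownames(b), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(ncol(b)), colnames(b), las = 2, cex.axis = 0.7)
  res <- x$results[x$results$dosage_type == dosage_type &
                     x$results$q < x$q_threshold, ]
  if (nrow(res))
    graphics::text(match(res$gene_set, rownames(b)),
                   match(res$trait, colnames(b)), "*")
  invisible(x)
}
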