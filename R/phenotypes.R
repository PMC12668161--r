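#' Outlier filter by standard-deviation distance
#'
#' Marks values retained after removing missing entries and entries more than
#' `k` standard deviations from the mean (mean and SD computed on the
#' non-missing values). The default `k = 6` is the conventional broad filter
#' for biobank-scale continuous traits, removing only gross measurement
#' errors.
#'
#' @param values Numeric vector.
#' @param k Standard-deviation multiple; default 6.
#' @return Logical mask aligned with `values`; `FALSE` for missing values and
#'   outliers.
#' @export
outlier_filter <- function(values, k = 6) {
  if (sum(!is.na(values)) < 2L) stop("need at least two non-missing values")
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (s == 0) {
    warning("constant trait: no outliers to filter")
    return(!is.na(values))
  }
  !is.na(values) & abs(values - m) <= k * s
}

#' Inverse rank normal transformation (IRNT)
#'
#' Ranks the values (ties receive their average rank) and maps rank `r` of `n`
#' to the standard-normal quantile `qnorm((r - 0.5) / n)`. The result is
#' invariant to strictly monotone transforms of the input, which is why
#' biobank GWAS pipelines use it to put heterogeneous continuous traits on a
#' common scale.
#'
#' @param values Numeric vector; missing values propagate as `NA`.
#' @return Numeric vector of normal quantiles.
#' @export
irnt <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(unique(v)) < 2L) stop("IRNT undefined: fewer than two distinct values")
  n <- length(v)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  out
}

#' Residualize a trait on covariates
#'
#' Removes covariate effects before penalized burden modelling. Continuous
#' traits (assumed IRNT-scaled) are residualized by ordinary least squares.
#' Binary traits are fitted by logistic regression and the response-scale
#' residuals (observed minus fitted probability) are returned, to be treated
#' as continuous outcomes downstream. If the logistic fit separates, a
#' lightly ridge-penalized logistic fit is used instead, with a warning.
#'
#' @param y Numeric (continuous) or 0/1 (binary) outcome vector.
#' @param covariates Data frame or matrix of covariates (age, sex, PCs).
#' @param trait_type `"continuous"` or `"binary"`.
#' @return Numeric vector of residuals aligned with `y`.
#' @export
residualize <- function(y, covariates, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (trait_type == "continuous") {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    return(as.vector(fit$residuals))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged) {
    warning("separation in logistic covariate fit; using ridge-penalized fit")
    pen <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 1e-3)
    fitted <- as.vector(stats::predict(pen, newx = X, type = "response"))
    return(y - fitted)
  }
  y - fit$fitted.values
}
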