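covmat <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5))
  for (k in 1:10) d[[paste0("PC", k)]] <- rnorm(n)
  d
}

test_that("residualization leaves nothing correlated with the covariates", {
  n <- 500
  cov <- covmat(n, 1)
  y <- 0.05 * cov$age + 0.3 * cov$sex + rnorm(n)
  r <- residualize(y, cov, "continuous")
  for (j in seq_along(cov)) expect_lt(abs(cor(r, cov[[j]])), 1e-10)
  # trait exactly linear in covariates -> residuals ~ 0
  y2 <- 1 + 0.1 * cov$age - 2 * cov$sex + 0.5 * cov$PC3
  expect_lt(max(abs(residualize(y2, cov, "continuous"))), 1e-8)
  # orthogonal covariates -> residuals are the centered trait
  set.seed(2)
  yy <- rnorm(n)
  Xo <- data.frame(a = rep(c(-1, 1), n / 2))
  r2 <- residualize(yy, Xo, "continuous")
  expect_equal(r2, yy - mean(yy) -
                 cov(yy, Xo$a) / var(Xo$a) * (Xo$a - mean(Xo$a)),
               tolerance = 1e-8)
})

test_that("binary residuals are observed minus fitted probability", {
  set.seed(3)
  n <- 800
  cov <- covmat(n, 3)
  y <- rbinom(n, 1, plogis(-1 + 0.02 * (cov$age - 55)))
  r <- residualize(y, cov, "binary")
  fit <- glm(y ~ ., data = cbind(y = y, cov), family = binomial())
  expect_equal(r, unname(y - fitted(fit)), tolerance = 1e-8)
})

test_that("LASSO selection finds planted supports and respects limits", {
  set.seed(4)
  n <- 400
  X <- matrix(rpois(n * 6, 0.8), n, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  X[, 6] <- 0 # all-zero burden column
  hits <- 0
  for (r in 1:20) {
    y <- 1.2 * X[, 3] + rnorm(n)
    sel <- lasso_selection(cbind(t1 = y), X, seed = r)
    if (sel$selected["s3", "t1"]) hits <- hits + 1
    expect_false(sel$selected["s6", "t1"]) # zero column never selected
  }
  expect_gte(hits / 20, 0.95)
  # penalty -> infinity removes everything
  y <- 1.2 * X[, 3] + rnorm(n)
  sel_inf <- lasso_selection(cbind(t1 = y), X, lambda = 1e6)
  expect_true(all(!sel_inf$selected))
  expect_equal(unname(sel_inf$removal_freq), rep(1, 6))
  expect_error(lasso_selection(cbind(t1 = y), X[, 1, drop = FALSE]), "two")
})

test_that("redundancy filter needs BOTH high overlap percentile and frequent removal", {
  j <- diag(6)
  rownames(j) <- colnames(j) <- paste0("s", 1:6)
  j["s1", "s2"] <- j["s2", "s1"] <- 1     # duplicated pair
  j["s3", "s4"] <- j["s4", "s3"] <- 0.5
  j["s5", "s6"] <- j["s6", "s5"] <- 0.03
  j["s4", "s6"] <- j["s6", "s4"] <- 0.1
  # max similarities: s1,s2 = 1; s3,s4 = 0.5; s6 = 0.1; s5 = 0.03
  rf <- c(s1 = 0.1, s2 = 1.0, s3 = 0.9, s4 = 0.0, s5 = 1.0, s6 = 0.0)
  kept <- filter_genesets(j, rf)
  expect_false("s2" %in% kept)  # high percentile AND freq >= 0.8
  expect_false("s3" %in% kept)
  expect_true("s1" %in% kept)   # high percentile but LASSO keeps it
  expect_true("s5" %in% kept)   # always removed but lowest overlap percentile
  # no set meets both conditions -> all retained
  expect_equal(filter_genesets(j, setNames(rep(0, 6), rownames(j))),
               paste0("s", 1:6))
})

test_that("ridge profile shares weight across collinear sets and obeys penalty limits", {
  set.seed(5)
  n <- 300
  x <- rpois(n, 1)
  X <- cbind(a = x, b = x, c = rpois(n, 1))
  y <- 0.8 * x + 0.2 * X[, "c"] + rnorm(n, 0, 0.3)
  prof <- shrinkage_profile(y, X, lambda = 0.5)
  expect_equal(prof[["a"]], prof[["b"]], tolerance = 1e-3)
  big <- shrinkage_profile(y, X, lambda = 1e7)
  expect_lt(max(abs(big)), 1e-3)
  # near-zero penalty on a well-conditioned design approaches OLS
  set.seed(6)
  X2 <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  y2 <- X2 %*% c(0.5, -0.3, 0) + rnorm(n, 0, 0.2)
  prof2 <- shrinkage_profile(as.vector(y2), X2, lambda = 1e-5)
  ols <- ols_normal_equations(cbind(1, X2), as.vector(y2))[-1, 1]
  expect_equal(unname(prof2), unname(ols), tolerance = 1e-3)
})

test_that("variance explained behaves like an R-squared", {
  set.seed(7)
  n <- 200
  X <- matrix(rpois(n * 4, 1), n, 4)
  y_lin <- as.vector(X %*% c(1, -1, 0.5, 2))
  expect_equal(variance_explained(y_lin, X), 1, tolerance = 1e-10)
  y_noise <- rnorm(n)
  r2 <- variance_explained(y_noise, X)
  expect_lt(r2, 3 * ncol(X) / n) # null expectation ~ p/n
  expect_gte(variance_explained(y_noise, cbind(X, rpois(n, 1))), r2) # nested
  expect_error(variance_explained(rnorm(3), matrix(1:12, 3, 4)), "more samples")
})

test_that("burden rg follows the covariance formula and its symmetries", {
  p1 <- c(1, -1, 2, 0)
  p2 <- c(1, 1, 0.5, 1.5) # cov(p1, p2) = ?
  expect_equal(as.numeric(burden_rg(p1, p2, 0.04, 0.09)),
               cov(p1, p2) / sqrt(0.04 * 0.09))
  orth <- c(1, -1, 1, -1)
  expect_equal(as.numeric(burden_rg(orth, rep(2, 4) , 0.1, 0.1)), 0)
  expect_equal(as.numeric(burden_rg(-p1, p2, 0.04, 0.09)),
               -as.numeric(burden_rg(p1, p2, 0.04, 0.09)))
  expect_error(burden_rg(p1, p2, 0, 0.1), "positive")
  # homogeneity: scaling both profiles by c and both h2 by c^2 leaves rg fixed
  cc <- 3.7
  expect_equal(as.numeric(burden_rg(cc * p1, cc * p2, cc^2 * 0.04, cc^2 * 0.09)),
               as.numeric(burden_rg(p1, p2, 0.04, 0.09)), tolerance = 1e-12)
  big <- burden_rg(10 * p1, 10 * p2, 0.01, 0.01)
  expect_true(attr(big, "out_of_range"))
})

test_that("sign concordance and fold ratio match direct computation", {
  A <- matrix(c(1, 0.5, -0.2, 0.5, 1, 0.4, -0.2, 0.4, 1), 3)
  expect_equal(sign_concordance(A, A), 100)
  expect_equal(sign_concordance(A, -A), 0)
  expect_equal(fold_ratio(2 * A, A), 2)
  expect_equal(fold_ratio(A, A), 1)
  B <- matrix(c(1, 0.1, 0.1, 0.1, 1, -0.8, 0.1, -0.8, 1), 3)
  expect_equal(fold_ratio(A, B),
               mean(abs(c(0.5, -0.2, 0.4))) / mean(abs(c(0.1, 0.1, -0.8))))
  set.seed(8)
  r1 <- matrix(rnorm(100), 10); r2 <- matrix(rnorm(100), 10)
  expect_lt(abs(sign_concordance(r1, r2) - 50), 35) # Bernoulli(0.5) on 45 pairs
  expect_error(fold_ratio(A, A * 0), "zero")
})

test_that("deletion and duplication correlation channels are independent", {
  co <- cached_cohort()
  coll <- gene_set_collection(co$truth$marker_sets, universe = co$genes$gene_id)
  bc1 <- burden_correlations(co$phenotypes, co$traits, co$burden_true,
                             dosage_type = "DEL", collection = coll,
                             retained_sets = names(coll$sets), seed = 1)
  # scramble the duplication channel only
  set.seed(42)
  bt2 <- co$burden_true
  bt2$x1$DUP <- bt2$x1$DUP[sample(nrow(bt2$x1$DUP)), ]
  bc2 <- burden_correlations(co$phenotypes, co$traits, bt2,
                             dosage_type = "DEL", collection = coll,
                             retained_sets = names(coll$sets), seed = 1)
  expect_identical(bc1$rg, bc2$rg)
  expect_s3_class(bc1, "burden_correlation")
  expect_equal(bc1$rg, t(bc1$rg))
})
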