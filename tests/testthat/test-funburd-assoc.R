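fake_covars <- function(n, seed = 1) {
  set.seed(seed)
  d <- data.frame(age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5))
  for (k in 1:10) d[[paste0("PC", k)]] <- rnorm(n)
  d
}

test_that("outlier filter drops only beyond-k-SD values, on the observed scale", {
  v <- c(0, 0, 0, 100)
  # oracle: mean 25, SD 50 -> 100 lies 1.5 SD away, retained at k = 6
  expect_true(all(outlier_filter(v, k = 6)))
  expect_equal(outlier_filter(c(rep(0, 1000), 1e6), k = 6),
               c(rep(TRUE, 1000), FALSE))
  expect_warning(mask <- outlier_filter(rep(3, 5)), "constant")
  expect_true(all(mask))
  expect_equal(outlier_filter(c(1, NA, 2)), c(TRUE, FALSE, TRUE))
  expect_error(outlier_filter(c(NA, 1)), "non-missing")
})

test_that("IRNT maps ranks to normal quantiles and ignores monotone rescaling", {
  expect_equal(irnt(c(10, 20, 30)),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  x <- rexp(101)
  expect_equal(irnt(x), irnt(exp(x)))
  expect_equal(sort(irnt(x))[51], 0) # median of odd-length distinct input
  expect_error(irnt(rep(1, 5)), "distinct")
  # ties share the average rank
  expect_equal(irnt(c(1, 1, 2))[1], irnt(c(1, 1, 2))[2])
})

test_that("continuous fit matches the normal-equations solution exactly", {
  set.seed(2)
  n <- 50
  cov <- fake_covars(n, 2)
  x1 <- rpois(n, 0.5); x2 <- rpois(n, 1)
  y <- 0.4 * x1 + 0.1 * x2 + 0.02 * cov$age + rnorm(n)
  fit <- fit_funburd(y, x1, x2, cov, "continuous")
  X <- cbind(1, x1, x2, as.matrix(cov))
  expect_equal(fit$beta, unname(ols_normal_equations(X, y)[2, 1]),
               tolerance = 1e-8)
  expect_true(fit$estimable)
  expect_equal(fit$n_carriers, sum(x1 > 0))
})

test_that("planted effect recovered within 3 SE; degenerate cells flagged", {
  set.seed(3)
  n <- 2000
  cov <- fake_covars(n, 3)
  x1 <- rpois(n, 0.3); x2 <- rpois(n, 0.5)
  y <- 0.5 * x1 + rnorm(n, 0, 0.1)
  fit <- fit_funburd(y, x1, x2, cov, "continuous")
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)

  none <- fit_funburd(y, rep(0, n), x2, cov, "continuous")
  expect_false(none$estimable)
  expect_equal(none$p, 1)
  expect_equal(none$beta, 0)
  const <- fit_funburd(y, rep(2, n), x2, cov, "continuous")
  expect_false(const$estimable) # no carriers variation, same contract
})

test_that("binary traits are fitted by logistic regression on the raw outcome", {
  set.seed(4)
  n <- 1500
  cov <- fake_covars(n, 4)
  x1 <- rpois(n, 0.4); x2 <- rpois(n, 0.6)
  eta <- -1 + 0.8 * x1
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_funburd(y, x1, x2, cov, "binary")
  oracle <- glm(y ~ ., data = data.frame(y, x1, x2, cov), family = binomial())
  expect_equal(fit$beta, unname(coef(oracle)["x1"]), tolerance = 1e-10)
  expect_lt(abs(fit$beta - 0.8), 3 * fit$se)
  expect_error(fit_funburd(y + 1, x1, x2, cov, "binary"), "0/1")
})

test_that("BH correction matches an independent step-up implementation", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_correct(0.007), 0.007) # m = 1 identity
  set.seed(5)
  for (r in 1:20) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    q <- fdr_correct(p)
    expect_equal(q, bh_stepup(p))
    expect_true(all(q[order(p)] == cummax(q[order(p)]))) # monotone in p
    expect_true(all(q >= p))
  }
})

test_that("pleiotropy counts FDR-significant traits per set and type", {
  grid <- funburd:::.grid_template("S", sprintf("t%02d", 1:43))
  grid$q <- 1
  grid$q[grid$dosage_type == "DEL" & grid$trait %in% sprintf("t%02d", 1:5)] <- 0.01
  pl <- pleiotropy(grid, q_threshold = 0.05)
  del <- pl[pl$dosage_type == "DEL", ]
  expect_equal(del$n_sig, 5)
  expect_equal(del$pct_sig, 100 * 5 / 43, tolerance = 1e-10)
  expect_equal(pl$n_sig[pl$dosage_type == "DUP"], 0)
  expect_true(all(pl$n_sig <= 43))
})

test_that("two-proportion test follows the z formula and its symmetries", {
  expect_equal(proportion_compare(10, 100, 10, 100), 1)
  # counts reported for deletion vs duplication significant fractions
  p <- proportion_compare(568, 2580, 352, 2580)
  z <- (568 / 2580 - 352 / 2580) /
    sqrt((920 / 5160) * (1 - 920 / 5160) * (2 / 2580))
  expect_equal(p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_lt(p, 1e-10)
  expect_equal(p, proportion_compare(352, 2580, 568, 2580))
  expect_error(proportion_compare(5, 0, 1, 10), "positive")
  expect_error(proportion_compare(11, 10, 1, 10), "exceed")
})

test_that("liability transform applies phi(t) / (K(1-K)) and its symmetry", {
  expect_equal(liability_transform(0, 0.123), 0)
  expect_equal(liability_transform(1, 0.5), dnorm(0) / 0.25, tolerance = 1e-12)
  expect_equal(liability_transform(1, 0.5), 1.595769, tolerance = 1e-6)
  for (K in c(0.01, 0.2, 0.4)) {
    expect_equal(liability_transform(2.5, K), liability_transform(2.5, 1 - K))
    t <- qnorm(1 - K)
    expect_equal(liability_transform(1, K), dnorm(t) / (K * (1 - K)))
  }
  expect_error(liability_transform(1, 0), "K")
  expect_error(liability_transform(1, 1), "K")
})

test_that("an irrelevant noise covariate barely moves the burden coefficient", {
  set.seed(6)
  n <- 1000
  deltas <- ses <- numeric(20)
  for (r in 1:20) {
    cov <- fake_covars(n, 600 + r)
    x1 <- rpois(n, 0.4); x2 <- rpois(n, 0.6)
    y <- 0.3 * x1 + 0.05 * x2 + rnorm(n)
    f1 <- fit_funburd(y, x1, x2, cov, "continuous")
    cov$noise <- rnorm(n)
    f2 <- fit_funburd(y, x1, x2, cov, "continuous")
    deltas[r] <- abs(f2$beta - f1$beta)
    ses[r] <- f1$se
  }
  expect_lt(mean(deltas), mean(ses))
})

test_that("the grid object is rectangular with joint FDR and carries metadata", {
  co <- cached_cohort()
  coll <- build_tdep_sets(expression_proportion(co$expression))
  bt <- aggregate_burden(co$cnvs, co$genes, coll,
                         samples = co$phenotypes$sample_id)
  fit <- funburd(co$phenotypes, co$traits, bt)
  expect_s3_class(fit, "funburd")
  expect_equal(nrow(fit$results), length(coll) * nrow(co$traits) * 2)
  expect_equal(fit$results$q, fdr_correct(fit$results$p))
  expect_true(all(fit$results$q >= fit$results$p))
  cf <- coef(fit)
  expect_equal(dim(cf$DEL), c(length(coll), nrow(co$traits)))
  expect_output(print(fit), "gene sets")
  expect_output(print(summary(fit)), "significant")
})
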