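fake_grid <- function(cells) {
  # cells: list of c(set, trait, del_beta, del_q, dup_beta, dup_q)
  do.call(rbind, lapply(cells, function(cl)
    data.frame(gene_set = cl[[1]], trait = cl[[2]],
               dosage_type = c("DEL", "DUP"),
               beta = as.numeric(c(cl[[3]], cl[[5]])),
               q = as.numeric(c(cl[[4]], cl[[6]])),
               stringsAsFactors = FALSE)))
}

test_that("dosage responses follow the sign and evidence rule table", {
  grid <- fake_grid(list(
    list("S1", "t1", -0.2, 0.01, +0.1, 0.3),   # monotonic, undetermined_del
    list("S1", "t2", +0.2, 0.01, +0.3, 0.01),  # non-monotonic, truly
    list("S1", "t3", +0.2, 0.9, -0.1, 0.9),    # null
    list("S2", "t1", -0.3, 0.01, +0.2, 0.01),  # monotonic, truly
    list("S2", "t2", +0.1, 0.4, +0.2, 0.02),   # non-monotonic, undetermined_dup
    list("S2", "t3", 0.0, 0.01, +0.2, 0.3)))   # zero effect -> non-monotonic
  r <- classify_responses(grid)
  get <- function(s, t) r[r$gene_set == s & r$trait == t, ]
  expect_equal(get("S1", "t1")$sign_class, "monotonic")
  expect_equal(get("S1", "t1")$evidence_class, "undetermined_del")
  expect_equal(get("S1", "t2")$evidence_class, "truly_non_monotonic")
  expect_true(is.na(get("S1", "t3")$sign_class))
  expect_equal(get("S1", "t3")$evidence_class, "null")
  expect_equal(get("S2", "t1")$evidence_class, "truly_monotonic")
  expect_equal(get("S2", "t2")$evidence_class, "undetermined_dup")
  expect_equal(get("S2", "t3")$sign_class, "non-monotonic")

  s <- summary(r)
  expect_equal(s$n_non_null, 5)
  expect_equal(sum(s$evidence_counts), 6) # partition of all set-trait pairs
  expect_output(print(s), "monotonic")

  expect_error(classify_responses(grid[grid$dosage_type == "DEL", ]),
               "rectangular")
})

test_that("swapping DEL and DUP labels preserves signs and mirrors evidence", {
  set.seed(1)
  cells <- lapply(1:40, function(i)
    list(paste0("S", (i - 1) %% 8 + 1), paste0("t", (i - 1) %/% 8 + 1),
         rnorm(1), runif(1)^2, rnorm(1), runif(1)^2))
  grid <- fake_grid(cells)
  swapped <- grid
  swapped$dosage_type <- ifelse(grid$dosage_type == "DEL", "DUP", "DEL")
  r1 <- classify_responses(grid)
  r2 <- classify_responses(swapped)
  key <- paste(r1$gene_set, r1$trait)
  r2 <- r2[match(key, paste(r2$gene_set, r2$trait)), ]
  expect_equal(r1$sign_class, r2$sign_class)
  map <- c(null = "null", truly_monotonic = "truly_monotonic",
           truly_non_monotonic = "truly_non_monotonic",
           undetermined_del = "undetermined_dup",
           undetermined_dup = "undetermined_del")
  expect_equal(unname(map[r1$evidence_class]), r2$evidence_class)
  # partition property
  expect_equal(sum(table(r1$evidence_class)), 40)
})

test_that("del-dup effect correlations hit the algebraic extremes", {
  co <- cached_cohort()
  coll <- gene_set_collection(co$truth$marker_sets, universe = co$genes$gene_id)
  sets <- names(coll$sets)
  set.seed(2)
  beta_del <- rnorm(length(sets))
  grid <- rbind(
    data.frame(gene_set = sets, trait = "t1", dosage_type = "DEL",
               beta = beta_del),
    data.frame(gene_set = sets, trait = "t1", dosage_type = "DUP",
               beta = -beta_del))
  obj <- structure(list(results = grid, sets = sets,
                        traits = data.frame(trait = "t1", type = "continuous")),
                   class = "funburd")
  out <- deldup_effect_correlation(obj, "t1", coll, n_perm = 150, seed = 3)
  expect_equal(out$r, -1)
  obj$results$beta[obj$results$dosage_type == "DUP"] <- beta_del
  out2 <- deldup_effect_correlation(obj, "t1", coll, n_perm = 150, seed = 3)
  expect_equal(out2$r, 1)
})

test_that("monotonic fractions tally per trait and compare groups", {
  grid <- fake_grid(list(
    list("S1", "tA", -1, 0.01, 1, 0.01),  # monotonic
    list("S2", "tA", -1, 0.01, 1, 0.3),   # monotonic
    list("S1", "tB", 1, 0.01, 1, 0.01),   # non-monotonic
    list("S2", "tB", -1, 0.01, 1, 0.01),  # monotonic
    list("S1", "tC", 1, 0.01, 1, 0.3),    # non-monotonic
    list("S2", "tC", 2, 0.9, 1, 0.9)))    # null
  r <- classify_responses(grid)
  out <- monotonic_fraction_by_group(r, c(tA = "brain", tB = "brain",
                                          tC = "non-brain"))
  frac <- setNames(out$per_trait$monotonic_fraction, out$per_trait$trait)
  expect_equal(unname(frac[c("tA", "tB", "tC")]), c(1, 0.5, 0))
  expect_true(all(frac >= 0 & frac <= 1))
  expect_true("group_p" %in% names(out))

  # a trait with no non-null responses is excluded with a warning
  grid2 <- fake_grid(list(list("S1", "tD", 1, 0.9, 1, 0.9),
                          list("S1", "tE", -1, 0.01, 1, 0.2)))
  expect_warning(out2 <- monotonic_fraction_by_group(classify_responses(grid2)),
                 "excluded")
  expect_equal(out2$per_trait$trait, "tE")
})

test_that("functional overlap test matches the hypergeometric tail", {
  universe <- sprintf("u%03d", 1:172)
  ten <- universe[1:10]
  same <- functional_overlap_test(ten, ten, universe, n_perm = 1000, seed = 1)
  expect_equal(same$observed, 1)
  expect_equal(same$p, 1 / 1001)

  # degenerate universe: every draw matches everything
  tiny <- functional_overlap_test(c("a", "b"), c("a", "b"), c("a", "b"),
                                  n_perm = 200, seed = 2)
  expect_equal(tiny$observed, 1)
  expect_equal(tiny$p, 1)

  disj <- functional_overlap_test("a", "b", c("a", "b", "c"),
                                  n_perm = 200, seed = 3)
  expect_equal(disj$observed, 0)
  expect_gt(disj$p, 0.5)

  # exact tail check on a small configuration
  uni <- sprintf("v%02d", 1:12)
  cnv <- uni[1:4]; ref <- uni[3:7]
  ot <- functional_overlap_test(cnv, ref, uni, n_perm = 4000, seed = 4)
  obs_k <- length(intersect(cnv, ref))
  exact <- sum(dhyper(obs_k:4, 5, 7, 4)) # P(X >= observed)
  expect_lt(abs(ot$p - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)
  expect_gte(ot$p, 1 / 4001)

  expect_error(functional_overlap_test(character(0), ref, uni), "undefined")
})
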