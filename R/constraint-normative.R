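#' Constrained fraction of a gene set
#'
#' Fraction of set members that belong to the top decile of a genetic
#' constraint metric (LOEUF, pLI, missense-Z, CDS conservation, pHaplo,
#' pTriplo, s-het or gene length — all consumed as precomputed top-decile
#' flags).
#'
#' @param gene_set Character vector of member genes.
#' @param top_decile_genes Character vector of top-decile (constrained)
#'   genes.
#' @return Fraction in `[0, 1]`.
#' @export
constrained_fraction <- function(gene_set, top_decile_genes) {
  if (length(gene_set) == 0L) stop("empty gene set")
  length(intersect(gene_set, top_decile_genes)) / length(unique(gene_set))
}

#' Constrained fractions for every set in a collection
#'
#' @param collection A [gene_set_collection()].
#' @param constraint_flags Named logical vector over the universe (`TRUE` =
#'   top-decile constrained) or a character vector of constrained genes.
#' @return Named numeric vector of fractions per set.
#' @export
constrained_fractions <- function(collection, constraint_flags) {
  top <- if (is.character(constraint_flags)) constraint_flags
         else names(constraint_flags)[constraint_flags]
  vapply(collection$sets, constrained_fraction, numeric(1),
         top_decile_genes = top)
}

#' Correlation between constraint and pleiotropy with P-Jaccard p-value
#'
#' Pearson correlation between per-set constrained fractions and per-set
#' functional pleiotropy, with significance assessed by the overlap-aware
#' gene-permutation null ([pjaccard_correlation()], constraint flags as the
#' gene-level attribute).
#'
#' @param fractions Per-set constrained fractions (aligned with the
#'   collection).
#' @param pleiotropy Per-set pleiotropy values (counts or percentages).
#' @param collection A [gene_set_collection()].
#' @param constraint_flags Named logical attribute over the universe.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `r` and the `permutation_null` object (element `null`).
#' @export
constraint_pleiotropy_correlation <- function(fractions, pleiotropy, collection,
                                              constraint_flags, n_perm = 1000,
                                              seed = NULL) {
  if (stats::sd(fractions) == 0 || stats::sd(pleiotropy) == 0)
    stop("correlation undefined: constant vector")
  pn <- pjaccard_correlation(set_stat_a = fractions, set_stat_b = pleiotropy,
                             collection = collection,
                             attribute = as.numeric(constraint_flags) |>
                               stats::setNames(names(constraint_flags)),
                             n_perm = n_perm, seed = seed)
  list(r = pn$observed, p = pn$p, null = pn)
}

#' Normative model of pleiotropy versus genetic constraint
#'
#' Builds the expected distribution of functional pleiotropy for gene sets of
#' a given size as a function of their constrained fraction: for each
#' fraction `f` on the grid, `n_reps` gene sets of `set_size` genes are drawn
#' without replacement (`floor(f * set_size)` constrained + the rest
#' unconstrained), the full FunBurd analysis is run for each, and its
#' pleiotropy recorded. Centile curves over the draws define the normative
#' bands against which an observed set's pleiotropy is expressed as a
#' centile.
#'
#' @param constraint_flags Named logical vector over the gene universe.
#' @param funburd_runner Function mapping a character vector of gene ids to a
#'   pleiotropy value (see [make_funburd_runner()]).
#' @param fraction_grid Grid of constrained fractions (default 0 to 0.6 by
#'   0.05).
#' @param set_size Genes per sampled set (the cohort-scale default is 1298;
#'   reduce for small universes).
#' @param n_reps Resamples per grid point (default 100).
#' @param seed RNG seed.
#' @return Object of class `normative_bands`: `draws` (n_reps x grid),
#'   `centiles` (long data frame: fraction, centile, value), and the sampling
#'   parameters.
#' @export
normative_model <- function(constraint_flags, funburd_runner,
                            fraction_grid = seq(0, 0.6, by = 0.05),
                            set_size = 1298, n_reps = 100, seed = NULL) {
  stopifnot(is.logical(constraint_flags), !is.null(names(constraint_flags)))
  if (!is.null(seed)) set.seed(seed)
  con <- names(constraint_flags)[constraint_flags]
  uncon <- names(constraint_flags)[!constraint_flags]
  probs <- c(5, 10, 25, 50, 75, 90, 95) / 100
  keep <- vapply(fraction_grid, function(f) {
    n_con <- floor(f * set_size)
    ok <- n_con <= length(con) && (set_size - n_con) <= length(uncon)
    if (!ok) warning("skipping fraction ", f, ": not enough genes to sample")
    ok
  }, logical(1))
  fraction_grid <- fraction_grid[keep]
  if (!length(fraction_grid)) stop("no feasible fraction grid points")
  draws <- matrix(NA_real_, n_reps, length(fraction_grid),
                  dimnames = list(NULL, format(fraction_grid)))
  for (g in seq_along(fraction_grid)) {
    n_con <- floor(fraction_grid[g] * set_size)
    for (r in seq_len(n_reps)) {
      genes <- c(sample(con, n_con), sample(uncon, set_size - n_con))
      draws[r, g] <- funburd_runner(genes)
    }
  }
  centiles <- do.call(rbind, lapply(seq_along(fraction_grid), function(g) {
    data.frame(fraction = fraction_grid[g], centile = 100 * probs,
               value = unname(stats::quantile(draws[, g], probs)))
  }))
  structure(list(draws = draws, centiles = centiles,
                 fraction_grid = fraction_grid, set_size = set_size,
                 n_reps = n_reps, seed = seed),
            class = "normative_bands")
}

#' @export
print.normative_bands <- function(x, ...) {
  cat("normative bands:", length(x$fraction_grid), "constraint fractions x",
      x$n_reps, "resampled sets of", x$set_size, "genes\n")
  med <- x$centiles$value[x$centiles$centile == 50]
  cat("  median pleiotropy by fraction:", paste(signif(med, 3), collapse = " "), "\n")
  invisible(x)
}

#' Constraint-normalized pleiotropy centile
#'
#' Expresses an observed gene set's pleiotropy as an empirical centile of the
#' normative null for its constrained fraction (nearest grid point; midrank
#' convention for ties). Sets outside the 5th-95th centile band are flagged
#' as outliers — more (or less) pleiotropic than expected from their genetic
#' constraint alone.
#'
#' @param observed Observed pleiotropy value.
#' @param fraction The set's constrained fraction; must lie within the bands'
#'   grid range (no extrapolation).
#' @param bands A `normative_bands` object.
#' @return List with `centile`, `outlier`, and the matched `grid_fraction`.
#' @export
normalized_pleiotropy <- function(observed, fraction, bands) {
  stopifnot(inherits(bands, "normative_bands"))
  rng <- range(bands$fraction_grid)
  half_step <- if (length(bands$fraction_grid) > 1)
    max(diff(sort(bands$fraction_grid))) / 2 else 0
  if (fraction < rng[1] - half_step || fraction > rng[2] + half_step)
    stop("constrained fraction ", fraction,
         " outside the normative grid range [", rng[1], ", ", rng[2],
         "]; extrapolation refused")
  g <- which.min(abs(bands$fraction_grid - fraction))
  null <- bands$draws[, g]
  centile <- 100 * (sum(null < observed) + 0.5 * sum(null == observed)) /
    length(null)
  list(centile = centile, outlier = centile < 5 || centile > 95,
       grid_fraction = bands$fraction_grid[g])
}

#' Rank-sum comparison of two groups
#'
#' Two-sided Wilcoxon rank-sum test, the package's standard comparison for
#' brain versus non-brain distributions of constrained fractions, centiles or
#' monotonic proportions.
#'
#' @param groupA,groupB Numeric vectors (non-empty).
#' @return Two-sided p-value.
#' @export
group_difference <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  suppressWarnings(stats::wilcox.test(groupA, groupB)$p.value)
}

#' Build a pleiotropy evaluator for arbitrary gene sets
#'
#' Precomputes the CNV-to-gene containment index and preprocessed traits once
#' and returns a closure that, given any gene set, aggregates its burden,
#' fits the FunBurd regression for every trait at one dosage type, applies
#' BH-FDR across those cells, and returns the number of significantly
#' associated traits. This is the engine behind [normative_model()].
#'
#' @param cnvs,genes As in [aggregate_burden()].
#' @param phenotypes,traits As in [funburd()].
#' @param dosage_type `"DEL"` or `"DUP"`.
#' @param q_threshold FDR threshold for counting associations.
#' @param x2_scope Burden x2 scope.
#' @return Function `(gene_ids) -> integer pleiotropy`.
#' @export
make_funburd_runner <- function(cnvs, genes, phenotypes, traits,
                                dosage_type = "DEL", q_threshold = 0.05,
                                x2_scope = "same_cnv") {
  samples <- sort(unique(as.character(phenotypes$sample_id)))
  ph <- phenotypes[match(samples, as.character(phenotypes$sample_id)), , drop = FALSE]
  pc_cols <- grep("^PC[0-9]+$", names(ph), value = TRUE)
  covars <- ph[, c("age", "sex", pc_cols), drop = FALSE]
  ys <- list()
  for (i in seq_len(nrow(traits))) {
    y <- ph[[traits$trait[i]]]
    if (traits$type[i] == "continuous") {
      keep <- outlier_filter(y)
      y[!keep] <- NA
      y <- irnt(y)
    }
    ys[[traits$trait[i]]] <- y
  }
  cnvs_t <- cnvs[cnvs$dosage_type == dosage_type, , drop = FALSE]
  function(gene_ids) {
    coll <- gene_set_collection(list(sampled = gene_ids),
                                universe = genes$gene_id)
    bt <- aggregate_burden(cnvs_t, genes, coll, x2_scope = x2_scope,
                           samples = samples)
    p <- vapply(seq_len(nrow(traits)), function(i) {
      fit_funburd(ys[[traits$trait[i]]],
                  bt$x1[[dosage_type]][, 1], bt$x2[[dosage_type]][, 1],
                  covars, traits$type[i])$p
    }, numeric(1))
    sum(fdr_correct(p) < q_threshold)
  }
}
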