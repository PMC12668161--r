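#' Overlap-aware permutation p-values (P-Jaccard)
#'
#' Gene sets defined from expression patterns partially overlap, so naive
#' permutation tests of per-set statistics are anti-conservative: overlapping
#' sets do not contribute independent information. The P-Jaccard scheme
#' conditions the null on the overlap structure by permuting the *gene-level*
#' attribute across the universe and propagating it through the unchanged set
#' memberships. Every null replicate therefore shares the exact Jaccard
#' matrix of the observed collection, and only the assignment of attribute
#' values to genes is randomized.
#'
#' Empirical p-values use the add-one estimator
#' `p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1)` (two-sided), which is
#' never smaller than `1 / (n_perm + 1)`.
#'
#' @name pjaccard
NULL

.new_permutation_null <- function(observed, null, p, n_perm, seed, statistic) {
  structure(list(observed = observed, null = null, p = p,
                 n_perm = n_perm, seed = seed, statistic = statistic),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation null (", x$statistic, ")\n", sep = "")
  cat(sprintf("  observed = %.4g; empirical p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

# Mean attribute value over each set's members (the default attribute-derived
# per-set statistic, e.g. the constrained fraction for a 0/1 attribute).
.set_attribute_stat <- function(collection, attribute) {
  vapply(collection$sets, function(g) mean(attribute[g]), numeric(1))
}

#' P-Jaccard test for a correlation between per-set statistics
#'
#' Tests the Pearson correlation between an attribute-derived per-set
#' statistic (e.g. the fraction of constrained genes per set) and a second,
#' fixed per-set statistic (e.g. functional pleiotropy). Null replicates
#' permute the gene-level attribute over the universe and recompute the
#' attribute-derived statistic through the fixed set memberships, preserving
#' the full Jaccard structure.
#'
#' @param set_stat_a Attribute-derived statistic per set, or `NULL` to compute
#'   it from `attribute` via `stat_fn`.
#' @param set_stat_b Fixed per-set statistic (same order as the collection's
#'   sets).
#' @param collection A [gene_set_collection()].
#' @param attribute Named vector (names = universe genes) of the gene-level
#'   attribute the null permutes.
#' @param n_perm Number of permutations (default 1000; below 100 a warning is
#'   issued).
#' @param seed Optional RNG seed for reproducibility.
#' @param stat_fn Function `(collection, attribute) -> per-set vector`;
#'   default is the mean attribute over set members.
#' @return A `permutation_null` object.
#' @export
pjaccard_correlation <- function(set_stat_a = NULL, set_stat_b, collection,
                                 attribute, n_perm = 1000, seed = NULL,
                                 stat_fn = .set_attribute_stat) {
  stopifnot(inherits(collection, "gene_set_collection"))
  attribute <- .check_attribute(attribute, collection)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(set_stat_a)) set_stat_a <- stat_fn(collection, attribute)
  stopifnot(length(set_stat_a) == length(collection$sets),
            length(set_stat_b) == length(collection$sets))
  if (stats::sd(set_stat_a) == 0 || stats::sd(set_stat_b) == 0)
    stop("correlation undefined: constant per-set statistic")
  observed <- stats::cor(set_stat_a, set_stat_b)
  null <- numeric(n_perm)
  vals <- unname(attribute)
  nm <- names(attribute)
  for (r in seq_len(n_perm)) {
    perm <- stats::setNames(vals[sample.int(length(vals))], nm)
    stat_a <- stat_fn(collection, perm)
    null[r] <- if (stats::sd(stat_a) == 0) 0 else stats::cor(stat_a, set_stat_b)
  }
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_perm + 1)
  .new_permutation_null(observed, null, p, n_perm, seed, "pearson_correlation")
}

#' P-Jaccard test for an arbitrary statistic
#'
#' Same permutation scheme as [pjaccard_correlation()] for any scalar
#' statistic of (collection, gene-level attribute).
#'
#' @param statistic_fn Function `(collection, attribute) -> scalar`.
#' @inheritParams pjaccard_correlation
#' @return A `permutation_null` object.
#' @export
pjaccard_generic <- function(statistic_fn, collection, attribute,
                             n_perm = 1000, seed = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"), is.function(statistic_fn))
  attribute <- .check_attribute(attribute, collection)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse empirical p-value")
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic_fn(collection, attribute)
  if (!is.finite(observed)) stop("statistic_fn returned a non-finite observed value")
  null <- numeric(n_perm)
  vals <- unname(attribute)
  nm <- names(attribute)
  for (r in seq_len(n_perm)) {
    perm <- stats::setNames(vals[sample.int(length(vals))], nm)
    null[r] <- tryCatch(statistic_fn(collection, perm), error = function(e)
      stop("statistic_fn failed on permutation replicate ", r, ": ",
           conditionMessage(e), call. = FALSE))
  }
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_perm + 1)
  .new_permutation_null(observed, null, p, n_perm, seed, "generic")
}

.check_attribute <- function(attribute, collection) {
  if (is.null(names(attribute)))
    stop("attribute must be named by gene identifier")
  missing <- setdiff(collection$universe, names(attribute))
  if (length(missing))
    stop("attribute undefined for ", length(missing), " universe genes")
  attribute[collection$universe]
}

# Gene-level scores induced by a per-set effect profile: each gene receives
# the mean coefficient of the sets containing it (0 when in none). Used to
# expose regression-derived profiles to the gene-permutation null.
.gene_scores_from_profile <- function(profile, collection) {
  stopifnot(length(profile) == length(collection$sets))
  num <- stats::setNames(numeric(length(collection$universe)), collection$universe)
  den <- num
  for (k in seq_along(collection$sets)) {
    g <- collection$sets[[k]]
    num[g] <- num[g] + profile[k]
    den[g] <- den[g] + 1
  }
  out <- num
  out[den > 0] <- num[den > 0] / den[den > 0]
  out
}
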