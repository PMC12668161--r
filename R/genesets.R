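#' Gene set collections
#'
#' A `gene_set_collection` bundles named gene sets, the gene universe they are
#' drawn from, and optional per-set annotations (brain / non-brain flag and the
#' level of the defining expression resource: tissue, body-cell or brain-cell).
#'
#' @param sets Named list of character vectors of gene identifiers. Names must
#'   be unique and every set non-empty.
#' @param universe Character vector of all gene identifiers. Defaults to the
#'   union of the sets.
#' @param annotations Optional data frame with columns `name`, `brain`
#'   (logical) and `level`; one row per set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, annotations = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a named list with unique names")
  if (any(lengths(sets) == 0L))
    stop("empty gene sets are not allowed: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("duplicate gene identifiers in universe")
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside))
    stop("set members outside the universe: ", paste(utils::head(outside, 5), collapse = ", "))
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations), all(c("name", "brain") %in% names(annotations)))
    missing_ann <- setdiff(names(sets), annotations$name)
    if (length(missing_ann))
      stop("annotations missing for sets: ", paste(missing_ann, collapse = ", "))
  }
  structure(list(sets = sets, universe = universe, annotations = annotations),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over",
      length(x$universe), "genes\n")
  sz <- lengths(x$sets)
  cat("  set sizes: min", min(sz), "median", stats::median(sz), "max", max(sz), "\n")
  if (!is.null(x$annotations))
    cat("  brain sets:", sum(x$annotations$brain), "/", nrow(x$annotations), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Expression proportion per gene and context
#'
#' Divides each gene's expression in a tissue or cell type by its total
#' expression across contexts, giving the share of the gene's output attributed
#' to each context. Genes with zero total expression have undefined proportions
#' and are returned as `NaN` rows; downstream set construction excludes them.
#'
#' @param expr Numeric matrix (genes x contexts) of non-negative expression
#'   values (nTPM-like), with unique row and column names.
#' @return Matrix of the same shape; rows with positive totals sum to 1.
#' @export
expression_proportion <- function(expr) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene row names and context column names")
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
    stop("duplicate gene or context identifiers")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("expression values must be finite and non-negative")
  tot <- rowSums(expr)
  prop <- expr / tot # zero-total rows become NaN
  prop
}

#' Build TDEP gene sets from an expression-proportion matrix
#'
#' For each context, selects the top decile of genes by expression proportion
#' (Top Decile Expression Proportion). Genes with undefined proportions (zero
#' total expression) are removed from the eligible universe before the decile
#' is taken. Set size is `ceiling(decile * n_eligible)`; ties at the boundary
#' are broken by proportion (descending) then gene identifier (ascending), so
#' construction is deterministic.
#'
#' @param prop Proportion matrix from [expression_proportion()].
#' @param decile Fraction of eligible genes per set, in (0, 1]. Default 0.10.
#' @param annotations Optional per-set annotation data frame (see
#'   [gene_set_collection()]); contexts inherit rows by name.
#' @return A [gene_set_collection()] whose universe is the eligible genes.
#' @export
build_tdep_sets <- function(prop, decile = 0.10, annotations = NULL) {
  if (!is.numeric(decile) || length(decile) != 1L || decile <= 0 || decile > 1)
    stop("'decile' must be a single value in (0, 1]")
  eligible <- rowSums(is.finite(prop)) == ncol(prop)
  prop <- prop[eligible, , drop = FALSE]
  n_eligible <- nrow(prop)
  if (n_eligible == 0L) stop("no eligible genes (all totals zero)")
  k <- ceiling(decile * n_eligible)
  ids <- rownames(prop)
  sets <- lapply(colnames(prop), function(ctx) {
    o <- order(-prop[, ctx], ids)
    ids[o[seq_len(k)]]
  })
  names(sets) <- colnames(prop)
  gene_set_collection(sets, universe = ids, annotations = annotations)
}

#' Pairwise Jaccard similarity of gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; the corresponding distance is
#' `1 - J`. The matrix is symmetric with unit diagonal.
#'
#' @param collection A [gene_set_collection()] with at least two sets.
#' @return Numeric similarity matrix, sets x sets.
#' @export
jaccard_matrix <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- collection$sets
  if (length(sets) < 2L) stop("need at least two sets")
  # binary membership matrix gives all pairwise intersections in one product
  m <- vapply(sets, function(g) collection$universe %in% g,
              logical(length(collection$universe)))
  inter <- crossprod(m)
  sz <- lengths(sets)
  uni <- outer(sz, sz, "+") - inter
  j <- inter / uni
  dimnames(j) <- list(names(sets), names(sets))
  j
}

#' Mean pairwise overlap of a collection
#'
#' Mean of the off-diagonal Jaccard similarities, the summary used to describe
#' how redundant a family of expression-defined gene sets is.
#'
#' @inheritParams jaccard_matrix
#' @return A single fraction in `[0, 1]`.
#' @export
mean_overlap <- function(collection) {
  j <- jaccard_matrix(collection)
  mean(j[upper.tri(j)])
}
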