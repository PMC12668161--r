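#' Classify gene dosage responses
#'
#' Pairs each (gene set, trait)'s deletion and duplication associations and
#' classifies the dosage response. A response is `null` when neither dosage
#' type is FDR-significant; otherwise its sign class is `monotonic` when the
#' deletion and duplication effects oppose each other (`del_beta * dup_beta
#' < 0`, the signature of a dose-responsive trait) and `non-monotonic`
#' otherwise. The evidence class distinguishes responses significant for
#' both types (`truly_monotonic` / `truly_non_monotonic`) from those
#' significant for one type only (`undetermined_del` / `undetermined_dup`).
#'
#' @param object A `funburd` fit or its `results` data frame (must contain
#'   both dosage types for every set x trait pair).
#' @param q_threshold FDR threshold (default 0.05).
#' @return Data frame of class `dosage_responses` with one row per (set,
#'   trait): `del_beta`, `del_q`, `dup_beta`, `dup_q`, `sign_class`,
#'   `evidence_class`.
#' @export
classify_responses <- function(object, q_threshold = 0.05) {
  res <- if (inherits(object, "funburd")) object$results else object
  del <- res[res$dosage_type == "DEL", ]
  dup <- res[res$dosage_type == "DUP", ]
  key <- function(d) paste(d$gene_set, d$trait, sep = "\r")
  if (nrow(del) != nrow(dup) || !setequal(key(del), key(dup)))
    stop("grid must be rectangular: every (set, trait) needs both DEL and DUP cells")
  dup <- dup[match(key(del), key(dup)), ]
  del_sig <- del$q < q_threshold
  dup_sig <- dup$q < q_threshold
  sign_class <- ifelse(del$beta * dup$beta < 0, "monotonic", "non-monotonic")
  evidence <- rep("null", nrow(del))
  evidence[del_sig & dup_sig & sign_class == "monotonic"] <- "truly_monotonic"
  evidence[del_sig & dup_sig & sign_class == "non-monotonic"] <- "truly_non_monotonic"
  evidence[del_sig & !dup_sig] <- "undetermined_del"
  evidence[!del_sig & dup_sig] <- "undetermined_dup"
  sign_class[evidence == "null"] <- NA_character_
  out <- data.frame(gene_set = del$gene_set, trait = del$trait,
                    del_beta = del$beta, del_q = del$q,
                    dup_beta = dup$beta, dup_q = dup$q,
                    sign_class = sign_class, evidence_class = evidence,
                    stringsAsFactors = FALSE)
  class(out) <- c("dosage_responses", "data.frame")
  attr(out, "q_threshold") <- q_threshold
  out
}

#' @export
summary.dosage_responses <- function(object, ...) {
  non_null <- object[object$evidence_class != "null", ]
  sign_tab <- table(factor(non_null$sign_class,
                           levels = c("monotonic", "non-monotonic")))
  ev_tab <- table(factor(object$evidence_class,
                         levels = c("null", "truly_monotonic", "truly_non_monotonic",
                                    "undetermined_del", "undetermined_dup")))
  out <- list(n_responses = nrow(object), n_non_null = nrow(non_null),
              sign_counts = sign_tab,
              sign_pct = 100 * prop.table(sign_tab),
              evidence_counts = ev_tab)
  class(out) <- "summary.dosage_responses"
  out
}

#' @export
print.summary.dosage_responses <- function(x, ...) {
  cat("gene dosage responses:", x$n_responses, "set-trait pairs;",
      x$n_non_null, "with an FDR-significant association\n")
  cat(sprintf("  monotonic %.1f%% / non-monotonic %.1f%% of non-null responses\n",
              x$sign_pct[["monotonic"]], x$sign_pct[["non-monotonic"]]))
  print(x$evidence_counts)
  invisible(x)
}

#' Deletion-duplication effect-size correlation for one trait
#'
#' Pearson correlation between a trait's deletion and duplication effect-size
#' profiles across gene sets, with an overlap-aware P-Jaccard p-value (the
#' duplication profile is mapped to gene-level scores, permuted over the
#' universe, and re-aggregated through the fixed memberships).
#'
#' @param object A `funburd` fit.
#' @param trait Trait name.
#' @param collection The [gene_set_collection()] behind the grid.
#' @param n_perm Permutations (default 1000).
#' @param seed RNG seed.
#' @return List with `r` and `p` plus the `permutation_null`.
#' @export
deldup_effect_correlation <- function(object, trait, collection,
                                      n_perm = 1000, seed = NULL) {
  res <- object$results[object$results$trait == trait, ]
  del <- res$beta[res$dosage_type == "DEL"][match(object$sets,
                                                  res$gene_set[res$dosage_type == "DEL"])]
  dup <- res$beta[res$dosage_type == "DUP"][match(object$sets,
                                                  res$gene_set[res$dosage_type == "DUP"])]
  if (stats::sd(del) == 0 || stats::sd(dup) == 0)
    stop("constant effect-size profile for trait ", trait)
  scores <- .gene_scores_from_profile(dup, collection)
  stat_fn <- function(coll, attribute)
    stats::cor(del, .set_attribute_stat(coll, attribute))
  pn <- pjaccard_generic(stat_fn, collection, scores, n_perm = n_perm, seed = seed)
  list(r = stats::cor(del, dup), p = pn$p, null = pn)
}

#' Deletion-duplication effect correlations across all traits
#'
#' Applies [deldup_effect_correlation()] to every trait and corrects the
#' p-values by BH-FDR across traits.
#'
#' @inheritParams deldup_effect_correlation
#' @return Data frame with `trait`, `r`, `p`, `q`.
#' @export
deldup_effect_correlations <- function(object, collection, n_perm = 1000,
                                       seed = NULL) {
  traits <- object$traits$trait
  out <- data.frame(trait = traits, r = NA_real_, p = NA_real_)
  for (i in seq_along(traits)) {
    cc <- deldup_effect_correlation(object, traits[i], collection,
                                    n_perm = n_perm,
                                    seed = if (is.null(seed)) NULL else seed + i)
    out$r[i] <- cc$r
    out$p[i] <- cc$p
  }
  out$q <- fdr_correct(out$p)
  out
}

#' Monotonic response fraction per trait and group comparison
#'
#' For each trait, the share of monotonic responses among its non-null
#' dosage responses; traits with no non-null responses are excluded with a
#' warning. When `trait_groups` is given (named vector, e.g. brain /
#' non-brain), group distributions are compared by Wilcoxon rank-sum.
#'
#' @param responses A `dosage_responses` table ([classify_responses()]).
#' @param trait_groups Optional named character vector mapping trait to
#'   group.
#' @return List with `per_trait` (trait, n_non_null, monotonic_fraction,
#'   group) and, when two groups are present, `group_p`.
#' @export
monotonic_fraction_by_group <- function(responses, trait_groups = NULL) {
  non_null <- responses[responses$evidence_class != "null", ]
  traits <- unique(responses$trait)
  frac <- vapply(traits, function(tr) {
    sub <- non_null[non_null$trait == tr, ]
    if (!nrow(sub)) return(NA_real_)
    mean(sub$sign_class == "monotonic")
  }, numeric(1))
  if (anyNA(frac)) {
    warning("traits with no non-null responses excluded: ",
            paste(traits[is.na(frac)], collapse = ", "))
  }
  per_trait <- data.frame(trait = traits,
                          n_non_null = vapply(traits, function(tr)
                            sum(non_null$trait == tr), integer(1)),
                          monotonic_fraction = frac,
                          stringsAsFactors = FALSE)
  per_trait <- per_trait[!is.na(per_trait$monotonic_fraction), ]
  out <- list(per_trait = per_trait)
  if (!is.null(trait_groups)) {
    per_trait$group <- trait_groups[per_trait$trait]
    out$per_trait <- per_trait
    gr <- unique(per_trait$group)
    if (length(gr) == 2)
      out$group_p <- group_difference(
        per_trait$monotonic_fraction[per_trait$group == gr[1]],
        per_trait$monotonic_fraction[per_trait$group == gr[2]])
  }
  out
}

#' Functional overlap test between variant classes
#'
#' Tests whether the gene sets significant for CNV burden overlap the sets
#' enriched in a fixed external reference (e.g. common-variant enrichments)
#' more than chance. Observed overlap = `|intersection| /
#' |cnv_significant_sets|`. Null replicates redraw the CNV side uniformly
#' without replacement from the universe of sets, keeping the reference side
#' fixed; the p-value is one-sided for greater-than-chance overlap.
#'
#' @param cnv_significant_sets Character vector of CNV-associated set names
#'   (non-empty).
#' @param reference_enriched_sets Character vector of reference-enriched set
#'   names.
#' @param universe_sets All candidate set names.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return A `permutation_null` with the observed overlap proportion.
#' @export
functional_overlap_test <- function(cnv_significant_sets,
                                    reference_enriched_sets, universe_sets,
                                    n_perm = 1000, seed = NULL) {
  if (!length(cnv_significant_sets)) stop("no CNV-significant sets: overlap undefined")
  stopifnot(all(cnv_significant_sets %in% universe_sets),
            all(reference_enriched_sets %in% universe_sets))
  if (!is.null(seed)) set.seed(seed)
  k <- length(cnv_significant_sets)
  observed <- length(intersect(cnv_significant_sets, reference_enriched_sets)) / k
  null <- vapply(seq_len(n_perm), function(r) {
    draw <- sample(universe_sets, k)
    length(intersect(draw, reference_enriched_sets)) / k
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  .new_permutation_null(observed, null, p, n_perm, seed, "overlap_proportion")
}
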