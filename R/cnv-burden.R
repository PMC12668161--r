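#' Genes fully encompassed by a CNV
#'
#' A gene contributes to CNV burden only when the CNV covers it completely:
#' same chromosome, `gene start >= cnv start` and `gene end <= cnv end`.
#' Coordinates are 1-based inclusive on both sides.
#'
#' @param cnv A single-row data frame (or list) with `chrom`, `start`, `end`.
#' @param genes Data frame of gene models with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @return Character vector of fully encompassed gene identifiers.
#' @export
genes_fully_encompassed <- function(cnv, genes) {
  .validate_intervals(genes)
  if (cnv$start < 1 || cnv$end < cnv$start)
    stop("invalid CNV coordinates (must be 1-based inclusive, start <= end)")
  hit <- genes$chrom == cnv$chrom & genes$start >= cnv$start & genes$end <= cnv$end
  genes$gene_id[hit]
}

.validate_intervals <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("invalid gene coordinates (must be 1-based inclusive, start <= end)")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene models")
  invisible(TRUE)
}

# Map each CNV to the indices of genes it fully encompasses.
# Containment search is delegated to GenomicRanges (type = "within").
.cnv_gene_index <- function(cnvs, genes) {
  .validate_intervals(genes)
  if (nrow(cnvs) == 0L) return(list())
  if (any(cnvs$start < 1) || any(cnvs$end < cnvs$start))
    stop("invalid CNV coordinates (must be 1-based inclusive, start <= end)")
  bad <- setdiff(unique(cnvs$dosage_type), c("DEL", "DUP"))
  if (length(bad)) stop("unknown dosage type: ", paste(bad, collapse = ", "))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
  gr_cnvs <- GenomicRanges::GRanges(cnvs$chrom,
                                    IRanges::IRanges(cnvs$start, cnvs$end))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_cnvs, type = "within")
  out <- vector("list", nrow(cnvs))
  out[] <- list(integer(0))
  if (length(ov)) {
    sp <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    out[as.integer(names(sp))] <- unname(sp)
  }
  out
}

#' Aggregate per-sample gene-set CNV burden
#'
#' For every (sample, gene set, dosage type) cell, computes the two burden
#' predictors of the functional burden regression: `x1`, the number of distinct
#' set-member genes fully encompassed by that sample's CNVs of that type, and
#' `x2`, the number of distinct non-member genes encompassed alongside. Under
#' `x2_scope = "same_cnv"` (default) only CNVs that hit at least one set member
#' contribute to `x2` — the adjustment for multigenic CNVs; under `"all_cnvs"`
#' every CNV of the type contributes. Deletions and duplications are never
#' pooled, and a gene hit by two same-type CNVs counts once.
#'
#' @param cnvs Data frame with `sample_id`, `chrom`, `start`, `end`,
#'   `dosage_type` (`"DEL"` or `"DUP"`).
#' @param genes Gene model data frame (`gene_id`, `chrom`, `start`, `end`),
#'   1-based inclusive coordinates.
#' @param collection A [gene_set_collection()]. Set members absent from the
#'   gene models are dropped with a warning.
#' @param x2_scope `"same_cnv"` or `"all_cnvs"`.
#' @param samples Optional character vector of all cohort sample identifiers
#'   (so non-carriers get zero rows); defaults to the samples present in
#'   `cnvs`.
#' @return A `burden_table`: matrices `x1[[type]]` and `x2[[type]]`
#'   (samples x sets) plus metadata. Convert to the long format with
#'   [as.data.frame()].
#' @export
aggregate_burden <- function(cnvs, genes, collection,
                             x2_scope = c("same_cnv", "all_cnvs"),
                             samples = NULL) {
  x2_scope <- match.arg(x2_scope)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(samples)) samples <- sort(unique(as.character(cnvs$sample_id)))
  samples <- as.character(samples)
  set_names <- names(collection$sets)
  hit_idx <- .cnv_gene_index(cnvs, genes)

  member_idx <- lapply(collection$sets, function(g) {
    unknown <- setdiff(g, genes$gene_id)
    if (length(unknown))
      warning("ignoring set members without gene models: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    match(intersect(g, genes$gene_id), genes$gene_id)
  })

  empty <- matrix(0L, length(samples), length(set_names),
                  dimnames = list(samples, set_names))
  x1 <- list(DEL = empty, DUP = empty)
  x2 <- list(DEL = empty, DUP = empty)

  if (nrow(cnvs) > 0L) {
    samp <- as.character(cnvs$sample_id)
    for (type in c("DEL", "DUP")) {
      rows <- which(cnvs$dosage_type == type & samp %in% samples)
      if (!length(rows)) next
      by_sample <- split(rows, samp[rows])
      for (sid in names(by_sample)) {
        gene_lists <- hit_idx[by_sample[[sid]]]
        all_genes <- unique(unlist(gene_lists, use.names = FALSE))
        if (!length(all_genes)) next
        for (k in seq_along(set_names)) {
          mem <- member_idx[[k]]
          in_set <- all_genes[all_genes %in% mem]
          x1[[type]][sid, k] <- length(in_set)
          if (x2_scope == "all_cnvs") {
            x2[[type]][sid, k] <- length(all_genes) - length(in_set)
          } else {
            contrib <- gene_lists[vapply(gene_lists,
                                         function(g) any(g %in% mem), logical(1))]
            cg <- unique(unlist(contrib, use.names = FALSE))
            x2[[type]][sid, k] <- sum(!cg %in% mem)
          }
        }
      }
    }
  }
  structure(list(x1 = x1, x2 = x2, samples = samples, sets = set_names,
                 x2_scope = x2_scope),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  cat("burden_table:", length(x$samples), "samples x", length(x$sets),
      "gene sets x 2 dosage types (x2_scope =", paste0(x$x2_scope, ")\n"))
  cat("  carriers (x1 > 0): DEL", sum(rowSums(x$x1$DEL) > 0),
      " DUP", sum(rowSums(x$x1$DUP) > 0), "\n")
  invisible(x)
}

#' @export
as.data.frame.burden_table <- function(x, ...) {
  out <- do.call(rbind, lapply(c("DEL", "DUP"), function(type) {
    data.frame(sample_id = rep(x$samples, times = length(x$sets)),
               gene_set = rep(x$sets, each = length(x$samples)),
               dosage_type = type,
               x1 = as.vector(x$x1[[type]]),
               x2 = as.vector(x$x2[[type]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
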