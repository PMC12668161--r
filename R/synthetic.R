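#' Configuration for a synthetic CNV cohort
#'
#' Defines a fully specified synthetic study — genome, context-specific
#' expression, sparse multigenic CNVs, covariates and traits generated from
#' planted gene-set burden effects — so every stage of the functional burden
#' pipeline can be tested against known ground truth.
#'
#' Traits follow the generative mirror of the burden regression: a continuous
#' trait is `sum(planted beta * x1) + x2_beta * (total genes disrupted) +
#' covariate effects + N(0, noise_sd^2)`; a binary trait thresholds the
#' standardized continuous construction at `qnorm(1 - prevalence)`. Trait
#' pairs with a planned burden correlation draw their per-set effect vectors
#' from a bivariate normal with the requested correlation.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes (laid out disjointly across chromosomes).
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_contexts Number of tissues / cell types.
#' @param marker_genes_per_context Planted marker genes per context.
#' @param cnv_rate Mean CNVs per sample per dosage type (Poisson).
#' @param cnv_gene_span_mean Mean genes per CNV; genes per CNV follow
#'   `1 + Poisson(cnv_gene_span_mean - 1)`.
#' @param planted_effects Data frame (`gene_set`, `trait`, `dosage_type`,
#'   `beta`) of planted burden effects; set names are contexts
#'   (`"context_01"`, ...). `NULL` for the default scenario.
#' @param trait_specs Data frame (`trait`, `type`, `prevalence`, `category`);
#'   `NULL` for the default four-trait panel.
#' @param rg_specs Optional data frame (`trait1`, `trait2`, `rho`,
#'   `beta_sd`): per-context effect pairs for these traits are drawn from a
#'   bivariate normal with correlation `rho`, planting a known burden
#'   correlation.
#' @param constraint_fraction Proportion of genes labeled top-decile
#'   constrained. Markers of contexts carrying planted effects are labeled
#'   first (constraint correlates with effect size), then random genes fill
#'   the quota.
#' @param x2_beta Effect per disrupted gene outside the planted sets.
#' @param covariate_betas Named vector `c(age=, sex=, pc=)` of covariate
#'   effects on the continuous construction.
#' @param noise_sd Residual SD of continuous traits.
#' @param seed RNG seed; one global stream consumed in documented order
#'   (markers, expression, constraint fill, CNVs, covariates, rg effect
#'   vectors, noise).
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 2000, n_genes = 1200, n_chroms = 4,
                         chrom_length = 5e7, n_contexts = 8,
                         marker_genes_per_context = 40,
                         cnv_rate = 0.2, cnv_gene_span_mean = 3,
                         planted_effects = NULL, trait_specs = NULL,
                         rg_specs = NULL, constraint_fraction = 0.10,
                         x2_beta = 0.05,
                         covariate_betas = c(age = 0.01, sex = 0.1, pc = 0.05),
                         noise_sd = 1, seed = 1) {
  if (is.null(trait_specs)) {
    trait_specs <- data.frame(
      trait = c("cognition", "height", "anxiety", "diabetes"),
      type = c("continuous", "continuous", "binary", "binary"),
      prevalence = c(NA, NA, 0.2, 0.1),
      category = c("brain", "non-brain", "brain", "non-brain"),
      stringsAsFactors = FALSE)
  }
  if (is.null(planted_effects) && is.null(rg_specs)) {
    planted_effects <- data.frame(
      gene_set = c("context_01", "context_01", "context_02", "context_02", "context_03"),
      trait = c("cognition", "anxiety", "height", "height", "cognition"),
      dosage_type = c("DEL", "DEL", "DEL", "DUP", "DUP"),
      beta = c(-0.5, 0.8, 0.4, -0.4, 0.45),
      stringsAsFactors = FALSE)
    # small configurations keep only the contexts and traits they define
    planted_effects <- planted_effects[
      planted_effects$gene_set %in% sprintf("context_%02d", seq_len(n_contexts)) &
        planted_effects$trait %in% trait_specs$trait, , drop = FALSE]
  }
  if (is.null(planted_effects))
    planted_effects <- data.frame(gene_set = character(), trait = character(),
                                  dosage_type = character(), beta = numeric())
  cfg <- list(n_samples = n_samples, n_genes = n_genes, n_chroms = n_chroms,
              chrom_length = chrom_length, n_contexts = n_contexts,
              marker_genes_per_context = marker_genes_per_context,
              cnv_rate = cnv_rate, cnv_gene_span_mean = cnv_gene_span_mean,
              planted_effects = planted_effects, trait_specs = trait_specs,
              rg_specs = rg_specs, constraint_fraction = constraint_fraction,
              x2_beta = x2_beta, covariate_betas = covariate_betas,
              noise_sd = noise_sd, seed = seed)
  .validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

.validate_synth_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_samples > 0, n_genes >= 0, n_chroms > 0, chrom_length > 0,
              n_contexts > 0, marker_genes_per_context >= 0,
              cnv_rate >= 0, cnv_gene_span_mean >= 1, noise_sd > 0,
              constraint_fraction >= 0, constraint_fraction <= 1)
    if (marker_genes_per_context * n_contexts > n_genes)
      stop("marker_genes_per_context * n_contexts exceeds n_genes")
    bin <- trait_specs$type == "binary"
    if (any(bin) && (anyNA(trait_specs$prevalence[bin]) ||
                     any(trait_specs$prevalence[bin] <= 0) ||
                     any(trait_specs$prevalence[bin] >= 1)))
      stop("binary traits need prevalence in (0, 1)")
    if (nrow(planted_effects)) {
      if (!all(planted_effects$trait %in% trait_specs$trait))
        stop("planted effect on unknown trait: ",
             paste(setdiff(planted_effects$trait, trait_specs$trait), collapse = ", "))
      ctx <- sprintf("context_%02d", seq_len(n_contexts))
      if (!all(planted_effects$gene_set %in% ctx))
        stop("planted effect on unknown gene set: ",
             paste(setdiff(planted_effects$gene_set, ctx), collapse = ", "))
      if (!all(planted_effects$dosage_type %in% c("DEL", "DUP")))
        stop("planted effect with unknown dosage type")
    }
  })
  invisible(cfg)
}

#' Synthetic gene models
#'
#' Lays `n_genes` non-overlapping genes left-to-right across the chromosomes:
#' equal gene lengths and equal gaps, so each CNV can be placed to encompass
#' an exact run of genes. Deterministic given the configuration.
#'
#' @param config A [synth_config()].
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (1-based inclusive),
#'   sorted by chromosome and start.
#' @export
generate_gene_models <- function(config) {
  n <- config$n_genes
  if (n == 0L) return(data.frame(gene_id = character(), chrom = character(),
                                 start = integer(), end = integer()))
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  slot <- floor(config$chrom_length / max(per_chrom, 1))
  gene_len <- floor(slot / 2)
  if (gene_len < 1)
    stop("chrom_length too small to place ", max(per_chrom), " genes per chromosome")
  rows <- vector("list", config$n_chroms)
  idx0 <- 0L
  for (c in seq_len(config$n_chroms)) {
    k <- per_chrom[c]
    if (k == 0L) next
    start <- (seq_len(k) - 1L) * slot + floor(slot / 4) + 1L
    rows[[c]] <- data.frame(
      gene_id = sprintf("gene_%05d", idx0 + seq_len(k)),
      chrom = sprintf("chr%d", c),
      start = start, end = start + gene_len - 1L,
      stringsAsFactors = FALSE)
    idx0 <- idx0 + k
  }
  do.call(rbind, rows)
}

#' Synthetic expression matrix with planted marker genes
#'
#' Marker genes express almost exclusively (> 90% of their total) in their
#' assigned context; background genes are near-uniform across contexts. A
#' TDEP construction on this matrix therefore recovers the planted markers
#' inside their context's set.
#'
#' @param config A [synth_config()].
#' @param marker_assignment Named character vector gene -> context (markers
#'   only).
#' @return Non-negative matrix genes x contexts.
#' @export
generate_expression <- function(config, marker_assignment) {
  ctx <- sprintf("context_%02d", seq_len(config$n_contexts))
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  nc <- config$n_contexts
  # background: each context Unif(5, 15) -> proportions near 1/nc
  expr <- matrix(stats::runif(config$n_genes * nc, 5, 15), config$n_genes, nc,
                 dimnames = list(genes, ctx))
  if (length(marker_assignment)) {
    off_max <- if (nc > 1) 8 / (nc - 1) else 0
    for (g in names(marker_assignment)) {
      expr[g, ] <- if (nc > 1) stats::runif(nc, 0, off_max) else 0
      expr[g, marker_assignment[g]] <- stats::runif(1, 90, 110)
    }
  }
  expr
}

#' Synthetic CNV calls
#'
#' Per sample and dosage type, the CNV count is Poisson(`cnv_rate`); each CNV
#' starts at a uniformly chosen gene and fully encompasses a contiguous run
#' of `1 + Poisson(cnv_gene_span_mean - 1)` genes (truncated at the
#' chromosome end), with breakpoints placed in the intergenic gaps so exactly
#' that run is encompassed.
#'
#' @param config A [synth_config()].
#' @param genes Gene models from [generate_gene_models()].
#' @return Data frame `sample_id`, `chrom`, `start`, `end`, `dosage_type`.
#' @export
generate_cnvs <- function(config, genes) {
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      dosage_type = character(), stringsAsFactors = FALSE)
  if (config$cnv_rate == 0 || nrow(genes) == 0L) return(empty)
  margin <- max(1L, floor((genes$start[1] - 1) / 2))
  out <- list()
  sample_ids <- sprintf("S%05d", seq_len(config$n_samples))
  for (type in c("DEL", "DUP")) {
    counts <- stats::rpois(config$n_samples, config$cnv_rate)
    total <- sum(counts)
    if (total == 0L) next
    first <- sample.int(nrow(genes), total, replace = TRUE)
    span <- 1L + stats::rpois(total, config$cnv_gene_span_mean - 1)
    last <- pmin(first + span - 1L, nrow(genes))
    # truncate runs at chromosome boundaries
    same_chrom <- genes$chrom[first]
    for (i in seq_len(total)) {
      idx <- first[i]:last[i]
      idx <- idx[genes$chrom[idx] == same_chrom[i]]
      last[i] <- idx[length(idx)]
    }
    out[[type]] <- data.frame(
      sample_id = rep(sample_ids, counts),
      chrom = same_chrom,
      start = pmax(1L, genes$start[first] - margin),
      end = genes$end[last] + margin,
      dosage_type = type, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic traits from planted burden effects
#'
#' Builds the continuous construction `sum(beta * x1) + x2_beta * (total
#' disrupted genes) + covariate effects + N(0, noise_sd^2)` per trait, and
#' thresholds its standardized value at `qnorm(1 - K)` for binary traits.
#'
#' @param config A [synth_config()].
#' @param planted Planted effects data frame (possibly augmented with
#'   rg-drawn effects).
#' @param burden `burden_table` over the true (marker) gene sets.
#' @param covariates Data frame `sample_id`, `age`, `sex`, `PC1`...`PC10`.
#' @param total_disrupted Per-sample total distinct genes disrupted (both
#'   dosage types).
#' @return Data frame of trait columns aligned with `covariates`.
#' @export
generate_traits <- function(config, planted, burden, covariates,
                            total_disrupted) {
  n <- nrow(covariates)
  cb <- config$covariate_betas
  pc_cols <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
  cov_part <- cb[["age"]] * (covariates$age - mean(covariates$age)) +
    cb[["sex"]] * covariates$sex +
    rowSums(as.matrix(covariates[, pc_cols]) * cb[["pc"]])
  out <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(config$trait_specs))) {
    tr <- config$trait_specs$trait[i]
    y <- cov_part + config$x2_beta * total_disrupted +
      stats::rnorm(n, 0, config$noise_sd)
    pe <- planted[planted$trait == tr, , drop = FALSE]
    for (r in seq_len(nrow(pe)))
      y <- y + pe$beta[r] * burden$x1[[pe$dosage_type[r]]][, pe$gene_set[r]]
    if (config$trait_specs$type[i] == "binary") {
      K <- config$trait_specs$prevalence[i]
      liab <- (y - mean(y)) / stats::sd(y)
      y <- as.integer(liab > stats::qnorm(1 - K))
    }
    out[[tr]] <- y
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Runs the whole generator under one RNG stream: gene models, marker
#' assignment, expression, constraint labels, CNVs, covariates, rg-planted
#' effect vectors, and traits. The burden table used to build the traits
#' (over the true marker sets) is included so downstream recovery can be
#' checked against an exact ground truth.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_cohort`: `config`, `genes`, `expression`,
#'   `cnvs`, `phenotypes` (covariates + traits), `traits` (metadata),
#'   `burden_true`, and `truth` (`marker_sets`, `marker_assignment`,
#'   `planted_effects`, `constraint_labels`, `rg_specs`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  genes <- generate_gene_models(config)
  ctx <- sprintf("context_%02d", seq_len(config$n_contexts))

  # 1. marker assignment
  n_mark <- config$marker_genes_per_context * config$n_contexts
  marker_genes <- sample(genes$gene_id, n_mark)
  marker_assignment <- stats::setNames(rep(ctx, each = config$marker_genes_per_context),
                                       marker_genes)
  marker_sets <- split(names(marker_assignment), marker_assignment)[ctx]

  # 2. expression
  expression <- generate_expression(config, marker_assignment)

  # 3. constraint labels: effect-carrying contexts' markers first, random fill
  effect_ctx <- unique(config$planted_effects$gene_set)
  if (!is.null(config$rg_specs)) effect_ctx <- ctx # rg effects span all contexts
  constrained <- unlist(marker_sets[intersect(ctx, effect_ctx)], use.names = FALSE)
  quota <- round(config$constraint_fraction * config$n_genes)
  if (length(constrained) < quota) {
    pool <- setdiff(genes$gene_id, constrained)
    constrained <- c(constrained, sample(pool, quota - length(constrained)))
  }
  constraint_labels <- stats::setNames(genes$gene_id %in% constrained, genes$gene_id)

  # 4. CNVs
  cnvs <- generate_cnvs(config, genes)

  # 5. covariates
  sample_ids <- sprintf("S%05d", seq_len(config$n_samples))
  covariates <- data.frame(sample_id = sample_ids,
                           age = stats::runif(config$n_samples, 40, 70),
                           sex = stats::rbinom(config$n_samples, 1, 0.5))
  for (k in 1:10) covariates[[paste0("PC", k)]] <- stats::rnorm(config$n_samples)

  # 6. rg-planted effect vectors (bivariate normal across contexts)
  planted <- config$planted_effects
  if (!is.null(config$rg_specs)) {
    for (r in seq_len(nrow(config$rg_specs))) {
      rs <- config$rg_specs[r, ]
      z <- matrix(stats::rnorm(2 * config$n_contexts), ncol = 2)
      L <- chol(matrix(c(1, rs$rho, rs$rho, 1), 2))
      b <- z %*% L * rs$beta_sd
      planted <- rbind(planted,
                       data.frame(gene_set = rep(ctx, 2),
                                  trait = rep(c(rs$trait1, rs$trait2),
                                              each = config$n_contexts),
                                  dosage_type = "DEL",
                                  beta = c(b[, 1], b[, 2])))
    }
  }

  # 7. burden over the true marker sets, then traits
  truth_coll <- gene_set_collection(marker_sets, universe = genes$gene_id)
  burden_true <- aggregate_burden(cnvs, genes, truth_coll, samples = sample_ids)
  hit_idx <- .cnv_gene_index(cnvs, genes)
  total_disrupted <- stats::setNames(numeric(config$n_samples), sample_ids)
  if (nrow(cnvs)) {
    per_sample <- vapply(split(hit_idx, as.character(cnvs$sample_id)),
                         function(l) length(unique(unlist(l, use.names = FALSE))),
                         numeric(1))
    total_disrupted[names(per_sample)] <- per_sample
  }
  trait_cols <- generate_traits(config, planted, burden_true, covariates,
                                unname(total_disrupted))
  phenotypes <- cbind(covariates, trait_cols)

  structure(list(config = config, genes = genes, expression = expression,
                 cnvs = cnvs, phenotypes = phenotypes,
                 traits = config$trait_specs, burden_true = burden_true,
                 truth = list(marker_sets = marker_sets,
                              marker_assignment = marker_assignment,
                              planted_effects = planted,
                              constraint_labels = constraint_labels,
                              rg_specs = config$rg_specs)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("synthetic cohort:", x$config$n_samples, "samples,",
      x$config$n_genes, "genes,", nrow(x$cnvs), "CNVs,",
      nrow(x$traits), "traits\n")
  cat("  planted effects:", nrow(x$truth$planted_effects),
      " constrained genes:", sum(x$truth$constraint_labels), "\n")
  invisible(x)
}
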