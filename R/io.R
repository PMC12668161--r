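#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line with
#' name, description, then member genes.
#'
#' @param path File path.
#' @param universe Optional universe passed to [gene_set_collection()].
#' @param annotations Optional annotation data frame.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL, annotations = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate set name in GMT: ", nms[duplicated(nms)][1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, universe = universe, annotations = annotations)
}

#' Write gene sets to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' internal 1-based inclusive convention (`start + 1`).
#'
#' @param path BED file (chrom, start, end, name).
#' @return Gene model data frame (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "gene_id"),
                         colClasses = c("character", "integer", "integer", "character"))
  if (any(d$start < 0)) stop("negative BED coordinate")
  out <- data.frame(gene_id = d$gene_id, chrom = d$chrom,
                    start = d$start + 1L, end = d$end, stringsAsFactors = FALSE)
  if (any(out$end < out$start)) stop("end < start after BED conversion")
  out
}

#' Write gene models as BED (0-based half-open)
#'
#' @param genes Gene model data frame (1-based inclusive).
#' @param path Output path.
#' @export
write_bed <- function(genes, path) {
  utils::write.table(data.frame(genes$chrom, genes$start - 1L, genes$end,
                                genes$gene_id),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CNV calls from TSV
#'
#' Expects a header with `sample_id`, `chrom`, `start`, `end`, `dosage_type`
#' (1-based inclusive coordinates, types DEL/DUP).
#'
#' @param path File path.
#' @return CNV call data frame.
#' @export
read_cnv_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "dosage_type")
  if (!all(need %in% names(d))) stop("CNV TSV must have columns: ",
                                     paste(need, collapse = ", "))
  if (any(d$start < 1) || any(d$end < d$start)) stop("invalid CNV coordinates")
  bad <- setdiff(unique(d$dosage_type), c("DEL", "DUP"))
  if (length(bad)) stop("unknown dosage type: ", paste(bad, collapse = ", "))
  d[need]
}

#' Read an expression matrix from TSV (genes x contexts)
#'
#' @param path File path; first column gene identifiers, remaining columns
#'   contexts.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(d)
}

.write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1)) & !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], signif, digits = 6)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exchange formats the pipeline reads back: genes as BED and TSV,
#' CNVs, expression, phenotypes as TSV, and the ground truth as JSON.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(cohort$genes, file.path(dir, "genes.bed"))
  .write_tsv(cohort$genes, file.path(dir, "genes.tsv"))
  .write_tsv(cohort$cnvs, file.path(dir, "cnvs.tsv"))
  expr <- data.frame(gene_id = rownames(cohort$expression), cohort$expression,
                     check.names = FALSE)
  .write_tsv(expr, file.path(dir, "expression.tsv"))
  .write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  .write_tsv(cohort$traits, file.path(dir, "traits.tsv"))
  truth <- cohort$truth
  truth$constraint_labels <- names(truth$constraint_labels)[truth$constraint_labels]
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Run the full functional burden pipeline
#'
#' Orchestrates every stage on either a synthetic cohort (generated from the
#' config's `synthetic` block) or on-disk inputs: TDEP gene sets from the
#' expression matrix, burden aggregation, the FunBurd association grid with
#' joint FDR, functional pleiotropy, constraint summaries and normative
#' bands, burden correlations, and dosage-response classification. All
#' tables are written as TSV plus a JSON manifest (input checksums, seeds,
#' grid dimensions, package version) sufficient to reproduce the run.
#'
#' @param config Path to a YAML file or a named list with elements
#'   `out_dir`, optional `seed`, `q_threshold`, `decile`, `x2_scope`,
#'   `n_perm`, `normative` (`set_size`, `n_reps`, `fraction_grid`; omit the
#'   block to skip the normative stage), and
#'   either `synthetic` (arguments to [synth_config()]) or file paths
#'   `genes`, `cnvs`, `expression`, `phenotypes`, `traits`, `constraint`.
#' @return Invisibly, a list with the fitted objects and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  q_threshold <- config$q_threshold %||% 0.05
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      sc <- do.call(synth_config, c(config$synthetic, list(seed = seed)))
      cohort <- simulate_cohort(sc)
      write_cohort(cohort, file.path(out_dir, "inputs"))
      list(genes = cohort$genes, cnvs = cohort$cnvs,
           expression = cohort$expression, phenotypes = cohort$phenotypes,
           traits = cohort$traits,
           constraint = cohort$truth$constraint_labels)
    } else {
      list(genes = read_bed(config$genes),
           cnvs = read_cnv_tsv(config$cnvs),
           expression = read_expression_tsv(config$expression),
           phenotypes = utils::read.table(config$phenotypes, sep = "\t",
                                          header = TRUE, stringsAsFactors = FALSE),
           traits = utils::read.table(config$traits, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE),
           constraint = if (!is.null(config$constraint)) {
             d <- utils::read.table(config$constraint, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
             stats::setNames(as.logical(d$top_decile_flag), d$gene_id)
           })
    }
  })

  collection <- stage("genesets", {
    prop <- expression_proportion(inputs$expression)
    coll <- build_tdep_sets(prop, decile = config$decile %||% 0.10)
    write_gmt(coll, file.path(out_dir, "gene_sets.gmt"))
    coll
  })

  burden <- stage("burden", {
    b <- aggregate_burden(inputs$cnvs, inputs$genes, collection,
                          x2_scope = config$x2_scope %||% "same_cnv",
                          samples = as.character(inputs$phenotypes$sample_id))
    .write_tsv(as.data.frame(b), file.path(out_dir, "burden.tsv"))
    b
  })

  fit <- stage("assoc", {
    f <- funburd(inputs$phenotypes, inputs$traits, burden,
                 q_threshold = q_threshold)
    .write_tsv(f$results, file.path(out_dir, "association_grid.tsv"))
    f
  })

  pleio <- stage("pleiotropy", {
    p <- pleiotropy(fit)
    .write_tsv(p, file.path(out_dir, "pleiotropy.tsv"))
    p
  })

  norm <- NULL
  if (!is.null(inputs$constraint) && !is.null(config$normative)) {
    norm <- stage("normative", {
      fr <- constrained_fractions(collection, inputs$constraint)
      nv <- config$normative %||% list()
      runner <- make_funburd_runner(inputs$cnvs, inputs$genes,
                                    inputs$phenotypes, inputs$traits,
                                    q_threshold = q_threshold)
      bands <- normative_model(inputs$constraint, runner,
                               fraction_grid = nv$fraction_grid %||% seq(0, 0.4, 0.1),
                               set_size = nv$set_size %||% 100,
                               n_reps = nv$n_reps %||% 50,
                               seed = seed)
      .write_tsv(bands$centiles, file.path(out_dir, "normative_bands.tsv"))
      pk <- pleio[pleio$dosage_type == "DEL", ]
      cent <- vapply(seq_len(nrow(pk)), function(i) {
        fr_i <- min(max(fr[pk$gene_set[i]], min(bands$fraction_grid)),
                    max(bands$fraction_grid))
        normalized_pleiotropy(pk$n_sig[i], fr_i, bands)$centile
      }, numeric(1))
      .write_tsv(data.frame(gene_set = pk$gene_set, constrained_fraction =
                              unname(fr[pk$gene_set]), pleiotropy = pk$n_sig,
                            centile = cent),
                 file.path(out_dir, "normalized_pleiotropy.tsv"))
      bands
    })
  }

  corr <- stage("correlate", {
    lapply(c(DEL = "DEL", DUP = "DUP"), function(type) {
      bc <- burden_correlations(inputs$phenotypes, inputs$traits, burden,
                                dosage_type = type, collection = collection,
                                n_perm = config$n_perm %||% 0, seed = seed)
      utils::write.table(signif(bc$rg, 6),
                         file.path(out_dir, paste0("burden_rg_", type, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
      bc
    })
  })

  responses <- stage("dosage", {
    r <- classify_responses(fit, q_threshold = q_threshold)
    .write_tsv(r, file.path(out_dir, "dosage_responses.tsv"))
    r
  })

  stage("manifest", {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("funburd")),
      r_version = R.version.string,
      seed = seed, q_threshold = q_threshold,
      grid = list(n_sets = length(collection$sets),
                  n_traits = nrow(inputs$traits), n_types = 2,
                  n_cells = nrow(fit$results)),
      checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(collection = collection, burden = burden, fit = fit,
                 pleiotropy = pleio, normative = norm, correlations = corr,
                 responses = responses, out_dir = out_dir))
}
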