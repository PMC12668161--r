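# Independent oracles used across tests: deliberately naive implementations
# that never share code with the package internals.

# All-pairs interval containment scan with set-union semantics.
brute_burden <- function(cnvs, genes, sets, x2_scope = "same_cnv",
                         samples = sort(unique(cnvs$sample_id))) {
  out <- expand.grid(sample_id = samples, gene_set = names(sets),
                     dosage_type = c("DEL", "DUP"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$x1 <- 0L
  out$x2 <- 0L
  for (r in seq_len(nrow(out))) {
    rows <- which(cnvs$sample_id == out$sample_id[r] &
                    cnvs$dosage_type == out$dosage_type[r])
    members <- sets[[out$gene_set[r]]]
    in_genes <- character(0)
    out_genes <- character(0)
    all_genes <- character(0)
    for (i in rows) {
      hit <- genes$gene_id[genes$chrom == cnvs$chrom[i] &
                             genes$start >= cnvs$start[i] &
                             genes$end <= cnvs$end[i]]
      all_genes <- union(all_genes, hit)
      if (any(hit %in% members)) {
        in_genes <- union(in_genes, intersect(hit, members))
        out_genes <- union(out_genes, setdiff(hit, members))
      }
    }
    out$x1[r] <- length(if (x2_scope == "same_cnv") in_genes
                        else intersect(all_genes, members))
    out$x2[r] <- if (x2_scope == "same_cnv") length(out_genes)
                 else length(setdiff(all_genes, members))
  }
  out
}

# Benjamini-Hochberg by the textbook step-up recursion.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# OLS coefficient for the second column via explicit normal equations.
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Long-format lookup into a burden_table.
burden_cell <- function(bt, sample, set, type) {
  c(x1 = unname(bt$x1[[type]][sample, set]),
    x2 = unname(bt$x2[[type]][sample, set]))
}
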