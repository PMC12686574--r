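# Shared in-code fixtures for the test suite.

# Small count matrix with explicit per-group means (one column block per
# genotype:age cell), NB noise optional.
make_counts <- function(mean_matrix, groups, n_reps = 3, dispersion = NULL,
                        seed = 1) {
  set.seed(seed)
  G <- nrow(mean_matrix)
  cols <- list(); meta <- list()
  for (g in seq_len(ncol(mean_matrix))) {
    for (r in seq_len(n_reps)) {
      mu <- mean_matrix[, g]
      y <- if (is.null(dispersion)) round(mu)
           else stats::rnbinom(G, mu = mu, size = 1 / dispersion)
      cols[[length(cols) + 1]] <- y
      meta[[length(meta) + 1]] <- data.frame(
        genotype = groups$genotype[g], age_group = groups$age_group[g],
        replicate = r)
    }
  }
  counts <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  meta$sample <- sprintf("%s_%s_R%d", meta$genotype, meta$age_group,
                         meta$replicate)
  dimnames(counts) <- list(
    if (is.null(rownames(mean_matrix))) sprintf("g%04d", seq_len(G))
    else rownames(mean_matrix),
    meta$sample)
  count_matrix(counts, meta)
}

# Hand-built deg_table for rule-level acceleration tests.
make_deg <- function(genes, sig_genes = character(), directions = character(),
                     reference = list(genotype = "WT", age_group = "2-6"),
                     test = list(genotype = "WT", age_group = "30-36")) {
  dmap <- stats::setNames(directions, sig_genes)
  res <- data.frame(
    gene = genes, baseMean = 100, log2FC = 0, se = 0.1, stat = 0,
    pvalue = 1, padj = 1, direction = NA_character_, significant = FALSE,
    stringsAsFactors = FALSE)
  i <- match(sig_genes, genes)
  res$significant[i] <- TRUE
  res$padj[i] <- 0.001
  res$direction[i] <- dmap[res$gene[i]]
  res$log2FC[i] <- ifelse(res$direction[i] == "up", 2, -2)
  structure(res, class = c("deg_table", "data.frame"),
            reference = reference, test = test, alpha_fdr = 0.05, lfc_min = 0,
            contrast = paste(paste(unlist(reference), collapse = ":"), "vs",
                             paste(unlist(test), collapse = ":")))
}

# Minimal stem_fit-like object for overlap rule tests.
make_stem_fit <- function(genotype, vectors, assignments, significance) {
  attr(vectors, "ages") <- colnames(vectors)
  structure(list(genotype = genotype, vectors = vectors, profiles = NULL,
                 assignments = assignments, significance = significance),
            class = "stem_fit")
}

# Default small simulated experiment reused across tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_experiment(sim_design(n_genes = 1200, seed = 404))
    cache
  }
})
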