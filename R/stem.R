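#' Per-gene temporal expression vectors for one genotype
#'
#' Collapses a count matrix to one vector per gene over the ordered age
#' groups of a genotype: the log2 ratio of the age-group mean of normalised
#' counts to the first-age mean, with a pseudocount, so every vector starts
#' at exactly 0.
#'
#' @param x A [count_matrix()].
#' @param genotype Genotype whose samples to use.
#' @param pseudocount Added to both numerator and denominator means before the
#'   log ratio (in normalised-count units).
#' @param sf Optional pre-computed size factors for all samples of `x`.
#' @return Numeric matrix, genes by age groups, with an `ages` attribute.
#' @export
transform_expression <- function(x, genotype, pseudocount = 1, sf = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  sel <- x$samples$genotype == genotype
  if (!any(sel)) stop("genotype not present: ", genotype)
  ages <- levels(droplevels(x$samples$age_group[sel]))
  if (length(ages) < 2) stop("genotype needs at least two age groups")
  if (is.null(sf)) sf <- size_factors(x, fallback = TRUE)
  norm <- sweep(x$counts, 2, sf, "/")
  means <- vapply(ages, function(a) {
    j <- which(sel & as.character(x$samples$age_group) == a)
    rowMeans(norm[, j, drop = FALSE])
  }, numeric(nrow(norm)))
  v <- log2((means + pseudocount) / (means[, 1] + pseudocount))
  v[, 1] <- 0
  dimnames(v) <- list(rownames(x$counts), ages)
  attr(v, "ages") <- ages
  v
}

#' Enumerate integer-step model profiles
#'
#' All temporal model profiles over `T` time points whose successive changes
#' are integers in `[-c, c]`: `(2c+1)^(T-1)` profiles in total, with
#' deterministic 0-based ids in lexicographic order over the step sequences
#' (steps of the first transition vary slowest, `-c` first).
#'
#' @param n_time Number of time points `T` (>= 2).
#' @param c_max Maximum absolute unit change per transition (>= 1).
#' @return An object of class `stem_profiles`: list with `id` (integer),
#'   `steps` (profiles x T-1) and `values` (profiles x T, cumulative from 0).
#' @examples
#' p <- enumerate_profiles(4, 1)
#' nrow(p$steps)  # 27
#' @export
enumerate_profiles <- function(n_time, c_max = 1) {
  if (n_time < 2) stop("need at least 2 time points")
  if (c_max < 1) stop("c_max must be >= 1")
  k <- n_time - 1
  grids <- rep(list(seq(-c_max, c_max)), k)
  # expand.grid varies the first factor fastest; reverse for lexicographic ids
  steps <- as.matrix(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE))[, k:1,
                                                                      drop = FALSE]
  colnames(steps) <- paste0("step", seq_len(k))
  values <- cbind(0, t(apply(steps, 1, cumsum)))
  if (k == 1) values <- cbind(0, steps[, 1])  # apply drops dims at k = 1
  colnames(values) <- paste0("t", seq_len(n_time))
  structure(list(id = seq_len(nrow(steps)) - 1L, steps = steps,
                 values = values),
            class = "stem_profiles")
}

#' @export
print.stem_profiles <- function(x, ...) {
  cat(sprintf("stem_profiles: %d profiles over %d time points\n",
              length(x$id), ncol(x$values)))
  invisible(x)
}

profileDirection <- function(profiles) {
  s <- rowSums(profiles$steps)
  ifelse(s > 0, "up", ifelse(s < 0, "down", "flat"))
}

#' Greedy max-min selection of representative profiles
#'
#' Reduces the full profile catalogue to `m` mutually dissimilar
#' representatives under the distance `1 - Pearson correlation` of profile
#' values. The first representative is the non-flat profile with the largest
#' summed absolute step size (lowest id on ties); each subsequent one
#' maximises the minimum distance to the already-chosen set (again lowest id
#' on ties). Flat profiles (all steps 0) are excluded because their
#' correlation is undefined.
#'
#' @param profiles A `stem_profiles` catalogue.
#' @param m Number of representatives; if `m` is at least the number of
#'   usable profiles, all are returned.
#' @return A `stem_profiles` object restricted to the selection (original ids
#'   kept).
#' @export
select_representatives <- function(profiles, m = 50) {
  stopifnot(inherits(profiles, "stem_profiles"))
  if (m < 2) stop("m must be >= 2")
  usable <- which(apply(profiles$values, 1, stats::sd) > 0)
  if (length(usable) == 0)
    stop("no non-flat profiles: correlation distance undefined")
  vals <- profiles$values[usable, , drop = FALSE]
  if (m >= length(usable)) {
    keep <- usable
  } else {
    cm <- stats::cor(t(vals))          # profiles x profiles
    d <- 1 - cm
    sz <- rowSums(abs(profiles$steps[usable, , drop = FALSE]))
    chosen <- which.max(sz)            # ties -> lowest index = lowest id
    while (length(chosen) < m) {
      mind <- apply(d[, chosen, drop = FALSE], 1, min)
      mind[chosen] <- -Inf
      chosen <- c(chosen, which.max(mind))
    }
    keep <- usable[sort(chosen)]
  }
  structure(list(id = profiles$id[keep],
                 steps = profiles$steps[keep, , drop = FALSE],
                 values = profiles$values[keep, , drop = FALSE]),
            class = "stem_profiles")
}

#' Assign genes to their best-correlated model profile
#'
#' Each gene with a non-constant expression vector is assigned to the
#' representative profile whose values have the largest Pearson correlation
#' with the gene's vector; ties break to the lowest profile id. Constant
#' vectors are unassignable (`profile_id` NA) and excluded from profile
#' counts.
#'
#' @param vectors Genes-by-time matrix, e.g. from [transform_expression()].
#' @param profiles Representative `stem_profiles` (same number of time
#'   points).
#' @return Data frame with columns `gene`, `profile_id`, `correlation`,
#'   `direction` (net profile direction: up / down / flat).
#' @export
assign_genes <- function(vectors, profiles) {
  stopifnot(inherits(profiles, "stem_profiles"))
  if (ncol(vectors) != ncol(profiles$values))
    stop("vector length does not match profile length")
  keep <- apply(vectors, 1, stats::sd) > 0
  co <- matrix(NA_real_, nrow(vectors), length(profiles$id))
  if (any(keep))
    co[keep, ] <- stats::cor(t(vectors[keep, , drop = FALSE]),
                             t(profiles$values))
  best <- rep(NA_integer_, nrow(vectors))
  best[keep] <- max.col(co[keep, , drop = FALSE], ties.method = "first")
  dirs <- profileDirection(profiles)
  data.frame(
    gene = rownames(vectors),
    profile_id = ifelse(is.na(best), NA_integer_, profiles$id[best]),
    correlation = ifelse(is.na(best), NA_real_,
                         co[cbind(seq_len(nrow(vectors)), best)]),
    direction = ifelse(is.na(best), NA_character_, dirs[best]),
    stringsAsFactors = FALSE)
}

# Permute the columns of each row of `vectors` independently. Time series are
# short (T <= ~6), so genes are binned by one of the T! column permutations.
permuteRows <- function(vectors) {
  n_time <- ncol(vectors)
  perms <- allPermutations(n_time)
  pick <- sample.int(nrow(perms), nrow(vectors), replace = TRUE)
  out <- vectors
  for (p in seq_len(nrow(perms))) {
    rows <- which(pick == p)
    if (length(rows))
      out[rows, ] <- vectors[rows, perms[p, ], drop = FALSE]
  }
  out
}

allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) }))
}

#' Permutation significance of profile gene counts
#'
#' Tests whether each representative profile attracts more genes than
#' expected under temporal exchangeability. The null is built by permuting
#' each gene's time points independently and re-assigning all genes; the
#' per-profile p-value is `(1 + #(null count >= observed)) / (1 + n_perm)`,
#' Bonferroni-adjusted over the representatives.
#'
#' @param vectors Genes-by-time matrix.
#' @param profiles Representative `stem_profiles`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Data frame with one row per representative: `profile_id`,
#'   `direction`, `n_genes`, `pvalue`, `padj`, `significant`.
#' @export
profile_significance <- function(vectors, profiles, n_perm = 1000,
                                 seed = 1L, alpha = 0.05) {
  stopifnot(inherits(profiles, "stem_profiles"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  ids <- profiles$id
  pv <- t(profiles$values)
  # constant vectors stay constant under permutation, so filter once
  keep <- apply(vectors, 1, stats::sd) > 0
  kept <- t(vectors[keep, , drop = FALSE])
  count_kept <- function(mat) {
    best <- max.col(stats::cor(mat, pv), ties.method = "first")
    tabulate(best, nbins = length(ids))
  }
  n_obs <- count_kept(kept)
  exceed <- integer(length(ids))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- t(permuteRows(t(kept)))
      exceed <- exceed + (count_kept(perm) >= n_obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  padj <- pmin(1, p * length(ids))
  data.frame(profile_id = ids, direction = profileDirection(profiles),
             n_genes = n_obs, pvalue = p, padj = padj,
             significant = padj < alpha, stringsAsFactors = FALSE)
}

#' Run the full profile-clustering stage for one genotype
#'
#' Convenience wrapper: transform expression, enumerate and select
#' representative profiles (profile length driven by the genotype's number of
#' age groups), assign genes and assess profile significance by permutation.
#'
#' @inheritParams transform_expression
#' @inheritParams profile_significance
#' @param c_max Maximum absolute unit change per transition.
#' @param m Number of representative profiles.
#' @return A list of class `stem_fit`: `genotype`, `vectors`, `profiles`
#'   (representatives), `assignments`, `significance`.
#' @export
stem_fit <- function(x, genotype, c_max = 1, m = 50, n_perm = 1000,
                     seed = 1L, pseudocount = 1, sf = NULL, alpha = 0.05) {
  vectors <- transform_expression(x, genotype, pseudocount = pseudocount,
                                  sf = sf)
  catalogue <- enumerate_profiles(ncol(vectors), c_max)
  reps <- select_representatives(catalogue, m)
  assignments <- assign_genes(vectors, reps)
  significance <- profile_significance(vectors, reps, n_perm = n_perm,
                                       seed = seed, alpha = alpha)
  structure(list(genotype = genotype, vectors = vectors, profiles = reps,
                 assignments = assignments, significance = significance),
            class = "stem_fit")
}

#' @export
print.stem_fit <- function(x, ...) {
  cat(sprintf("stem_fit (%s): %d representatives over %d ages, %d significant\n",
              x$genotype, nrow(x$significance), ncol(x$vectors),
              sum(x$significance$significant)))
  print(x$significance[x$significance$significant, , drop = FALSE])
  invisible(x)
}

#' Gene lists of the significant profiles of a `stem_fit`
#'
#' @param fit A `stem_fit`.
#' @return Data frame `gene`, `profile_id`, `direction`, `correlation`
#'   restricted to genes assigned to significant profiles.
#' @export
significant_profile_genes <- function(fit) {
  stopifnot(inherits(fit, "stem_fit"))
  sig <- fit$significance$profile_id[fit$significance$significant]
  out <- fit$assignments[!is.na(fit$assignments$profile_id) &
                           fit$assignments$profile_id %in% sig, , drop = FALSE]
  rownames(out) <- NULL
  out
}
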