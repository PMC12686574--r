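#' Signed old-age signature from the wild-type young-vs-old contrast
#'
#' The "DEGs of old age": genes flagged significant in the contrast of the
#' youngest versus the oldest wild-type age group, together with their
#' direction of change. The function refuses DEG tables from any other
#' contrast, so the signature cannot silently be built from the wrong
#' comparison.
#'
#' @param deg A `deg_table` from [nb_test()] whose reference is the youngest
#'   and test the oldest wild-type group.
#' @param wt_genotype Genotype label of the wild type.
#' @param age_levels Ordered age-group labels of the wild-type arm.
#' @return Data frame `gene`, `direction` of the significant genes, with the
#'   old age group kept as attribute `old_age`.
#' @export
old_age_signature <- function(deg, wt_genotype = "WT",
                              age_levels = AGE_GROUPS) {
  stopifnot(inherits(deg, "deg_table"))
  ref <- attr(deg, "reference"); tst <- attr(deg, "test")
  ok <- identical(ref$genotype, wt_genotype) &&
    identical(tst$genotype, wt_genotype) &&
    identical(as.character(ref$age_group), age_levels[1]) &&
    identical(as.character(tst$age_group), age_levels[length(age_levels)])
  if (!ok)
    stop("signature requires the WT youngest-vs-oldest contrast, got: ",
         attr(deg, "contrast"))
  sig <- deg[deg$significant %in% TRUE, c("gene", "direction")]
  rownames(sig) <- NULL
  structure(sig, old_age = age_levels[length(age_levels)],
            age_levels = age_levels)
}

sigSameDirection <- function(deg, genes, directions) {
  i <- match(genes, deg$gene)
  hit <- !is.na(i) & deg$significant[i] %in% TRUE &
    deg$direction[i] == directions
  hit
}

#' Classify old-age genes as accelerated in the mutant
#'
#' For each gene of the old-age signature, scans the mutant DEG tables in
#' increasing age order for the earliest age ("onset") at which the gene
#' changes significantly in the same direction as in old wild types. The gene
#' is called accelerated when such an onset exists, its age rank is strictly
#' below the rank of the oldest wild-type group, and the sibling wild-type
#' contrast at the onset age shows no significant same-direction change
#' (i.e. the change really arrives earlier in the mutant than in siblings).
#'
#' @param signature Output of [old_age_signature()].
#' @param mutant_degs Named list of `deg_table`s, one per mutant contrast,
#'   names = the test age group, in any order; ages are ranked against
#'   `age_levels`.
#' @param sibling_degs Named list of wild-type `deg_table`s for the same test
#'   ages (same names as `mutant_degs`).
#' @param age_levels Ordered age-group labels (defaults to the attribute
#'   stored on the signature).
#' @param require_direction Require the mutant (and sibling) change to have
#'   the wild-type old-age direction. `TRUE` is the definition of
#'   acceleration; `FALSE` is offered as a sensitivity analysis and can only
#'   enlarge the accelerated set.
#' @return A list of class `acceleration_result`: `records` (data frame
#'   `gene`, `direction`, `onset_age`, `sibling_significant`, `accelerated`),
#'   `onset_counts` (named integer vector over onset ages), `n_accelerated`,
#'   `n_signature`, `pct_of_signature`.
#' @examples
#' # see the package tests for fully worked synthetic examples
#' @export
classify_acceleration <- function(signature, mutant_degs, sibling_degs,
                                  age_levels = attr(signature, "age_levels"),
                                  require_direction = TRUE) {
  if (is.null(age_levels)) age_levels <- AGE_GROUPS
  if (!setequal(names(mutant_degs), names(sibling_degs)))
    stop("mutant and sibling-WT DEG tables must cover the same age groups")
  ages <- names(mutant_degs)
  if (!all(ages %in% age_levels)) stop("unknown age group in DEG tables")
  ages <- ages[order(match(ages, age_levels))]
  old_rank <- length(age_levels)

  genes <- signature$gene
  dirs <- signature$direction
  sigHit <- function(deg, g, d) {
    if (require_direction) sigSameDirection(deg, g, d)
    else { i <- match(g, deg$gene); !is.na(i) & deg$significant[i] %in% TRUE }
  }
  onset <- rep(NA_character_, length(genes))
  sib <- rep(NA, length(genes))
  for (a in ages) {
    hit <- sigHit(mutant_degs[[a]], genes, dirs)
    new <- hit & is.na(onset)
    onset[new] <- a
    # the sibling block always requires the same direction: a sibling change
    # the other way is not evidence that the WT ages like the mutant does
    sib[new] <- sigSameDirection(sibling_degs[[a]], genes[new], dirs[new])
  }
  onset_rank <- match(onset, age_levels)
  accelerated <- !is.na(onset) & onset_rank < old_rank & !sib
  records <- data.frame(gene = genes, direction = dirs, onset_age = onset,
                        sibling_significant = sib, accelerated = accelerated,
                        stringsAsFactors = FALSE)
  onset_counts <- vapply(ages, function(a)
    sum(records$accelerated & records$onset_age == a, na.rm = TRUE), 0L)
  structure(list(records = records, onset_counts = onset_counts,
                 n_accelerated = sum(accelerated),
                 n_signature = length(genes),
                 pct_of_signature = if (length(genes))
                   100 * sum(accelerated) / length(genes) else 0),
            class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf("acceleration_result: %d / %d signature genes accelerated (%.1f%%)\n",
              x$n_accelerated, x$n_signature, x$pct_of_signature))
  cat("per-onset counts:\n")
  print(x$onset_counts)
  invisible(x)
}

#' Profile-based acceleration overlap between genotypes
#'
#' The profile-clustering analogue of [classify_acceleration()]: genes that
#' sit in a significant wild-type profile and in a significant mutant profile
#' of the same net direction, and whose mutant temporal vector reaches the
#' "changed" threshold (an absolute log2 deviation from the first age of at
#' least `threshold`, in the profile's direction) at a strictly earlier age
#' rank than the wild-type vector does. Results are grouped by the mutant
#' onset age.
#'
#' @param wt_fit,mut_fit `stem_fit` objects for the two genotypes.
#' @param threshold Absolute log2 deviation from the first age that counts as
#'   "changed".
#' @return Data frame `gene`, `direction`, `onset_age` (mutant onset),
#'   `wt_onset_age` (NA when the wild type never reaches the threshold).
#' @export
stem_acceleration_overlap <- function(wt_fit, mut_fit, threshold = 0.5) {
  stopifnot(inherits(wt_fit, "stem_fit"), inherits(mut_fit, "stem_fit"))
  wt <- significant_profile_genes(wt_fit)
  mut <- significant_profile_genes(mut_fit)
  wt <- wt[wt$direction %in% c("up", "down"), , drop = FALSE]
  m <- match(wt$gene, mut$gene)
  keep <- !is.na(m) & mut$direction[m] == wt$direction
  wt <- wt[keep, , drop = FALSE]
  if (nrow(wt) == 0)
    return(data.frame(gene = character(), direction = character(),
                      onset_age = character(), wt_onset_age = character(),
                      stringsAsFactors = FALSE))
  firstCross <- function(vec_row, dir) {
    dev <- if (dir == "up") vec_row >= threshold else vec_row <= -threshold
    i <- which(dev)
    if (length(i)) i[1] else NA_integer_
  }
  wt_ages <- attr(wt_fit$vectors, "ages")
  mut_ages <- attr(mut_fit$vectors, "ages")
  wt_on <- mapply(function(g, d) firstCross(wt_fit$vectors[g, ], d),
                  wt$gene, wt$direction)
  mut_on <- mapply(function(g, d) firstCross(mut_fit$vectors[g, ], d),
                   wt$gene, wt$direction)
  acc <- !is.na(mut_on) & (is.na(wt_on) | mut_on < wt_on)
  out <- data.frame(gene = wt$gene[acc], direction = wt$direction[acc],
                    onset_age = mut_ages[mut_on[acc]],
                    wt_onset_age = ifelse(is.na(wt_on[acc]), NA_character_,
                                          wt_ages[wt_on[acc]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(match(out$onset_age, mut_ages), out$gene), , drop = FALSE]
}

#' Write acceleration records as TSV
#'
#' @param result An `acceleration_result` (route "deg") or the data frame
#'   from [stem_acceleration_overlap()] (route "stem").
#' @param file Output path.
#' @param route Label recorded in the `route` column.
#' @export
write_acceleration <- function(result, file, route = c("deg", "stem")) {
  route <- match.arg(route)
  tab <- if (inherits(result, "acceleration_result")) {
    r <- result$records
    data.frame(gene = r$gene, direction = r$direction,
               onset_age = r$onset_age, accelerated = r$accelerated,
               route = route, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = result$gene, direction = result$direction,
               onset_age = result$onset_age,
               accelerated = rep(TRUE, nrow(result)),
               route = rep(route, nrow(result)), stringsAsFactors = FALSE)
  }
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
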