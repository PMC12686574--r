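#' Age-group labels of the wild-type study design
#'
#' Ordered age-group labels (months) used by default throughout the package:
#' young, young adult, middle aged and old. The mutant arm of the design uses
#' the first three only, because telomerase-deficient fish do not reach the
#' oldest group. All functions compare age groups by rank within this ordered
#' set, never by string value.
#'
#' @format Character vector of length 4.
#' @export
AGE_GROUPS <- c("2-6", "9-16", "18-24", "30-36")

#' Construct a count matrix with sample metadata
#'
#' Bundles a genes-by-samples integer count matrix with its sample metadata
#' table into a validated `count_matrix` object, the input container for the
#' differential-expression and profile-clustering stages.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Counts must be non-negative.
#' @param samples Data frame with one row per column of `counts` and columns
#'   `sample`, `genotype`, `age_group`, `replicate`. `age_group` is coerced to
#'   an ordered factor; its level order defines age rank.
#' @param age_levels Ordered age-group labels. Defaults to the levels already
#'   present on `samples$age_group`, or [AGE_GROUPS] restricted to the
#'   observed labels.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @examples
#' cm <- count_matrix(
#'   matrix(rpois(12, 10), 3, 4,
#'          dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
#'   data.frame(sample = paste0("s", 1:4), genotype = "WT",
#'              age_group = rep(c("2-6", "9-16"), each = 2),
#'              replicate = rep(1:2, 2)))
#' @export
count_matrix <- function(counts, samples, age_levels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in 'counts'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in 'counts'")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  storage.mode(counts) <- "double"  # keeps large counts exact, avoids int overflow in sums
  samples <- as.data.frame(samples)
  need <- c("sample", "genotype", "age_group", "replicate")
  if (!all(need %in% names(samples)))
    stop("'samples' must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids in metadata")
  if (!setequal(samples$sample, colnames(counts)))
    stop("metadata samples and count columns disagree")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(age_levels)) {
    age_levels <- if (is.factor(samples$age_group)) {
      levels(samples$age_group)
    } else {
      lv <- AGE_GROUPS[AGE_GROUPS %in% unique(as.character(samples$age_group))]
      if (length(lv)) lv else unique(as.character(samples$age_group))
    }
  }
  if (!all(as.character(samples$age_group) %in% age_levels))
    stop("age_group labels outside 'age_levels'")
  samples$age_group <- factor(as.character(samples$age_group),
                              levels = age_levels, ordered = TRUE)
  samples$genotype <- as.character(samples$genotype)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(genotype = x$samples$genotype, age = x$samples$age_group)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read / write a count matrix as TSV
#'
#' The counts file has the gene id in the first column and one column per
#' sample; the metadata file has columns `sample`, `genotype`, `age_group`,
#' `replicate`.
#'
#' @param counts_file,metadata_file Paths to the two TSV files.
#' @param age_levels Passed to [count_matrix()].
#' @return A `count_matrix`.
#' @export
read_counts <- function(counts_file, metadata_file, age_levels = NULL) {
  tab <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
  meta$sample <- as.character(meta$sample)
  count_matrix(counts, meta, age_levels = age_levels)
}

#' @rdname read_counts
#' @param x A `count_matrix`.
#' @export
write_counts <- function(x, counts_file, metadata_file) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Sample selector for a genotype / age-group cell
#'
#' @param x A `count_matrix`.
#' @param genotype,age_group Values to match; either may be `NULL` to match
#'   all.
#' @return Integer indices into the sample columns.
#' @keywords internal
sample_index <- function(x, genotype = NULL, age_group = NULL) {
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(genotype)) keep <- keep & x$samples$genotype == genotype
  if (!is.null(age_group))
    keep <- keep & as.character(x$samples$age_group) == as.character(age_group)
  which(keep)
}
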