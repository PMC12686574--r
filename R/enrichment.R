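#' Gene-set collection with a universe
#'
#' Named gene sets harmonised against a declared gene universe: set members
#' outside the universe are dropped (with a message when any are), and set
#' names must be unique. The universe is the denominator of every
#' over-representation test run against the collection.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector: the gene universe.
#' @param provenance Free-text label describing where the sets come from.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, provenance = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must have unique names")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  dropped <- 0L
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    keep <- s %in% universe
    dropped <<- dropped + sum(!keep)
    s[keep]
  })
  if (dropped > 0)
    message(dropped, " set member(s) outside the universe were dropped")
  structure(list(sets = sets, universe = universe, provenance = provenance),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d universe genes (%s)\n",
              length(x$sets), length(x$universe), x$provenance))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param file Path to a GMT file.
#' @param universe Universe for the resulting collection; defaults to the
#'   union of all set members.
#' @param provenance Label for the collection (defaults to the file name).
#' @return `read_gmt()`: a [gene_set_collection()]. `write_gmt()`: the
#'   collection, invisibly.
#' @export
read_gmt <- function(file, universe = NULL, provenance = basename(file)) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  gene_set_collection(sets, universe, provenance)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, file) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$provenance, collection$sets[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, file)
  invisible(collection)
}

#' Upper-tail hypergeometric test
#'
#' Exact probability of observing an overlap at least as large as `k` between
#' a query of size `n` and a set of size `K` drawn without replacement from a
#' universe of size `N` (Fisher's exact test under the hypergeometric
#' distribution, enrichment-only).
#'
#' @param k Observed overlap.
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return P(X >= k), in (0, 1]. Vectorised over its arguments.
#' @examples
#' hypergeom_test(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stop("inconsistent margins: need 0 <= k <= min(K, n), K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' One upper-tail hypergeometric test per set, with the chosen
#' multiple-testing correction applied over the tested sets, results sorted
#' by adjusted p, then raw p, then set name, and truncated to the top `top_k`
#' rows. Query genes outside the universe are dropped (with a message).
#'
#' @param query Character vector of gene ids.
#' @param collection A [gene_set_collection()].
#' @param correction `"bh"` or `"bonferroni"`.
#' @param top_k Maximum number of rows to return.
#' @return Data frame `set`, `k`, `K`, `n`, `N`, `pvalue`, `padj`, `method`.
#' @export
ora <- function(query, collection, correction = c("bh", "bonferroni"),
                top_k = Inf) {
  correction <- match.arg(correction)
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query")
  inuniv <- query %in% collection$universe
  if (any(!inuniv))
    message(sum(!inuniv), " query gene(s) outside the universe were dropped")
  query <- query[inuniv]
  if (length(query) == 0) stop("no query gene is in the universe")
  N <- length(collection$universe)
  n <- length(query)
  K <- lengths(collection$sets)
  k <- vapply(collection$sets, function(s) sum(query %in% s), 0L)
  p <- hypergeom_test(k, K, n, N)
  padj <- if (correction == "bh") bh_adjust(p) else pmin(1, p * length(p))
  out <- data.frame(set = names(collection$sets), k = k, K = K, n = n, N = N,
                    pvalue = p, padj = padj, method = correction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$pvalue, out$set), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Cell-type marker-programme enrichment per profile
#'
#' Runs [ora()] with Bonferroni correction (the convention for cell-type
#' marker programmes) for each profile's gene list against the marker
#' collection, whose universe should be the full gene catalogue.
#'
#' @param profile_genes Named list: profile label -> character vector of
#'   genes.
#' @param programmes A [gene_set_collection()] of marker programmes.
#' @param top_k Rows kept per profile.
#' @return Named list of [ora()] tables, one per profile.
#' @export
celltype_enrichment <- function(profile_genes, programmes, top_k = Inf) {
  lapply(profile_genes, ora, collection = programmes,
         correction = "bonferroni", top_k = top_k)
}

#' Overlap of analysis routes with SASP gene sets
#'
#' Cross-references the genes flagged by the analysis routes (e.g. the
#' profile-based and the DEG-based acceleration analyses) with
#' senescence-associated secretory phenotype collections: for every flagged
#' gene found in at least one SASP set, reports which collections contain it,
#' which route flagged it and the route's onset age if available.
#'
#' @param routes Named list: route label -> data frame with a `gene` column
#'   and optionally an `onset_age` column (a bare character vector of genes
#'   also works).
#' @param sasp A [gene_set_collection()] of SASP sets.
#' @return Data frame `gene`, `collection`, `route`, `onset_age`.
#' @export
sasp_overlap <- function(routes, sasp) {
  stopifnot(inherits(sasp, "gene_set_collection"))
  out <- list()
  for (r in names(routes)) {
    tab <- routes[[r]]
    if (is.character(tab))
      tab <- data.frame(gene = tab, stringsAsFactors = FALSE)
    onset <- if ("onset_age" %in% names(tab)) tab$onset_age
             else rep(NA_character_, nrow(tab))
    for (s in names(sasp$sets)) {
      hit <- tab$gene %in% sasp$sets[[s]]
      if (any(hit))
        out[[length(out) + 1]] <- data.frame(
          gene = tab$gene[hit], collection = s, route = r,
          onset_age = onset[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene = character(), collection = character(),
                      route = character(), onset_age = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
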