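#' Minimal OBO reader / writer
#'
#' Parses `[Term]` stanzas of an OBO ontology file, keeping the four fields
#' the hallmark-mapping stage needs: `id`, `name`, `namespace` and
#' `is_obsolete`. Everything else (relationships, synonyms, typedefs) is
#' ignored.
#'
#' @param file Path to an OBO file.
#' @return `read_obo()`: data frame with columns `id`, `name`, `namespace`,
#'   `is_obsolete`.
#' @export
read_obo <- function(file) {
  lines <- readLines(file)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0)
    return(data.frame(id = character(), name = character(),
                      namespace = character(), is_obsolete = logical(),
                      stringsAsFactors = FALSE))
  bounds <- c(starts[-1] - 1L, length(lines))
  field <- function(block, key) {
    pat <- paste0("^", key, ": ")
    hit <- grep(pat, block, value = TRUE)
    if (length(hit)) sub(pat, "", hit[1]) else NA_character_
  }
  rows <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:bounds[i]]
    block <- block[seq_len(which(c(block, "") == "")[1] - 1)]  # stop at blank
    data.frame(id = field(block, "id"), name = field(block, "name"),
               namespace = field(block, "namespace"),
               is_obsolete = identical(field(block, "is_obsolete"), "true"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$id), , drop = FALSE]
}

#' @rdname read_obo
#' @param ontology Data frame with columns `id`, `name`, `namespace`,
#'   `is_obsolete`.
#' @export
write_obo <- function(ontology, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology))) {
    writeLines(c("[Term]",
                 paste0("id: ", ontology$id[i]),
                 paste0("name: ", ontology$name[i]),
                 paste0("namespace: ", ontology$namespace[i]),
                 if (isTRUE(ontology$is_obsolete[i])) "is_obsolete: true",
                 ""), con)
  }
  invisible(ontology)
}

#' Read a hallmark keyword map
#'
#' CSV with columns `hallmark` and `keyword` (one keyword per row, possibly
#' several rows per hallmark). Keywords are lowercased; every hallmark must
#' have at least one non-empty keyword.
#'
#' @param file Path to the CSV.
#' @return Data frame with columns `hallmark`, `keyword`.
#' @export
read_keyword_map <- function(file) {
  km <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_keyword_map(km)
}

validate_keyword_map <- function(km) {
  if (!all(c("hallmark", "keyword") %in% names(km)))
    stop("keyword map needs columns 'hallmark' and 'keyword'")
  km$keyword <- tolower(trimws(km$keyword))
  if (any(!nzchar(km$keyword))) stop("empty keyword in map")
  if (any(!nzchar(km$hallmark))) stop("empty hallmark label in map")
  km[, c("hallmark", "keyword")]
}

#' Map ontology terms to hallmarks by keyword matching
#'
#' A term maps to a hallmark when any of the hallmark's keywords occurs
#' case-insensitively inside the term name — as a plain substring by default,
#' or only at word boundaries with `word_boundary = TRUE`. Obsolete terms and
#' terms outside the requested namespaces are skipped; a term may map to
#' several hallmarks.
#'
#' @param ontology Data frame from [read_obo()].
#' @param keyword_map Data frame with columns `hallmark`, `keyword` (see
#'   [read_keyword_map()]); keywords are lowercased on the way in.
#' @param namespaces Ontology namespaces to use (default: biological process
#'   only).
#' @param word_boundary Require keyword matches to start and end at word
#'   boundaries.
#' @return Named list: term id -> character vector of hallmark labels. Terms
#'   with no match are absent.
#' @export
build_term_map <- function(ontology, keyword_map,
                           namespaces = "biological_process",
                           word_boundary = FALSE) {
  if (nrow(ontology) == 0) stop("empty ontology")
  keyword_map <- validate_keyword_map(keyword_map)
  keep <- !ontology$is_obsolete & ontology$namespace %in% namespaces &
    !is.na(ontology$name)
  terms <- ontology[keep, , drop = FALSE]
  nm <- tolower(terms$name)
  hits <- vector("list", nrow(terms))
  for (i in seq_len(nrow(keyword_map))) {
    kw <- keyword_map$keyword[i]
    found <- if (word_boundary) {
      grepl(paste0("\\b", kw, "\\b"), nm, perl = TRUE)
    } else {
      grepl(kw, nm, fixed = TRUE)
    }
    for (j in which(found))
      hits[[j]] <- c(hits[[j]], keyword_map$hallmark[i])
  }
  names(hits) <- terms$id
  hits <- lapply(hits, unique)
  hits[lengths(hits) > 0]
}

#' Assign genes to ageing transcriptomic hallmarks
#'
#' Per gene, counts how often each hallmark occurs among the hallmark-mapped
#' GO terms annotated to the gene (a term contributes once to every hallmark
#' it maps to, or — with `single_assignment = TRUE` — only to its first
#' hallmark). The label follows the three-case rule: a gene whose mapped
#' terms all point at one hallmark gets that hallmark (case 1); when several
#' hallmarks occur, the one with the strictly highest count wins (case 2),
#' with ties labelled `"ambiguous"`; a gene none of whose terms map to any
#' hallmark is `"unannotated"` (case 3). Unknown term ids are ignored with a
#' message.
#'
#' @param gene2go Data frame with columns `gene` and `term`.
#' @param term_map Named list from [build_term_map()].
#' @param genes Genes to report on (defaults to those present in `gene2go`);
#'   genes without any annotation row are labelled `"unannotated"`.
#' @param single_assignment Count a multi-hallmark term toward its first
#'   hallmark only.
#' @return Data frame of class `hallmark_assignment`: `gene`, `label`,
#'   `n_terms` (terms considered), one count column per hallmark.
#' @export
assign_hallmarks <- function(gene2go, term_map,
                             genes = unique(gene2go$gene),
                             single_assignment = FALSE) {
  hallmarks <- sort(unique(unlist(term_map, use.names = FALSE)))
  known <- gene2go$term %in% names(term_map)
  # term ids absent from the ontology-derived map but formatted like ids are
  # fine (they simply do not map); count unknown-looking ids for the log
  counts <- matrix(0L, length(genes), length(hallmarks),
                   dimnames = list(genes, hallmarks))
  n_terms <- integer(length(genes))
  names(n_terms) <- genes
  tab <- gene2go[gene2go$gene %in% genes, , drop = FALSE]
  tt <- table(factor(tab$gene, levels = genes))
  n_terms[names(tt)] <- as.integer(tt)
  tab <- tab[tab$term %in% names(term_map), , drop = FALSE]
  if (nrow(tab)) {
    hm <- term_map[tab$term]
    if (single_assignment) hm <- lapply(hm, `[`, 1)
    long_gene <- rep(tab$gene, lengths(hm))
    long_hm <- unlist(hm, use.names = FALSE)
    inc <- table(factor(long_gene, levels = genes),
                 factor(long_hm, levels = hallmarks))
    counts <- counts + unclass(inc)
  }
  label <- apply(counts, 1, function(r) {
    if (all(r == 0)) return("unannotated")
    top <- which(r == max(r))
    if (length(top) > 1) "ambiguous" else hallmarks[top]
  })
  out <- data.frame(gene = genes, label = unname(label),
                    n_terms = unname(n_terms),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(unclass(counts), row.names = NULL))
  rownames(out) <- NULL
  class(out) <- c("hallmark_assignment", "data.frame")
  attr(out, "hallmarks") <- hallmarks
  out
}

#' Hallmark label proportions over a gene set
#'
#' Proportions of each label (every hallmark, plus `ambiguous` and
#' `unannotated`) among the genes of a set; genes missing from the
#' assignment table count as unannotated. Also returns the proportions
#' renormalised over annotated genes only (hallmarks + ambiguous).
#'
#' @param genes Character vector of gene ids (the set).
#' @param assignments A `hallmark_assignment` table covering (at least) the
#'   set.
#' @return List with `proportions` (sums to 1 over all labels) and
#'   `annotated_proportions` (sums to 1 over annotated labels; all-NA when no
#'   gene is annotated).
#' @export
hallmark_proportions <- function(genes, assignments) {
  if (length(genes) == 0) stop("empty gene set")
  hallmarks <- attr(assignments, "hallmarks")
  labels <- c(hallmarks, "ambiguous", "unannotated")
  lab <- assignments$label[match(genes, assignments$gene)]
  lab[is.na(lab)] <- "unannotated"
  pr <- table(factor(lab, levels = labels)) / length(genes)
  pr <- stats::setNames(as.numeric(pr), labels)
  ann <- lab != "unannotated"
  annotated <- if (any(ann)) {
    a <- table(factor(lab[ann], levels = setdiff(labels, "unannotated")))
    stats::setNames(as.numeric(a) / sum(ann), setdiff(labels, "unannotated"))
  } else {
    stats::setNames(rep(NA_real_, length(labels) - 1),
                    setdiff(labels, "unannotated"))
  }
  list(proportions = pr, annotated_proportions = annotated)
}
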