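toy_ontology <- data.frame(
  id = sprintf("GO:%07d", 1:6),
  name = c("immune response", "cell cycle", "response to oxidative stress",
           "regulation of transcription", "obsolete immune thing",
           "immune receptor activity"),
  namespace = c(rep("biological_process", 5), "molecular_function"),
  is_obsolete = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE)

toy_map <- data.frame(
  hallmark = c("immune", "immune", "stress", "expression"),
  keyword = c("immune", "inflammat", "stress", "transcription"),
  stringsAsFactors = FALSE)

test_that("term map applies the substring rule and skips obsolete terms", {
  tm <- build_term_map(toy_ontology, toy_map)
  expect_identical(tm[["GO:0000001"]], "immune")
  expect_identical(tm[["GO:0000003"]], "stress")
  expect_false("GO:0000002" %in% names(tm))  # no keyword hit
  expect_false("GO:0000005" %in% names(tm))  # obsolete
  expect_false("GO:0000006" %in% names(tm))  # wrong namespace by default
  tm2 <- build_term_map(toy_ontology, toy_map,
                        namespaces = c("biological_process",
                                       "molecular_function"))
  expect_identical(tm2[["GO:0000006"]], "immune")
  expect_error(build_term_map(toy_ontology[0, ], toy_map), "empty ontology")
})

test_that("term map equals a brute-force double loop on the fixture ontology", {
  sim <- small_sim()
  ann <- simulate_annotation(sim)
  km <- ann$keyword_map
  tm <- build_term_map(ann$ontology, km)
  ok <- !ann$ontology$is_obsolete &
    ann$ontology$namespace == "biological_process"
  oracle <- list()
  for (i in which(ok)) {
    hs <- character()
    for (j in seq_len(nrow(km))) {
      if (grepl(km$keyword[j], tolower(ann$ontology$name[i]), fixed = TRUE))
        hs <- union(hs, km$hallmark[j])
    }
    if (length(hs)) oracle[[ann$ontology$id[i]]] <- hs
  }
  expect_identical(tm[order(names(tm))], oracle[order(names(oracle))])
})

test_that("gene assignment follows the three-case rule with ties ambiguous", {
  tm <- build_term_map(toy_ontology, toy_map)
  g2g <- data.frame(
    gene = c("case1", "case1",
             "case2", "case2", "case2",
             "tie", "tie",
             "case3",
             "unknown_terms"),
    term = c("GO:0000001", "GO:0000001",
             "GO:0000001", "GO:0000001", "GO:0000003",
             "GO:0000001", "GO:0000003",
             "GO:0000002",
             "GO:9999999"),
    stringsAsFactors = FALSE)
  a <- assign_hallmarks(g2g, tm, genes = c("case1", "case2", "tie", "case3",
                                           "unknown_terms", "absent"))
  lab <- setNames(a$label, a$gene)
  expect_identical(lab[["case1"]], "immune")       # all terms one hallmark
  expect_identical(lab[["case2"]], "immune")       # majority vote
  expect_identical(lab[["tie"]], "ambiguous")      # tie at the maximum
  expect_identical(lab[["case3"]], "unannotated")  # no mapped terms
  expect_identical(lab[["unknown_terms"]], "unannotated")
  expect_identical(lab[["absent"]], "unannotated")
  expect_equal(a$immune[a$gene == "case2"], 2)
  expect_equal(a$stress[a$gene == "case2"], 1)

  # invariant to annotation order; adding a winning term never flips a label
  a2 <- assign_hallmarks(g2g[sample(nrow(g2g)), ], tm,
                         genes = c("case1", "case2", "tie", "case3",
                                   "unknown_terms", "absent"))
  expect_identical(setNames(a2$label, a2$gene)[names(lab)], lab)
  g2g3 <- rbind(g2g, data.frame(gene = "case2", term = "GO:0000001"))
  a3 <- assign_hallmarks(g2g3, tm, genes = "case2")
  expect_identical(a3$label, "immune")
})

test_that("assignment matches an independent brute-force implementation", {
  sim <- small_sim()  # 1200 fixture genes
  ann <- simulate_annotation(sim)
  tm <- build_term_map(ann$ontology, ann$keyword_map)
  a <- assign_hallmarks(ann$gene2go, tm, genes = sim$truth$gene)
  hallmarks <- attr(a, "hallmarks")
  oracle_label <- function(g) {
    terms <- ann$gene2go$term[ann$gene2go$gene == g]
    counts <- setNames(numeric(length(hallmarks)), hallmarks)
    for (t in terms)
      for (h in tm[[t]]) counts[h] <- counts[h] + 1
    if (all(counts == 0)) return("unannotated")
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) "ambiguous" else top
  }
  expect_identical(a$label, vapply(sim$truth$gene, oracle_label, ""),
                   ignore_attr = TRUE)
})

test_that("hallmark proportions sum to one and single out planted classes", {
  sim <- small_sim()
  ann <- simulate_annotation(sim)
  tm <- build_term_map(ann$ontology, ann$keyword_map)
  a <- assign_hallmarks(ann$gene2go, tm, genes = sim$truth$gene)

  pr <- hallmark_proportions(c("absent1", sim$truth$gene[1:3]), a)
  expect_equal(sum(pr$proportions), 1, tolerance = 1e-12)

  g_imm <- sim$truth$gene[sim$truth$class == "immune_up"]
  pim <- hallmark_proportions(g_imm, a)
  hm <- pim$proportions[attr(a, "hallmarks")]
  expect_identical(names(which.max(hm)), "immune_dysregulation")
  expect_gt(hm[["immune_dysregulation"]], max(hm[names(hm) !=
                                                   "immune_dysregulation"]))
  expect_equal(sum(pim$proportions), 1, tolerance = 1e-12)
  expect_equal(sum(pim$annotated_proportions), 1, tolerance = 1e-12)
  expect_error(hallmark_proportions(character(), a), "empty gene set")

  # worked arithmetic: 2 immune, 1 stress, 1 unannotated
  b <- a[0, ]
  toy <- data.frame(gene = c("x1", "x2", "x3"),
                    label = c("immune_dysregulation", "immune_dysregulation",
                              "stress_response"),
                    n_terms = 1)
  toy <- cbind(toy, matrix(0, 3, length(attr(a, "hallmarks")),
                           dimnames = list(NULL, attr(a, "hallmarks"))))
  class(toy) <- class(a); attr(toy, "hallmarks") <- attr(a, "hallmarks")
  pr <- hallmark_proportions(c("x1", "x2", "x3", "x4"), toy)
  expect_equal(unname(pr$proportions[c("immune_dysregulation",
                                       "stress_response", "unannotated")]),
               c(0.5, 0.25, 0.25))
})

test_that("single-assignment mode counts multi-hallmark terms once", {
  onto <- data.frame(id = "GO:0000010", name = "stress immune process",
                     namespace = "biological_process", is_obsolete = FALSE)
  tm <- build_term_map(onto, toy_map)
  expect_setequal(tm[["GO:0000010"]], c("immune", "stress"))
  g2g <- data.frame(gene = "g", term = "GO:0000010")
  multi <- assign_hallmarks(g2g, tm)
  expect_identical(multi$label, "ambiguous")
  single <- assign_hallmarks(g2g, tm, single_assignment = TRUE)
  expect_false(single$label == "ambiguous")
})

test_that("word-boundary mode restricts keyword matches", {
  onto <- data.frame(id = c("GO:1", "GO:2"),
                     name = c("immune-like response", "autoimmune disease"),
                     namespace = "biological_process", is_obsolete = FALSE)
  km <- data.frame(hallmark = "immune", keyword = "immune")
  loose <- build_term_map(onto, km)
  strict <- build_term_map(onto, km, word_boundary = TRUE)
  expect_true("GO:2" %in% names(loose))   # substring matches inside a word
  expect_false("GO:2" %in% names(strict))
})
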